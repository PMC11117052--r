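# paired repertoire simulation: configuration, SHM, assembly, reversion

#' Construct a natively paired record
#' @param record_id Unique identifier within a repertoire.
#' @param heavy,light [chain_record()] objects.
#' @param pairing `"native"` or `"shuffled"`.
#' @param specificity Specificity label (`"none"` when unlabelled).
#' @param lineage_id Clonal lineage identifier.
#' @export
paired_record <- function(record_id, heavy, light, pairing = "native",
                          specificity = "none", lineage_id = record_id) {
  stopifnot(inherits(heavy, "chain_record"), inherits(light, "chain_record"))
  structure(list(record_id = record_id, heavy = heavy, light = light,
                 pairing = match.arg(pairing, c("native", "shuffled")),
                 specificity = specificity, lineage_id = lineage_id),
            class = "paired_record")
}

#' @export
print.paired_record <- function(x, ...) {
  cat(sprintf("<paired record %s> %s pairing, specificity %s\n",
              x$record_id, x$pairing, x$specificity))
  print(x$heavy); print(x$light)
  invisible(x)
}

#' Repertoire simulation configuration
#'
#' Defaults describe a healthy-donor-like memory/naive mix: a gamma-Poisson
#' shared mutation load couples heavy and light SHM within a pair
#' (correlation `(m/k)/(m/k + 1)` for mean `shm_rate = m` and gamma shape
#' `k`), mutations fall on CDR positions with `cdr_bias`-fold higher weight
#' than framework positions, and light V genes follow the database's
#' heavy-to-light pairing matrix except with probability `pairing_noise`.
#'
#' @param n_pairs Number of paired records to generate (>= 1).
#' @param naive_fraction Fraction of pairs left unmutated.
#' @param shm_rate Mean per-chain mutation count for mutated lineages.
#' @param shm_gamma_shape Gamma shape of the shared pair-level load.
#' @param cdr_bias Relative mutation weight of CDR vs framework positions.
#' @param pairing_noise Probability of ignoring the pairing matrix.
#' @param junction_insert_max,junction_trim_max Junctional diversity bounds.
#' @param duplicate_fraction Fraction of records that are exact copies.
#' @param nonproductive_fraction Fraction of records given a stop (`*`).
#' @param motif_spec Optional named list of per-class paired CDR3 motifs,
#'   each element `list(heavy = "....", light = "....")`.
#' @param class_fractions Optional named fractions over
#'   `c(names(motif_spec), "none")`; defaults to uniform over motif classes.
#' @param seed Integer seed; repertoires are deterministic given the config.
#' @return An object of class `repertoire_config`.
#' @export
repertoire_config <- function(n_pairs = 2000, naive_fraction = 0.3,
                              shm_rate = 6, shm_gamma_shape = 2,
                              cdr_bias = 3, pairing_noise = 0.1,
                              junction_insert_max = 4, junction_trim_max = 2,
                              duplicate_fraction = 0.02,
                              nonproductive_fraction = 0.02,
                              motif_spec = NULL, class_fractions = NULL,
                              seed = 1) {
  if (!is.numeric(n_pairs) || n_pairs < 1) stopf("'n_pairs' must be >= 1")
  for (nm in c("naive_fraction", "pairing_noise", "duplicate_fraction",
               "nonproductive_fraction"))
    check_prob(get(nm), nm)
  if (shm_rate < 0 || shm_gamma_shape <= 0 || cdr_bias <= 0)
    stopf("shm_rate must be >= 0; shm_gamma_shape and cdr_bias must be > 0")
  if (!is.null(motif_spec)) {
    if (is.null(names(motif_spec)) || any(names(motif_spec) == ""))
      stopf("'motif_spec' must be a named list of classes")
    for (m in motif_spec)
      if (!all(c("heavy", "light") %in% names(m)))
        stopf("each motif class needs 'heavy' and 'light' motifs")
    if (is.null(class_fractions)) {
      class_fractions <- rep(1 / length(motif_spec), length(motif_spec))
      names(class_fractions) <- names(motif_spec)
    }
    if (!all(names(class_fractions) %in% c(names(motif_spec), "none")) ||
        abs(sum(class_fractions) - 1) > 1e-9)
      stopf("'class_fractions' must be named over motif classes (+ 'none') and sum to 1")
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 naive_fraction = naive_fraction, shm_rate = shm_rate,
                 shm_gamma_shape = shm_gamma_shape, cdr_bias = cdr_bias,
                 pairing_noise = pairing_noise,
                 junction_insert_max = as.integer(junction_insert_max),
                 junction_trim_max = as.integer(junction_trim_max),
                 duplicate_fraction = duplicate_fraction,
                 nonproductive_fraction = nonproductive_fraction,
                 motif_spec = motif_spec, class_fractions = class_fractions,
                 seed = as.integer(seed)),
            class = "repertoire_config")
}

#' Read or write a repertoire configuration as JSON
#' @param cfg A [repertoire_config()].
#' @param path File path.
#' @export
write_repertoire_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_repertoire_config
#' @export
read_repertoire_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$motif_spec <- if (length(x$motif_spec)) lapply(x$motif_spec, as.list) else NULL
  cf <- x$class_fractions
  x$class_fractions <- if (length(cf)) unlist(cf) else NULL
  do.call(repertoire_config, x)
}

# sample mutated positions without replacement, CDR-weighted
sample_mutation_positions <- function(region_map, n, cdr_bias) {
  len <- length(region_map)
  if (n >= len) {
    warning("requested mutation count >= sequence length; truncating")
    n <- len - 1L
  }
  if (n == 0) return(integer(0))
  w <- ifelse(region_map %in% CDR_REGIONS, cdr_bias, 1)
  sort(sample.int(len, n, prob = w))
}

mutate_chain <- function(chain, n, cdr_bias) {
  pos <- sample_mutation_positions(chain$region_map, n, cdr_bias)
  s <- chars(chain$sequence)
  for (p in pos) s[p] <- sample(setdiff(AA_ALPHABET, s[p]), 1)
  chain_record(paste(s, collapse = ""), chain$germline_sequence, chain$chain,
               chain$v_id, chain$j_id, chain$d_id, chain$region_map,
               chain$productive)
}

#' Apply somatic hypermutation to a naive pair
#'
#' Draws one gamma-distributed load for the pair (mean `cfg$shm_rate`, shape
#' `cfg$shm_gamma_shape`) and Poisson per-chain mutation counts around it,
#' which induces the positive heavy/light mutation-count correlation seen in
#' natively paired repertoires. Mutated positions are sampled without
#' replacement with weight `cfg$cdr_bias` on CDR positions; each mutated
#' residue is replaced by a uniformly random different amino acid. The
#' germline sequence is left untouched. Uses the current RNG state.
#'
#' @param pair An unmutated [paired_record()].
#' @param cfg A [repertoire_config()].
#' @return The mutated pair.
#' @export
apply_shm <- function(pair, cfg) {
  if (length(pair$heavy$mutation_positions) ||
      length(pair$light$mutation_positions))
    stopf("apply_shm() expects an unmutated pair")
  k <- cfg$shm_gamma_shape
  lambda <- stats::rgamma(1, shape = k, rate = k / cfg$shm_rate)
  n_h <- stats::rpois(1, lambda)
  n_l <- stats::rpois(1, lambda)
  pair$heavy <- mutate_chain(pair$heavy, n_h, cfg$cdr_bias)
  pair$light <- mutate_chain(pair$light, n_l, cfg$cdr_bias)
  pair
}

#' Revert a chain to its germline (inferred naive) state
#'
#' Replaces every somatically mutated residue with its germline counterpart;
#' because the stored germline includes the nontemplated junction, the
#' reversion target is defined at every position.
#'
#' @param chain A [chain_record()].
#' @return The germline-reverted [chain_record()]; idempotent.
#' @export
germline_revert <- function(chain) {
  chain_record(chain$germline_sequence, chain$germline_sequence, chain$chain,
               chain$v_id, chain$j_id, chain$d_id, chain$region_map,
               chain$productive)
}

plant_motif <- function(chain, motif) {
  cdr3 <- which(chain$region_map == "CDR3")
  if (length(cdr3) == 0 || !nzchar(motif)) return(chain)
  n <- min(nchar(motif), length(cdr3))
  s <- chars(chain$sequence)
  s[cdr3[seq_len(n)]] <- chars(motif)[seq_len(n)]
  seq <- paste(s, collapse = "")
  # planted pre-SHM: the motif is part of the lineage's naive state
  chain_record(seq, seq, chain$chain, chain$v_id, chain$j_id, chain$d_id,
               chain$region_map, chain$productive)
}

make_nonproductive <- function(pair) {
  side <- sample(c("heavy", "light"), 1)
  ch <- pair[[side]]
  s <- chars(ch$sequence)
  s[sample.int(length(s), 1)] <- "*"
  pair[[side]] <- chain_record(paste(s, collapse = ""), ch$germline_sequence,
                               ch$chain, ch$v_id, ch$j_id, ch$d_id,
                               ch$region_map, productive = FALSE)
  pair
}

#' Simulate a natively paired antibody repertoire
#'
#' Generates `cfg$n_pairs` paired records: heavy V genes drawn uniformly,
#' light V genes from the database pairing matrix (ignored with probability
#' `cfg$pairing_noise`), optional class-specific CDR3 motifs planted before
#' SHM, a `naive_fraction` of pairs left unmutated, exact duplicate records
#' and nonproductive (stop-containing) records injected for filter
#' exercising. Deterministic given `cfg$seed`.
#'
#' @param db A [generate_germline_db()] database.
#' @param cfg A [repertoire_config()].
#' @return A list of [paired_record()] objects, classed `repertoire`, with
#'   the configuration attached as attribute `config`.
#' @export
build_repertoire <- function(db, cfg) {
  stopifnot(inherits(db, "germline_db"), inherits(cfg, "repertoire_config"))
  with_seed(cfg$seed, {
    n_dup <- round(cfg$n_pairs * cfg$duplicate_fraction)
    n_base <- cfg$n_pairs - n_dup
    if (n_base < 1) stopf("duplicate_fraction leaves no base records")
    pm <- db$pairing_matrix
    heavy_vs <- rownames(pm); light_vs <- colnames(pm)

    classes <- "none"
    if (!is.null(cfg$motif_spec)) classes <- names(cfg$class_fractions)

    recs <- vector("list", n_base)
    for (i in seq_len(n_base)) {
      hv <- sample(heavy_vs, 1)
      lv <- if (stats::runif(1) < cfg$pairing_noise) sample(light_vs, 1)
            else sample(light_vs, 1, prob = pm[hv, ])
      h <- recombine(db, "heavy", cfg$junction_insert_max,
                     cfg$junction_trim_max, v_id = hv)
      l <- recombine(db, "light", cfg$junction_insert_max,
                     cfg$junction_trim_max, v_id = lv)
      spec <- if (is.null(cfg$motif_spec)) "none"
              else sample(classes, 1, prob = cfg$class_fractions)
      if (spec != "none") {
        h <- plant_motif(h, cfg$motif_spec[[spec]]$heavy)
        l <- plant_motif(l, cfg$motif_spec[[spec]]$light)
      }
      pair <- paired_record(sprintf("P%05d", i), h, l,
                            specificity = spec,
                            lineage_id = sprintf("lin%05d", i))
      if (stats::runif(1) >= cfg$naive_fraction)
        pair <- apply_shm(pair, cfg)
      recs[[i]] <- pair
    }

    if (cfg$nonproductive_fraction > 0) {
      n_np <- round(cfg$n_pairs * cfg$nonproductive_fraction)
      for (i in sample.int(n_base, min(n_np, n_base)))
        recs[[i]] <- make_nonproductive(recs[[i]])
    }

    if (n_dup > 0) {
      src <- sample.int(n_base, n_dup, replace = TRUE)
      for (k in seq_len(n_dup)) {
        cp <- recs[[src[k]]]
        cp$record_id <- sprintf("P%05d", n_base + k)
        recs[[n_base + k]] <- cp
      }
    }
    structure(recs, class = "repertoire", config = cfg)
  })
}

#' @export
print.repertoire <- function(x, ...) {
  nm <- vapply(x, function(p) length(p$heavy$mutation_positions) +
                 length(p$light$mutation_positions), 0L)
  prod <- vapply(x, function(p) p$heavy$productive && p$light$productive, TRUE)
  cat(sprintf("Paired repertoire: %d pairs (%d unmutated, %d nonproductive)\n",
              length(x), sum(nm == 0), sum(!prod)))
  invisible(x)
}
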
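# germline segment database and V(D)J recombination

#' Construct a germline gene segment
#'
#' A segment carries its amino-acid residues together with an ordered region
#' layout (region label, length) whose lengths must sum to the sequence
#' length. D segments exist only for heavy chains and are entirely CDR3;
#' J segments open with a CDR3 portion followed by FR4.
#'
#' @param segment_id Segment identifier, e.g. `"HV03"`.
#' @param chain `"heavy"` or `"light"`.
#' @param segment_class `"V"`, `"D"` or `"J"`.
#' @param residues Amino-acid string.
#' @param region_layout Named integer vector of region lengths in segment
#'   order, names from `FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4`.
#' @return An object of class `germline_segment`.
#' @export
germline_segment <- function(segment_id, chain, segment_class, residues,
                             region_layout) {
  chain <- match.arg(chain, c("heavy", "light"))
  segment_class <- match.arg(segment_class, c("V", "D", "J"))
  if (segment_class == "D" && chain != "heavy")
    stopf("D segments exist only for heavy chains")
  if (sum(region_layout) != nchar(residues))
    stopf("region layout of '%s' sums to %d but sequence has %d residues",
          segment_id, sum(region_layout), nchar(residues))
  if (segment_class == "J" &&
      !identical(names(region_layout), c("CDR3", "FR4")))
    stopf("J segment layout must be CDR3 then FR4")
  structure(
    list(segment_id = segment_id, chain = chain,
         segment_class = segment_class, residues = residues,
         region_layout = region_layout),
    class = "germline_segment"
  )
}

# default region layouts (residue counts)
HEAVY_V_LAYOUT <- c(FR1 = 25L, CDR1 = 8L, FR2 = 17L, CDR2 = 8L, FR3 = 38L)
LIGHT_V_LAYOUT <- c(FR1 = 23L, CDR1 = 7L, FR2 = 15L, CDR2 = 7L, FR3 = 32L)
HEAVY_J_LAYOUT <- c(CDR3 = 3L, FR4 = 11L)
LIGHT_J_LAYOUT <- c(CDR3 = 3L, FR4 = 10L)
HEAVY_D_LEN <- 8L

#' Generate a random germline segment database
#'
#' Builds a set of V, D and J gene segments for both chains with fixed
#' region layouts, plus a row-stochastic heavy-to-light V pairing matrix
#' encoding the tendency of particular heavy V genes to recombine alongside
#' particular light V genes. By default each heavy V concentrates
#' `concentration` of its pairing mass on one preferred light V.
#'
#' @param n_heavy_v,n_heavy_d,n_heavy_j,n_light_v,n_light_j Segment counts;
#'   V counts must be at least 2, others at least 1.
#' @param seed Integer seed; the database is deterministic given the seed.
#' @param concentration Pairing-matrix mass placed on the preferred light V.
#' @return An object of class `germline_db` with elements `segments`
#'   (named list of [germline_segment()]), `pairing_matrix` and `seed`.
#' @examples
#' db <- generate_germline_db(2, 1, 1, 2, 1, seed = 7)
#' length(db$segments)       # 7 segments
#' rowSums(db$pairing_matrix)
#' @export
generate_germline_db <- function(n_heavy_v = 4, n_heavy_d = 2, n_heavy_j = 2,
                                 n_light_v = 4, n_light_j = 2, seed = 1,
                                 concentration = 0.8) {
  counts <- c(n_heavy_v = n_heavy_v, n_heavy_d = n_heavy_d,
              n_heavy_j = n_heavy_j, n_light_v = n_light_v,
              n_light_j = n_light_j)
  if (any(counts < 1)) stopf("all segment counts must be >= 1")
  if (n_heavy_v < 2 || n_light_v < 2) stopf("V gene counts must be >= 2")
  check_prob(concentration, "concentration")

  with_seed(seed, {
    segs <- list()
    add <- function(s) segs[[s$segment_id]] <<- s
    for (i in seq_len(n_heavy_v))
      add(germline_segment(sprintf("HV%02d", i), "heavy", "V",
                           rand_aa(sum(HEAVY_V_LAYOUT)), HEAVY_V_LAYOUT))
    for (i in seq_len(n_heavy_d))
      add(germline_segment(sprintf("HD%02d", i), "heavy", "D",
                           rand_aa(HEAVY_D_LEN), c(CDR3 = HEAVY_D_LEN)))
    for (i in seq_len(n_heavy_j))
      add(germline_segment(sprintf("HJ%02d", i), "heavy", "J",
                           rand_aa(sum(HEAVY_J_LAYOUT)), HEAVY_J_LAYOUT))
    for (i in seq_len(n_light_v))
      add(germline_segment(sprintf("LV%02d", i), "light", "V",
                           rand_aa(sum(LIGHT_V_LAYOUT)), LIGHT_V_LAYOUT))
    for (i in seq_len(n_light_j))
      add(germline_segment(sprintf("LJ%02d", i), "light", "J",
                           rand_aa(sum(LIGHT_J_LAYOUT)), LIGHT_J_LAYOUT))

    pm <- matrix(0, n_heavy_v, n_light_v,
                 dimnames = list(sprintf("HV%02d", seq_len(n_heavy_v)),
                                 sprintf("LV%02d", seq_len(n_light_v))))
    for (i in seq_len(n_heavy_v)) {
      pref <- ((i - 1L) %% n_light_v) + 1L
      if (n_light_v == 1L) pm[i, ] <- 1
      else {
        pm[i, ] <- (1 - concentration) / (n_light_v - 1)
        pm[i, pref] <- concentration
      }
    }
    structure(list(segments = segs, pairing_matrix = pm, seed = seed),
              class = "germline_db")
  })
}

#' @export
print.germline_db <- function(x, ...) {
  cls <- vapply(x$segments, function(s) paste0(substr(s$chain, 1, 1),
                                               s$segment_class), "")
  cat("Germline database:", length(x$segments), "segments (",
      paste(names(table(cls)), table(cls), collapse = ", "), ")\n")
  cat("Heavy->light V pairing matrix:", nrow(x$pairing_matrix), "x",
      ncol(x$pairing_matrix), "\n")
  invisible(x)
}

db_segments <- function(db, chain, segment_class) {
  Filter(function(s) s$chain == chain && s$segment_class == segment_class,
         db$segments)
}

#' Construct an antibody chain record
#'
#' Stores the observed sequence together with its pre-mutation germline
#' ancestor (junctions included), per-position region labels and bookkeeping
#' of mutated positions. Mutation positions are recomputed from the two
#' sequences so the stored list can never drift out of sync.
#'
#' @param sequence,germline_sequence Equal-length amino-acid strings.
#' @param chain `"heavy"` or `"light"`.
#' @param v_id,d_id,j_id Germline segment identifiers (`d_id` may be `NA`).
#' @param region_map Character vector of per-position region labels.
#' @param productive Logical; nonproductive chains carry a `"*"` residue.
#' @return An object of class `chain_record`.
#' @export
chain_record <- function(sequence, germline_sequence, chain, v_id,
                         j_id, d_id = NA_character_, region_map,
                         productive = TRUE) {
  if (nchar(sequence) != nchar(germline_sequence) ||
      nchar(sequence) != length(region_map))
    stopf("sequence, germline and region map lengths disagree")
  s <- chars(sequence); g <- chars(germline_sequence)
  structure(
    list(sequence = sequence, germline_sequence = germline_sequence,
         chain = chain, v_id = v_id, d_id = d_id, j_id = j_id,
         region_map = region_map,
         mutation_positions = which(s != g),
         productive = productive),
    class = "chain_record"
  )
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("<%s chain> %s / %s%s, %d aa, %d mutation(s)%s\n", x$chain,
              x$v_id, x$j_id,
              if (!is.na(x$d_id)) paste0(" / ", x$d_id) else "",
              nchar(x$sequence), length(x$mutation_positions),
              if (x$productive) "" else " [nonproductive]"))
  invisible(x)
}

#' Recombine a chain from germline segments
#'
#' Assembles `V + junction + (D +  junction, heavy only) + J` with uniform
#' exonuclease-style trims in `[0, trim_max]` at each joining end and
#' uniform-length nontemplated inserts in `[0, insert_max]` of random
#' residues. Every junction, D and insert position is labelled CDR3, which
#' together with the J segment's templated CDR3 portion forms one contiguous
#' CDR3 block. The result carries no somatic mutations: the germline sequence
#' equals the observed sequence. Uses the current RNG state.
#'
#' @param db A [generate_germline_db()] database.
#' @param chain `"heavy"` or `"light"`.
#' @param insert_max,trim_max Junctional diversity bounds (residues).
#' @param v_id Optional forced V segment id (used to apply pairing rules).
#' @return A [chain_record()].
#' @export
recombine <- function(db, chain = c("heavy", "light"), insert_max = 4,
                      trim_max = 2, v_id = NULL) {
  chain <- match.arg(chain)
  vs <- db_segments(db, chain, "V")
  js <- db_segments(db, chain, "J")
  if (length(vs) == 0 || length(js) == 0)
    stopf("database has no %s V or J segments", chain)
  v <- if (is.null(v_id)) vs[[sample.int(length(vs), 1)]] else {
    if (is.null(db$segments[[v_id]])) stopf("unknown V segment '%s'", v_id)
    db$segments[[v_id]]
  }
  j <- js[[sample.int(length(js), 1)]]

  rtrim <- function() sample.int(trim_max + 1L, 1L) - 1L
  rins <- function() sample.int(insert_max + 1L, 1L) - 1L

  # V portion, 3' trimmed (eats into FR3)
  t_v <- min(rtrim(), v$region_layout[["FR3"]] - 1L)
  v_len <- nchar(v$residues) - t_v
  v_seq <- substr(v$residues, 1, v_len)
  v_map <- rep(names(v$region_layout), v$region_layout)[seq_len(v_len)]

  pieces <- list(list(seq = v_seq, map = v_map))
  add_insert <- function() {
    n <- rins()
    if (n > 0) pieces[[length(pieces) + 1L]] <<-
        list(seq = rand_aa(n), map = rep("CDR3", n))
  }
  add_insert()

  d_id <- NA_character_
  if (chain == "heavy") {
    ds <- db_segments(db, chain, "D")
    if (length(ds) == 0) stopf("database has no heavy D segments")
    d <- ds[[sample.int(length(ds), 1)]]
    t5 <- rtrim(); t3 <- rtrim()
    keep <- nchar(d$residues) - t5 - t3
    if (keep > 0)
      pieces[[length(pieces) + 1L]] <-
        list(seq = substr(d$residues, t5 + 1L, t5 + keep),
             map = rep("CDR3", keep))
    d_id <- d$segment_id
    add_insert()
  }

  # J portion, 5' trimmed within its CDR3 part (at least one templated
  # CDR3 residue always survives, so CDR3 can never be empty)
  t_j <- min(rtrim(), j$region_layout[["CDR3"]] - 1L)
  j_seq <- substr(j$residues, t_j + 1L, nchar(j$residues))
  j_map <- rep(names(j$region_layout), j$region_layout)[-seq_len(t_j)]
  if (t_j == 0) j_map <- rep(names(j$region_layout), j$region_layout)
  pieces[[length(pieces) + 1L]] <- list(seq = j_seq, map = j_map)

  seq <- paste(vapply(pieces, `[[`, "", "seq"), collapse = "")
  map <- unlist(lapply(pieces, `[[`, "map"), use.names = FALSE)
  chain_record(sequence = seq, germline_sequence = seq, chain = chain,
               v_id = v$segment_id, j_id = j$segment_id, d_id = d_id,
               region_map = map)
}
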
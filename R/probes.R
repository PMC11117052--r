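# probing a trained encoder: region CEL, embeddings, mutation masking,
# cross-chain attention

softmax_row <- function(x) { e <- exp(x - max(x)); e / sum(e) }

cel_floor <- function(p) -log(max(p, 1e-12))

#' Per-position cross-entropy by iterative masking
#'
#' Masks one residue token at a time, runs the model, and records the
#' natural-log cross-entropy of the true residue at the masked position.
#' Special and pad tokens are skipped; one forward pass per residue.
#'
#' @param model An `ablm` fit or stub.
#' @param example An `encoded_example`.
#' @param spec The [tokenizer_spec()] used to encode it.
#' @return Numeric CEL vector, one entry per residue token in
#'   `example$residue_index_map` order, with the per-residue region labels
#'   as attribute `regions`.
#' @export
per_position_cel <- function(model, example, spec) {
  ids <- crop_ids(example)
  rmap <- example$residue_index_map
  cel <- numeric(nrow(rmap))
  for (r in seq_len(nrow(rmap))) {
    tk <- rmap$token[r]
    ids2 <- ids
    ids2[tk] <- spec$mask_id
    fw <- model_forward(model, ids2)
    p <- softmax_row(fw$logits[tk, ])
    cel[r] <- cel_floor(p[ids[tk]])
  }
  attr(cel, "regions") <- example$region_map[rmap$token]
  attr(cel, "chain") <- rmap$chain
  cel
}

#' Summarize per-position CEL by region
#'
#' For each sequence, the median CEL within each antibody region, split by
#' the pair's mutation status (unmutated = zero mutations in both chains).
#' Regions absent from a sequence are omitted for that sequence.
#'
#' @param cel_list List of CEL vectors (one per sequence).
#' @param region_list List of aligned per-residue region label vectors.
#' @param mutation_status Character vector (`"unmutated"`/`"mutated"`), one
#'   per sequence.
#' @param ids Optional sequence identifiers.
#' @return A data frame with columns `sequence`, `region`, `median_cel`,
#'   `mutation_status`.
#' @export
summarize_region_cel <- function(cel_list, region_list, mutation_status,
                                 ids = NULL) {
  stopifnot(length(cel_list) == length(region_list),
            length(cel_list) == length(mutation_status))
  if (is.null(ids)) ids <- as.character(seq_along(cel_list))
  rows <- list()
  for (i in seq_along(cel_list)) {
    cel <- cel_list[[i]]; reg <- region_list[[i]]
    stopifnot(length(cel) == length(reg))
    for (r in intersect(REGIONS_ALL, unique(reg[!is.na(reg)]))) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = ids[i], region = r,
        median_cel = stats::median(cel[which(reg == r)]),
        mutation_status = mutation_status[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$region <- factor(out$region, levels = REGIONS_ALL)
  out
}

#' Chain-sliced mean embeddings
#'
#' Extracts the final-layer hidden states, slices them to the residue span
#' of the requested chain (special tokens excluded) and averages over
#' positions, yielding one hidden-size vector per input. Paired and
#' unpaired models are thereby directly comparable.
#'
#' @param model An `ablm` fit or stub.
#' @param examples List of `encoded_example`.
#' @param chain `"heavy"` or `"light"`.
#' @return An N x H matrix with a `labels` attribute (data frame of
#'   record id, own-chain V gene, partner-chain V gene where available, and
#'   mutation count).
#' @export
extract_chain_embeddings <- function(model, examples,
                                     chain = c("heavy", "light")) {
  chain <- match.arg(chain)
  rows <- list(); labs <- list()
  for (i in seq_along(examples)) {
    ex <- examples[[i]]
    span <- ex[[paste0(chain, "_span")]]
    if (is.null(span)) stopf("example %d has no %s span", i, chain)
    fw <- model_forward(model, ex, want_hidden = TRUE)
    hid <- fw$hidden[[length(fw$hidden)]]
    rows[[i]] <- colMeans(hid[span[1]:span[2], , drop = FALSE])
    m <- ex$meta
    own <- if (!is.null(m$v)) m$v else m[[paste0(chain, "_v")]]
    partner <- m[[paste0(setdiff(c("heavy", "light"), chain), "_v")]]
    labs[[i]] <- data.frame(
      record_id = m$record_id %||% NA_character_,
      v_gene = own %||% NA_character_,
      partner_v_gene = partner %||% NA_character_,
      n_mut = (m[[paste0("n_mut_", substr(chain, 1, 5))]] %||%
                 m$n_mut) %||% NA_integer_,
      stringsAsFactors = FALSE)
  }
  emb <- do.call(rbind, rows)
  attr(emb, "labels") <- do.call(rbind, labs)
  emb
}

#' k-nearest-neighbour label purity of an embedding
#'
#' Mean, over rows, of the fraction of the `k` nearest neighbours
#' (Euclidean; ties broken by row order) sharing the row's label. A
#' quantitative stand-in for visual cluster separation in reduced
#' embeddings.
#'
#' @param emb Numeric matrix (rows = items).
#' @param labels Label vector, one per row.
#' @param k Neighbourhood size; requires `nrow(emb) > k`.
#' @return Purity in `[0, 1]`.
#' @export
embedding_cluster_purity <- function(emb, labels, k = 10) {
  n <- nrow(emb)
  if (n <= k) stopf("need more rows (%d) than neighbours k = %d", n, k)
  stopifnot(length(labels) == n)
  d <- as.matrix(stats::dist(emb))
  acc <- 0
  for (i in seq_len(n)) {
    ord <- order(d[i, -i], seq_len(n - 1))  # ties by row order
    nbr <- (seq_len(n)[-i])[ord[seq_len(k)]]
    acc <- acc + mean(labels[nbr] == labels[i])
  }
  acc / n
}

#' Mutation-masking probe with native or germline-reverted partner
#'
#' Implements the cross-chain mutation probe: pairs with at least
#' `min_mutations` somatic mutations in each chain are selected; all mutated
#' positions of `masked_chain` are masked simultaneously; the partner chain
#' is presented natively, germline-reverted (via [germline_revert()]) or not
#' at all (unpaired encoding, for unpaired-trained models). Because only
#' mutated positions are masked, predicting the germline residue is always
#' wrong. Per masked position the probe records the cross-entropy of the
#' true (mutated) residue and the vocabulary mass decomposition scaled to
#' percent: the correct residue, other non-germline amino acids, the
#' germline residue, and special tokens.
#'
#' @param model An `ablm` fit or stub.
#' @param pairs List of [paired_record()] carrying germline alignments.
#' @param spec A [tokenizer_spec()].
#' @param masked_chain `"heavy"` or `"light"`.
#' @param partner `"native"`, `"germline_reverted"` or `"none"`.
#' @param min_mutations Minimum mutations required in each chain.
#' @return An object of class `mutation_mask_summary` with mean CEL and the
#'   mean likelihoods (x100) across all masked positions of all sequences.
#' @export
mutation_mask_probe <- function(model, pairs, spec,
                                masked_chain = c("heavy", "light"),
                                partner = c("native", "germline_reverted",
                                            "none"),
                                min_mutations = 3) {
  masked_chain <- match.arg(masked_chain)
  partner <- match.arg(partner)
  other <- setdiff(c("heavy", "light"), masked_chain)

  keep <- Filter(function(p)
    p$heavy$productive && p$light$productive &&
      length(p$heavy$mutation_positions) >= min_mutations &&
      length(p$light$mutation_positions) >= min_mutations, pairs)
  if (length(keep) == 0)
    stopf("no pairs with >= %d mutations in both chains", min_mutations)

  cel <- cor_lik <- other_lik <- germ_lik <- spec_lik <- numeric(0)
  for (p in keep) {
    mc <- p[[masked_chain]]
    if (partner == "none") {
      ex <- encode(mc, spec)
    } else {
      p2 <- p
      if (partner == "germline_reverted")
        p2[[other]] <- germline_revert(p2[[other]])
      ex <- encode(p2, spec)
    }
    rmap <- ex$residue_index_map
    mut_tokens <- rmap$token[rmap$chain == masked_chain &
                               rmap$pos %in% mc$mutation_positions]
    ids <- crop_ids(ex)
    truth <- ids[mut_tokens]
    ids[mut_tokens] <- spec$mask_id
    fw <- model_forward(model, ids)
    germ <- chars(mc$germline_sequence)[mc$mutation_positions]
    for (j in seq_along(mut_tokens)) {
      prow <- softmax_row(fw$logits[mut_tokens[j], ])
      aa_mass <- sum(prow[spec$aa_ids])
      pc <- prow[truth[j]]
      pg <- prow[spec$aa_ids[[germ[j]]]]
      cel <- c(cel, cel_floor(pc))
      cor_lik <- c(cor_lik, 100 * pc)
      germ_lik <- c(germ_lik, 100 * pg)
      other_lik <- c(other_lik, 100 * (aa_mass - pc - pg))
      spec_lik <- c(spec_lik, 100 * (1 - aa_mass))
    }
  }
  structure(list(condition = switch(partner, native = "native_partner",
                                    germline_reverted = "germline_reverted_partner",
                                    none = "no_partner"),
                 masked_chain = masked_chain,
                 n_pairs = length(keep), n_positions = length(cel),
                 mean_cel = mean(cel),
                 likelihood_correct = mean(cor_lik),
                 likelihood_other_nongermline = mean(other_lik),
                 likelihood_germline = mean(germ_lik),
                 likelihood_special = mean(spec_lik)),
            class = "mutation_mask_summary")
}

#' @export
print.mutation_mask_summary <- function(x, ...) {
  cat(sprintf(
    "Mutation-mask probe [%s chain, %s]: %d pairs, %d positions\n",
    x$masked_chain, x$condition, x$n_pairs, x$n_positions))
  cat(sprintf(
    "  mean CEL %.3f | likelihood correct %.2f, other non-germline %.2f, germline %.2f\n",
    x$mean_cel, x$likelihood_correct, x$likelihood_other_nongermline,
    x$likelihood_germline))
  invisible(x)
}

mean_attention_slices <- function(A) {
  out <- A[, , 1]
  nh <- dim(A)[3]
  if (nh > 1) for (h in 2:nh) out <- out + A[, , h]
  out / nh
}

#' Cross-chain attention summary
#'
#' From the final-layer attention of paired inputs, keeps only position
#' pairs spanning both chains (rows/columns for special and pad tokens
#' dropped), computes the attention received by each position (mean over
#' heads and cross-chain queries, normalized within each input to mean 1
#' per position so every sequence contributes equally), and aggregates it
#' by region. The
#' attention ratio is the percentage of cross-chain attention directed at
#' CDR positions divided by the percentage of positions classified as CDR;
#' per-CDR totals are normalized by region length.
#'
#' @param model An `ablm` fit or stub.
#' @param examples List of paired `encoded_example`.
#' @return An object of class `cross_chain_attention_summary`.
#' @export
cross_chain_attention_summary <- function(model, examples) {
  att_sum <- len_sum <- stats::setNames(
    numeric(8), c("CDR-H1", "CDR-H2", "CDR-H3", "CDR-L1", "CDR-L2", "CDR-L3",
                  "FR-H", "FR-L"))
  for (ex in examples) {
    if (is.null(ex$heavy_span) || is.null(ex$light_span))
      stopf("cross-chain attention requires paired encodings")
    fw <- model_forward(model, ex, want_attention = TRUE)
    A <- mean_attention_slices(fw$attention[[length(fw$attention)]])
    rmap <- ex$residue_index_map
    hv <- rmap$token[rmap$chain == "heavy"]
    lv <- rmap$token[rmap$chain == "light"]
    a_h <- colMeans(A[lv, hv, drop = FALSE])  # received by heavy positions
    a_l <- colMeans(A[hv, lv, drop = FALSE])  # received by light positions
    scale <- (length(a_h) + length(a_l)) / sum(a_h, a_l)
    a_h <- a_h * scale; a_l <- a_l * scale
    reg_h <- ex$region_map[hv]; reg_l <- ex$region_map[lv]
    key_of <- function(reg, side)
      ifelse(reg %in% CDR_REGIONS,
             paste0("CDR-", side, substr(reg, 4, 4)), paste0("FR-", side))
    kh <- key_of(reg_h, "H"); kl <- key_of(reg_l, "L")
    for (k in unique(kh)) {
      att_sum[k] <- att_sum[k] + sum(a_h[kh == k])
      len_sum[k] <- len_sum[k] + sum(kh == k)
    }
    for (k in unique(kl)) {
      att_sum[k] <- att_sum[k] + sum(a_l[kl == k])
      len_sum[k] <- len_sum[k] + sum(kl == k)
    }
  }
  cdr_keys <- grep("^CDR", names(att_sum), value = TRUE)
  fr_keys <- grep("^FR", names(att_sum), value = TRUE)
  total <- sum(att_sum)
  pct_cdr <- 100 * sum(att_sum[cdr_keys]) / total
  pct_pos_cdr <- 100 * sum(len_sum[cdr_keys]) / sum(len_sum)
  structure(list(pct_attention_cdr = pct_cdr,
                 pct_attention_fr = 100 - pct_cdr,
                 pct_positions_cdr = pct_pos_cdr,
                 attention_ratio = pct_cdr / pct_pos_cdr,
                 per_cdr_normalized = att_sum[cdr_keys] / len_sum[cdr_keys],
                 fr_normalized = sum(att_sum[fr_keys]) / sum(len_sum[fr_keys]),
                 n_examples = length(examples)),
            class = "cross_chain_attention_summary")
}

#' @export
print.cross_chain_attention_summary <- function(x, ...) {
  cat(sprintf(
    "Cross-chain attention (%d inputs): %.1f%% to CDRs (%.1f%% of positions); ratio %.2f\n",
    x$n_examples, x$pct_attention_cdr, x$pct_positions_cdr,
    x$attention_ratio))
  invisible(x)
}

#' Per-antibody cross-chain attention map
#'
#' Averages attention across every layer and head, symmetrises each
#' heavy/light position pair, and returns the heavy x light matrix together
#' with the per-position summed attention vectors used for structure
#' colouring.
#'
#' @param model An `ablm` fit or stub.
#' @param example A paired `encoded_example`.
#' @return A list with `map` (heavy x light), `v_heavy`, `v_light`; class
#'   `mab_attention_map`.
#' @export
per_mab_attention_map <- function(model, example) {
  if (is.null(example$heavy_span) || is.null(example$light_span))
    stopf("per-antibody attention requires a paired encoding")
  fw <- model_forward(model, example, want_attention = TRUE)
  L <- example$n_real
  acc <- matrix(0, L, L); n <- 0
  for (A in fw$attention) {
    for (h in seq_len(dim(A)[3])) { acc <- acc + A[, , h]; n <- n + 1 }
  }
  acc <- acc / n
  rmap <- example$residue_index_map
  hv <- rmap$token[rmap$chain == "heavy"]
  lv <- rmap$token[rmap$chain == "light"]
  M <- (acc[hv, lv, drop = FALSE] + t(acc[lv, hv, drop = FALSE])) / 2
  dimnames(M) <- list(paste0("H", rmap$pos[rmap$chain == "heavy"]),
                      paste0("L", rmap$pos[rmap$chain == "light"]))
  structure(list(map = M, v_heavy = rowSums(M), v_light = colSums(M)),
            class = "mab_attention_map")
}

#' Write an attention map as TSV
#' @param x A `mab_attention_map`.
#' @param path Output path.
#' @export
write_attention_map <- function(x, path) {
  utils::write.table(x$map, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
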
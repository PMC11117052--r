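# corpus construction: filtering, splitting, shuffling, unpairing

#' Filter duplicate and nonproductive pairs
#'
#' Removes records whose heavy or light chain is nonproductive and exact
#' duplicates at the amino-acid level (identical heavy and light sequences;
#' first occurrence kept). Nonproductive removal is applied first, matching
#' the order in which annotation pipelines drop failed rearrangements.
#'
#' @param records A `repertoire` or list of [paired_record()].
#' @return A list with `records` (survivors) and `report` (counts of
#'   removals by reason).
#' @export
filter_pairs <- function(records) {
  prod <- vapply(records, function(p)
    isTRUE(p$heavy$productive) && isTRUE(p$light$productive), TRUE)
  n_nonprod <- sum(!prod)
  kept <- records[prod]
  key <- vapply(kept, function(p)
    paste(p$heavy$sequence, p$light$sequence, sep = "::"), "")
  dup <- duplicated(key)
  out <- kept[!dup]
  list(records = structure(out, class = "repertoire"),
       report = list(input = length(records),
                     nonproductive = n_nonprod,
                     duplicates = sum(dup),
                     output = length(out)))
}

#' Random train/eval/test split
#'
#' Partitions record ids at the given fractions (default 90/5/5). Eval and
#' test sizes are `round(n * fraction)`; the remainder goes to train.
#'
#' @param records List of [paired_record()] (or a character vector of ids).
#' @param fractions Numeric length-3 vector summing to 1.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return An object of class `dataset_split` with `train`, `eval`, `test`
#'   id vectors.
#' @export
split_dataset <- function(records, fractions = c(0.90, 0.05, 0.05), seed = 1) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9)
    stopf("'fractions' must be three values summing to 1")
  ids <- if (is.character(records)) records
         else vapply(records, `[[`, "", "record_id")
  n <- length(ids)
  n_eval <- round(n * fractions[2]); n_test <- round(n * fractions[3])
  with_seed(seed, {
    perm <- sample(ids)
    ev <- if (n_eval > 0) perm[seq_len(n_eval)] else character(0)
    te <- if (n_test > 0) perm[n_eval + seq_len(n_test)] else character(0)
    tr <- perm[-seq_len(n_eval + n_test)]
    if (n_eval + n_test == 0) tr <- perm
    structure(list(train = sort(tr), eval = sort(ev), test = sort(te),
                   fractions = fractions, seed = seed),
              class = "dataset_split")
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("Dataset split (seed %d): train %d / eval %d / test %d\n",
              x$seed, length(x$train), length(x$eval), length(x$test)))
  invisible(x)
}

#' Subset records to one side of a dataset split
#' @param records List of [paired_record()].
#' @param split A [split_dataset()] result (or a list with `train`/`eval`/
#'   `test` id vectors).
#' @param which `"train"`, `"eval"` or `"test"`.
#' @return The matching records, classed `repertoire`.
#' @export
subset_split <- function(records, split, which = "train") {
  ids <- vapply(records, `[[`, "", "record_id")
  structure(records[ids %in% split[[which]]], class = "repertoire")
}

#' Shuffle light chains across pairs
#'
#' Applies one uniform random permutation of the light chains, marking every
#' record `shuffled`. The heavy and light multisets are preserved exactly.
#' Also counts pairs that remain native (the permuted light sequence is
#' identical to the original partner's), which is nonzero in practice due to
#' light-chain redundancy.
#'
#' @param records List of at least 2 [paired_record()].
#' @param seed Integer seed.
#' @return A list with `records` (shuffled) and `n_native` (count of pairs
#'   whose light sequence is unchanged).
#' @export
make_shuffled <- function(records, seed = 1) {
  if (length(records) < 2) stopf("need at least 2 records to shuffle")
  with_seed(seed, {
    perm <- sample.int(length(records))
    orig <- vapply(records, function(p) p$light$sequence, "")
    out <- vector("list", length(records))
    for (i in seq_along(records)) {
      p <- records[[i]]
      p$light <- records[[perm[i]]]$light
      p$pairing <- "shuffled"
      out[[i]] <- p
    }
    list(records = structure(out, class = "repertoire"),
         n_native = sum(orig == orig[perm]))
  })
}

#' Unpair a paired corpus into single chains
#'
#' Emits the 2n individual chains of n pairs, preserving order (heavy then
#' light per record) so split membership is inherited from the paired split
#' and the corpora stay directly comparable. Redundant chains are
#' intentionally kept; the report counts them.
#'
#' @param records List of [paired_record()].
#' @return A list with `chains` (2n [chain_record()]s, named
#'   `<record_id>_heavy/light`) and `report` counting redundant heavy/light
#'   sequences.
#' @export
make_unpaired <- function(records) {
  chains <- list()
  for (p in records) {
    chains[[paste0(p$record_id, "_heavy")]] <- p$heavy
    chains[[paste0(p$record_id, "_light")]] <- p$light
  }
  hseq <- vapply(records, function(p) p$heavy$sequence, "")
  lseq <- vapply(records, function(p) p$light$sequence, "")
  list(chains = chains,
       report = list(total = length(chains),
                     redundant_heavy = sum(duplicated(hseq)),
                     redundant_light = sum(duplicated(lseq)),
                     unique_sequences = length(unique(c(hseq, lseq)))))
}

#' Encode a corpus of records or chains
#'
#' @param x A list of [paired_record()] (paired corpus) or of
#'   [chain_record()] (unpaired corpus).
#' @param spec A [tokenizer_spec()].
#' @return List of `encoded_example`.
#' @export
encode_corpus <- function(x, spec) lapply(x, encode, spec = spec)
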
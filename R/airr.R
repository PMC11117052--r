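# AIRR-style rearrangement TSV and FASTA import/export

region_bounds <- function(region_map) {
  out <- integer(0)
  for (r in REGIONS_ALL) {
    idx <- which(region_map == r)
    cols <- if (length(idx)) c(min(idx), max(idx)) else c(NA_integer_, NA_integer_)
    nm <- tolower(sub("FR", "fwr", r))
    out[paste0(nm, c("_start", "_end"))] <- cols
  }
  out
}

chain_row <- function(pair, side) {
  ch <- pair[[side]]
  b <- region_bounds(ch$region_map)
  data.frame(
    sequence_id = paste0(pair$record_id, "_", side),
    chain = side,
    sequence_aa = ch$sequence,
    germline_alignment_aa = ch$germline_sequence,
    v_call = ch$v_id, d_call = ch$d_id, j_call = ch$j_id,
    productive = ch$productive,
    as.list(b),
    pair_id = pair$record_id,
    specificity_label = pair$specificity,
    stringsAsFactors = FALSE
  )
}

#' Write a repertoire as an AIRR-style rearrangement TSV
#'
#' One row per chain (two per pair) with 1-based inclusive region boundary
#' columns (`fwr1_start` ... `fwr4_end`), germline alignment, segment calls
#' and the pair/specificity bookkeeping needed to round-trip a repertoire.
#'
#' @param records A `repertoire` or list of [paired_record()].
#' @param path Output TSV path.
#' @export
write_airr <- function(records, path) {
  rows <- do.call(rbind, unlist(lapply(records, function(p)
    list(chain_row(p, "heavy"), chain_row(p, "light"))), recursive = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

map_from_bounds <- function(row, len) {
  map <- rep(NA_character_, len)
  for (r in REGIONS_ALL) {
    nm <- tolower(sub("FR", "fwr", r))
    s <- row[[paste0(nm, "_start")]]; e <- row[[paste0(nm, "_end")]]
    if (!is.na(s) && !is.na(e)) map[s:e] <- r
  }
  map
}

#' Read an AIRR-style rearrangement TSV into a repertoire
#'
#' Inverse of [write_airr()]: rebuilds paired records, region maps and
#' mutation bookkeeping from the boundary columns.
#'
#' @param path TSV path.
#' @return A list of [paired_record()], classed `repertoire`.
#' @export
read_airr <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "")
  need <- c("sequence_id", "chain", "sequence_aa", "germline_alignment_aa",
            "v_call", "j_call", "productive", "pair_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("AIRR file lacks columns: %s",
                          paste(miss, collapse = ", "))
  recs <- lapply(split(df, factor(df$pair_id, levels = unique(df$pair_id))),
                 function(g) {
    h <- g[g$chain == "heavy", ][1, ]
    l <- g[g$chain == "light", ][1, ]
    if (any(is.na(h$sequence_id)) || any(is.na(l$sequence_id)))
      stopf("pair '%s' lacks a heavy or light row", g$pair_id[1])
    mk <- function(row) chain_record(
      row$sequence_aa, row$germline_alignment_aa, row$chain,
      row$v_call, row$j_call,
      if (is.na(row$d_call)) NA_character_ else row$d_call,
      map_from_bounds(row, nchar(row$sequence_aa)),
      productive = as.logical(row$productive))
    paired_record(h$pair_id, mk(h), mk(l),
                  specificity = h$specificity_label %||% "none",
                  lineage_id = h$pair_id)
  })
  structure(unname(recs), class = "repertoire")
}

#' Export chains as FASTA
#'
#' One record per chain with header
#' `record_id|chain|v_id|j_id|n_mut|specificity`.
#'
#' @param records A `repertoire` or list of [paired_record()].
#' @param path Output FASTA path.
#' @export
write_fasta <- function(records, path) {
  seqs <- character(0)
  for (p in records) for (side in c("heavy", "light")) {
    ch <- p[[side]]
    hdr <- paste(p$record_id, side, ch$v_id, ch$j_id,
                 length(ch$mutation_positions), p$specificity, sep = "|")
    seqs[hdr] <- ch$sequence
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
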
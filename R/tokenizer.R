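# tokenization of paired and unpaired chains

#' Tokenizer specification
#'
#' The `"roberta"` dialect uses a 25-token vocabulary (20 amino acids plus
#' `<s>`, `</s>`, `<pad>`, `<unk>`, `<mask>`); paired inputs are laid out as
#' `<s> heavy </s> light </s>` padded to 512 tokens and unpaired inputs as
#' `<s> chain </s>` padded to 256. The `"esm"` dialect separates the chains
#' with two `<cls>` tokens (`<cls> heavy <cls> <cls> light <eos>`) and pads
#' to 320.
#'
#' @param dialect `"roberta"` or `"esm"`.
#' @return An object of class `tokenizer_spec` with the vocabulary (stable
#'   token ids), special-token ids and maximum lengths.
#' @examples
#' spec <- tokenizer_spec("roberta")
#' length(spec$vocab)  # 25
#' @export
tokenizer_spec <- function(dialect = c("roberta", "esm")) {
  dialect <- match.arg(dialect)
  if (dialect == "roberta") {
    vocab <- c("<s>", "</s>", "<pad>", "<unk>", "<mask>", AA_ALPHABET)
    spec <- list(dialect = dialect, vocab = vocab,
                 bos_id = 1L, eos_id = 2L, pad_id = 3L, unk_id = 4L,
                 mask_id = 5L, max_len_paired = 512L, max_len_unpaired = 256L)
  } else {
    vocab <- c("<cls>", "<pad>", "<eos>", "<unk>", "<mask>", AA_ALPHABET)
    spec <- list(dialect = dialect, vocab = vocab,
                 cls_id = 1L, pad_id = 2L, eos_id = 3L, unk_id = 4L,
                 mask_id = 5L, max_len_paired = 320L, max_len_unpaired = 320L)
  }
  spec$aa_ids <- 5L + seq_along(AA_ALPHABET)
  names(spec$aa_ids) <- AA_ALPHABET
  spec$special_ids <- setdiff(seq_along(vocab), spec$aa_ids)
  structure(spec, class = "tokenizer_spec")
}

#' @export
print.tokenizer_spec <- function(x, ...) {
  cat(sprintf("Tokenizer (%s dialect): %d tokens, paired max %d, unpaired max %d\n",
              x$dialect, length(x$vocab), x$max_len_paired, x$max_len_unpaired))
  invisible(x)
}

aa_to_ids <- function(seq, spec) {
  s <- chars(seq)
  ids <- unname(spec$aa_ids[s])
  if (anyNA(ids)) {
    warning(sprintf("%d unknown residue(s) encoded as <unk>", sum(is.na(ids))))
    ids[is.na(ids)] <- spec$unk_id
  }
  as.integer(ids)
}

#' Serialize a tokenizer's token-id map to JSON
#' @param spec A [tokenizer_spec()].
#' @param path Output path.
#' @export
write_token_map <- function(spec, path) {
  jsonlite::write_json(as.list(stats::setNames(seq_along(spec$vocab), spec$vocab)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

new_encoded <- function(token_ids, n_real, heavy_span, light_span,
                        residue_index_map, region_map, meta, spec) {
  structure(list(token_ids = token_ids,
                 padding_mask = seq_along(token_ids) <= n_real,
                 n_real = n_real,
                 heavy_span = heavy_span, light_span = light_span,
                 residue_index_map = residue_index_map,
                 region_map = region_map,
                 meta = meta, dialect = spec$dialect),
            class = "encoded_example")
}

#' Encode a paired record or single chain into model tokens
#'
#' Produces an `encoded_example`: padded token ids, a padding mask, the
#' heavy/light token spans (residue tokens only, 1-based inclusive), a map
#' from token index back to (chain, residue position), and per-token region
#' labels when the input carries them. Sequences longer than the dialect
#' maximum raise an error rather than being truncated.
#'
#' @param x A [paired_record()] or [chain_record()] (or a plain string for a
#'   single chain).
#' @param spec A [tokenizer_spec()].
#' @return An object of class `encoded_example`.
#' @export
encode <- function(x, spec) {
  stopifnot(inherits(spec, "tokenizer_spec"))
  UseMethod("encode")
}

#' @export
encode.paired_record <- function(x, spec) {
  h <- aa_to_ids(x$heavy$sequence, spec)
  l <- aa_to_ids(x$light$sequence, spec)
  nh <- length(h); nl <- length(l)
  if (spec$dialect == "roberta") {
    ids <- c(spec$bos_id, h, spec$eos_id, l, spec$eos_id)
    h_start <- 2L; l_start <- nh + 3L
  } else {
    ids <- c(spec$cls_id, h, spec$cls_id, spec$cls_id, l, spec$eos_id)
    h_start <- 2L; l_start <- nh + 4L
  }
  n_real <- length(ids)
  if (n_real > spec$max_len_paired)
    stopf("encoded pair has %d tokens, exceeding max %d; refusing to truncate",
          n_real, spec$max_len_paired)
  region <- rep(NA_character_, n_real)
  region[h_start:(h_start + nh - 1L)] <- x$heavy$region_map
  region[l_start:(l_start + nl - 1L)] <- x$light$region_map
  ids <- c(ids, rep(spec$pad_id, spec$max_len_paired - n_real))
  region <- c(region, rep(NA_character_, spec$max_len_paired - n_real))
  rmap <- data.frame(
    token = c(h_start:(h_start + nh - 1L), l_start:(l_start + nl - 1L)),
    chain = rep(c("heavy", "light"), c(nh, nl)),
    pos = c(seq_len(nh), seq_len(nl)))
  meta <- list(record_id = x$record_id,
               heavy_v = x$heavy$v_id, light_v = x$light$v_id,
               n_mut_heavy = length(x$heavy$mutation_positions),
               n_mut_light = length(x$light$mutation_positions),
               specificity = x$specificity)
  new_encoded(ids, n_real, c(h_start, h_start + nh - 1L),
              c(l_start, l_start + nl - 1L), rmap, region, meta, spec)
}

#' @export
encode.chain_record <- function(x, spec) {
  ids_aa <- aa_to_ids(x$sequence, spec)
  n <- length(ids_aa)
  ids <- if (spec$dialect == "roberta") c(spec$bos_id, ids_aa, spec$eos_id)
         else c(spec$cls_id, ids_aa, spec$eos_id)
  n_real <- length(ids)
  if (n_real > spec$max_len_unpaired)
    stopf("encoded chain has %d tokens, exceeding max %d; refusing to truncate",
          n_real, spec$max_len_unpaired)
  region <- c(NA_character_, x$region_map, NA_character_,
              rep(NA_character_, spec$max_len_unpaired - n_real))
  ids <- c(ids, rep(spec$pad_id, spec$max_len_unpaired - n_real))
  rmap <- data.frame(token = 1L + seq_len(n), chain = x$chain, pos = seq_len(n))
  span <- c(2L, n + 1L)
  meta <- list(record_id = NA_character_, chain = x$chain, v = x$v_id,
               n_mut = length(x$mutation_positions))
  if (x$chain == "heavy")
    new_encoded(ids, n_real, span, NULL, rmap, region, meta, spec)
  else
    new_encoded(ids, n_real, NULL, span, rmap, region, meta, spec)
}

#' @export
encode.character <- function(x, spec) {
  ch <- chain_record(x, x, "heavy", NA_character_, NA_character_,
                     region_map = rep(NA_character_, nchar(x)))
  encode.chain_record(ch, spec)
}

#' Decode an encoded example back to amino-acid sequences
#'
#' @param example An `encoded_example`.
#' @param spec The [tokenizer_spec()] used to encode it.
#' @return A list with `heavy` and/or `light` sequence strings.
#' @export
decode <- function(example, spec) {
  out <- list()
  for (side in c("heavy", "light")) {
    span <- example[[paste0(side, "_span")]]
    if (is.null(span)) next
    ids <- example$token_ids[span[1]:span[2]]
    out[[side]] <- paste(spec$vocab[ids], collapse = "")
  }
  out
}

#' @export
print.encoded_example <- function(x, ...) {
  cat(sprintf("<encoded %s input> %d/%d real tokens%s%s\n", x$dialect,
              x$n_real, length(x$token_ids),
              if (!is.null(x$heavy_span))
                sprintf(", heavy %d-%d", x$heavy_span[1], x$heavy_span[2]) else "",
              if (!is.null(x$light_span))
                sprintf(", light %d-%d", x$light_span[1], x$light_span[2]) else ""))
  invisible(x)
}
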
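# encoder configuration, parameter initialization, masking, forward passes

#' Encoder architecture configuration
#'
#' The desk-scale default (2 layers, 4 heads, hidden size 64, intermediate
#' 256) trains in minutes on one CPU; `preset = "paper"` mirrors the
#' RoBERTa-large-class reference configuration (24 layers, 16 heads, hidden
#' 1024, intermediate 4096). Positional embeddings are absolute.
#'
#' @param n_layers,n_heads,hidden_size,intermediate_size Architecture sizes;
#'   `hidden_size` must be divisible by `n_heads`.
#' @param max_positions Maximum input length.
#' @param vocab_size Vocabulary size (25 for the roberta dialect).
#' @param seed Seed for parameter initialization.
#' @param preset Optional `"tiny"` or `"paper"` shorthand.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_layers = 2, n_heads = 4, hidden_size = 64,
                         intermediate_size = 256, max_positions = 512,
                         vocab_size = 25, seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("tiny", "paper"))
    if (preset == "paper") {
      n_layers <- 24; n_heads <- 16; hidden_size <- 1024
      intermediate_size <- 4096
    }
  }
  if (hidden_size %% n_heads != 0)
    stopf("hidden_size must be divisible by n_heads")
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 hidden_size = as.integer(hidden_size),
                 intermediate_size = as.integer(intermediate_size),
                 max_positions = as.integer(max_positions),
                 vocab_size = as.integer(vocab_size),
                 positional_embedding = "absolute",
                 seed = as.integer(seed)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "Encoder config: %d layers, %d heads, hidden %d, intermediate %d, max %d, vocab %d\n",
    x$n_layers, x$n_heads, x$hidden_size, x$intermediate_size,
    x$max_positions, x$vocab_size))
  invisible(x)
}

init_params <- function(cfg, classifier_classes = 0, sd = 0.02) {
  H <- cfg$hidden_size; I <- cfg$intermediate_size; V <- cfg$vocab_size
  rmat <- function(r, c) matrix(stats::rnorm(r * c, sd = sd), r, c)
  zmat <- function(r, c) matrix(0, r, c)
  omat <- function(c) matrix(1, 1, c)
  with_seed(cfg$seed, {
    p <- list(tok_emb = rmat(V, H), pos_emb = rmat(cfg$max_positions, H))
    for (l in seq_len(cfg$n_layers)) {
      key <- function(s) paste0("L", l, "_", s)
      p[[key("ln1_g")]] <- omat(H); p[[key("ln1_b")]] <- zmat(1, H)
      for (w in c("Wq", "Wk", "Wv", "Wo")) p[[key(w)]] <- rmat(H, H)
      for (b in c("bq", "bk", "bv", "bo")) p[[key(b)]] <- zmat(1, H)
      p[[key("ln2_g")]] <- omat(H); p[[key("ln2_b")]] <- zmat(1, H)
      p[[key("Wf1")]] <- rmat(H, I); p[[key("bf1")]] <- zmat(1, I)
      p[[key("Wf2")]] <- rmat(I, H); p[[key("bf2")]] <- zmat(1, H)
    }
    p$lnf_g <- omat(H); p$lnf_b <- zmat(1, H)
    p$head_W <- rmat(H, V); p$head_b <- zmat(1, V)
    if (classifier_classes > 0) {
      p$pool_W <- rmat(H, H); p$pool_b <- zmat(1, H)
      p$cls_W <- rmat(H, classifier_classes)
      p$cls_b <- zmat(1, classifier_classes)
    }
    p
  })
}

#' Dynamic masking configuration
#'
#' Defaults follow the standard MLM recipe: 15% of eligible (non-special,
#' non-pad) tokens are selected; of those, 80% become `<mask>`, 10% a random
#' amino-acid token and 10% are left unchanged. With `dynamic = TRUE` the
#' mask is resampled at every visit, so no two epochs see the same
#' corruption.
#'
#' @param select_fraction,mask_prob,random_prob,keep_prob Masking rates;
#'   the last three must sum to 1.
#' @param dynamic Resample the mask at every visit.
#' @return An object of class `masking_config`.
#' @export
masking_config <- function(select_fraction = 0.15, mask_prob = 0.8,
                           random_prob = 0.1, keep_prob = 0.1,
                           dynamic = TRUE) {
  check_prob(select_fraction, "select_fraction")
  if (abs(mask_prob + random_prob + keep_prob - 1) > 1e-9)
    stopf("mask_prob + random_prob + keep_prob must equal 1")
  structure(list(select_fraction = select_fraction, mask_prob = mask_prob,
                 random_prob = random_prob, keep_prob = keep_prob,
                 dynamic = dynamic),
            class = "masking_config")
}

#' Corrupt an encoded example for masked-language-model training
#'
#' Selects eligible residue tokens independently with probability
#' `cfg$select_fraction` and applies the 80/10/10 mask/random/keep rule.
#' Special and pad tokens are never selected; random replacements are drawn
#' from the 20 amino-acid tokens only. Labels hold the original token id at
#' selected positions and `NA` (the ignore sentinel) elsewhere. Uses the
#' current RNG state.
#'
#' @param example An `encoded_example`.
#' @param cfg A [masking_config()].
#' @param spec The [tokenizer_spec()] the example was encoded with.
#' @return A list with `token_ids` (corrupted) and `labels`.
#' @export
dynamic_mask <- function(example, cfg, spec) {
  ids <- example$token_ids
  labels <- rep(NA_integer_, length(ids))
  eligible <- example$residue_index_map$token
  if (cfg$select_fraction > 0 && length(eligible)) {
    sel <- eligible[stats::runif(length(eligible)) < cfg$select_fraction]
    if (length(sel)) {
      labels[sel] <- ids[sel]
      u <- stats::runif(length(sel))
      to_mask <- sel[u < cfg$mask_prob]
      to_rand <- sel[u >= cfg$mask_prob & u < cfg$mask_prob + cfg$random_prob]
      ids[to_mask] <- spec$mask_id
      if (length(to_rand))
        ids[to_rand] <- sample(spec$aa_ids, length(to_rand), replace = TRUE)
    }
  }
  list(token_ids = ids, labels = labels)
}

#' Mean masked-token cross-entropy
#'
#' Natural-log cross-entropy of the true token under the softmax of the
#' logits, averaged over labeled positions.
#'
#' @param output A model output with a `logits` matrix (tokens x vocab), or
#'   the matrix itself.
#' @param labels Integer labels (`NA` = ignore), aligned with logits rows.
#' @return Scalar loss.
#' @export
mlm_loss <- function(output, labels) {
  logits <- if (is.list(output)) output$logits else output
  idx <- which(!is.na(labels))
  if (length(idx) == 0) stopf("mlm_loss() needs at least one labeled position")
  tot <- 0
  for (i in idx) {
    row <- logits[i, ]
    p <- exp(row - max(row)); p <- p / sum(p)
    tot <- tot - log(max(p[labels[i]], 1e-300))
  }
  tot / length(idx)
}

crop_ids <- function(example) example$token_ids[seq_len(example$n_real)]

#' Run a model forward and expose logits, hidden states and attention
#'
#' Generic over model backends; the packaged encoder (`ablm`) and stub
#' models (`stub_model()`) both implement it. Inputs are cropped to their
#' real (non-pad) length, so returned matrices cover real tokens only.
#'
#' @param model An `ablm` model or stub.
#' @param example An `encoded_example` (or a bare integer id vector).
#' @param want_hidden,want_attention Request per-layer hidden states and
#'   attention stacks.
#' @return A list with `logits` (L x vocab), optional `hidden` (list of
#'   L x H matrices, last element the final layer-normed states) and
#'   `attention` (list over layers of L x L x heads arrays, rows summing
#'   to 1 over keys).
#' @export
model_forward <- function(model, example, want_hidden = FALSE,
                          want_attention = FALSE) UseMethod("model_forward")

#' @export
model_forward.ablm <- function(model, example, want_hidden = FALSE,
                               want_attention = FALSE) {
  ids <- if (is.numeric(example)) as.integer(example) else crop_ids(example)
  .enc_forward(model$params, ids, model$config$n_layers,
               model$config$n_heads, want_hidden, want_attention)
}

#' Build a stub model for probe calibration and testing
#'
#' Stubs expose the same `model_forward()` surface as a trained encoder but
#' compute their outputs from closures, allowing analytically known
#' behaviour: `type = "uniform"` emits uniform token probabilities and
#' uniform attention, giving known closed-form probe values.
#'
#' @param type `"uniform"` or `"custom"`.
#' @param vocab_size,n_layers,n_heads,hidden_size Shape of the emitted
#'   outputs.
#' @param logits_fn,hidden_fn,attention_fn For `type = "custom"`, closures
#'   taking the cropped id vector and returning the respective structures.
#' @return An object of class `ablm_stub`.
#' @export
stub_model <- function(type = c("uniform", "custom"), vocab_size = 25,
                       n_layers = 2, n_heads = 4, hidden_size = 64,
                       logits_fn = NULL, hidden_fn = NULL,
                       attention_fn = NULL) {
  type <- match.arg(type)
  structure(list(type = type, vocab_size = vocab_size, n_layers = n_layers,
                 n_heads = n_heads, hidden_size = hidden_size,
                 logits_fn = logits_fn, hidden_fn = hidden_fn,
                 attention_fn = attention_fn),
            class = "ablm_stub")
}

#' @export
model_forward.ablm_stub <- function(model, example, want_hidden = FALSE,
                                    want_attention = FALSE) {
  ids <- if (is.numeric(example)) as.integer(example) else crop_ids(example)
  L <- length(ids)
  out <- list()
  out$logits <- if (!is.null(model$logits_fn)) model$logits_fn(ids)
                else matrix(0, L, model$vocab_size)
  if (want_hidden) {
    out$hidden <- if (!is.null(model$hidden_fn)) model$hidden_fn(ids)
                  else rep(list(matrix(0, L, model$hidden_size)),
                           model$n_layers + 1)
  }
  if (want_attention) {
    out$attention <- if (!is.null(model$attention_fn)) model$attention_fn(ids)
                     else rep(list(array(1 / L, c(L, L, model$n_heads))),
                              model$n_layers)
  }
  out
}
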
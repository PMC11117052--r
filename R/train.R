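# masked-language-model training: optimizer, schedule, the ablm fit object

#' Training configuration
#'
#' Linear warmup to `peak_lr` over `warmup_steps`, then linear decay to zero
#' at `total_steps`; Adam with standard moment defaults. The reference
#' recipe at full scale used peak 4e-4 with 30,000 warmup steps out of
#' 500,000; desk-scale runs use proportionally reduced step counts.
#'
#' @param total_steps Number of optimizer steps.
#' @param batch_size Sequences per step.
#' @param peak_lr Peak learning rate.
#' @param warmup_steps Linear warmup length (must not exceed `total_steps`).
#' @param weight_decay Decoupled weight decay (0 disables; documented
#'   default, not part of the reference recipe).
#' @param seed Seed for batch order and masking.
#' @return An object of class `train_config`.
#' @export
train_config <- function(total_steps, batch_size = 8, peak_lr = 4e-4,
                         warmup_steps = max(1L, round(0.1 * total_steps)),
                         weight_decay = 0, seed = 1) {
  if (warmup_steps > total_steps)
    stopf("warmup_steps must not exceed total_steps")
  structure(list(total_steps = as.integer(total_steps),
                 batch_size = as.integer(batch_size), peak_lr = peak_lr,
                 warmup_steps = as.integer(warmup_steps),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given step
#'
#' @param step Step number (0-based: step 0 is before any update).
#' @param cfg A [train_config()].
#' @return The scheduled learning rate: 0 at step 0, `peak_lr` at
#'   `warmup_steps`, 0 at `total_steps`.
#' @export
lr_schedule <- function(step, cfg) {
  ifelse(step <= cfg$warmup_steps,
         cfg$peak_lr * step / cfg$warmup_steps,
         cfg$peak_lr * (cfg$total_steps - step) /
           (cfg$total_steps - cfg$warmup_steps))
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_update <- function(params, grads, st, lr, weight_decay = 0,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    upd <- (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && !grepl("_b$|_g$|_ln|ln", nm))
      upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = st)
}

# iterate epoch-shuffled batches over n items
batch_stream <- function(n, batch_size) {
  env <- new.env()
  env$order <- sample.int(n)
  env$pos <- 1L
  env$epoch <- 1L
  function() {
    take <- min(batch_size, n)
    if (env$pos + take - 1L > n) {
      env$order <- sample.int(n)
      env$pos <- 1L
      env$epoch <- env$epoch + 1L
    }
    idx <- env$order[env$pos:(env$pos + take - 1L)]
    env$pos <- env$pos + take
    idx
  }
}

#' Train a masked-language-model encoder
#'
#' Fits a bidirectional transformer encoder (see [model_config()]) to an
#' encoded corpus with the dynamic-masking MLM objective, Adam and a linear
#' warmup/decay schedule. Returns a classed fit object exposing the loss
#' trace and the usual methods (`print`, `summary`, `predict`, `plot`,
#' `coef`).
#'
#' @param corpus List of `encoded_example` (paired or unpaired).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param mask_cfg A [masking_config()].
#' @param spec The [tokenizer_spec()] used to encode the corpus.
#' @param init Optional `ablm` object or checkpoint path to initialize
#'   weights from (external-checkpoint hook).
#' @param eval_corpus Optional held-out encoded corpus; evaluation loss is
#'   recorded every `eval_every` steps.
#' @param eval_every Evaluation interval in steps.
#' @param early_stop_patience Optional integer: stop when the evaluation
#'   loss has not improved for this many consecutive evaluations (requires
#'   `eval_corpus`); guards against overfitting small corpora.
#' @param verbose Print progress.
#' @return An object of class `ablm`.
#' @export
train_mlm <- function(corpus, model_cfg, train_cfg,
                      mask_cfg = masking_config(), spec = tokenizer_spec(),
                      init = NULL, eval_corpus = NULL, eval_every = 50,
                      early_stop_patience = NULL, verbose = FALSE) {
  stopifnot(inherits(model_cfg, "model_config"),
            inherits(train_cfg, "train_config"))
  if (length(corpus) == 0) stopf("empty training corpus")
  params <- if (is.null(init)) init_params(model_cfg)
            else if (inherits(init, "ablm")) init$params
            else load_checkpoint(init)$params

  if (!is.null(early_stop_patience) && is.null(eval_corpus))
    stopf("early stopping requires an eval_corpus")
  st <- adam_state(params)
  trace <- data.frame(step = integer(0), loss = numeric(0), lr = numeric(0),
                      eval_loss = numeric(0))
  best_eval <- Inf; since_best <- 0L; stopped_at <- NA_integer_
  with_seed(train_cfg$seed, {
    next_batch <- batch_stream(length(corpus), train_cfg$batch_size)
    for (step in seq_len(train_cfg$total_steps)) {
      idx <- next_batch()
      ids_list <- vector("list", length(idx))
      lab_list <- vector("list", length(idx))
      for (b in seq_along(idx)) {
        ex <- corpus[[idx[b]]]
        m <- dynamic_mask(ex, mask_cfg, spec)
        keep <- seq_len(ex$n_real)
        ids_list[[b]] <- m$token_ids[keep]
        lab_list[[b]] <- m$labels[keep]
      }
      if (!any(vapply(lab_list, function(l) any(!is.na(l)), TRUE))) next
      res <- .enc_mlm_batch_grad(params, ids_list, lab_list,
                                 model_cfg$n_layers, model_cfg$n_heads)
      if (!is.finite(res$loss))
        stopf("training diverged at step %d (loss = %s)", step, res$loss)
      lr <- lr_schedule(step, train_cfg)
      upd <- adam_update(params, res$grads, st, lr, train_cfg$weight_decay)
      params <- upd$params; st <- upd$state
      ev <- NA_real_
      if (!is.null(eval_corpus) && step %% eval_every == 0) {
        ev <- eval_mlm_loss(params, model_cfg, eval_corpus, mask_cfg, spec,
                            seed = train_cfg$seed + 10000L)
        if (ev < best_eval) { best_eval <- ev; since_best <- 0L }
        else since_best <- since_best + 1L
      }
      trace[nrow(trace) + 1L, ] <- list(step, res$loss, lr, ev)
      if (verbose && step %% 50 == 0)
        message(sprintf("step %d  loss %.4f  lr %.2e", step, res$loss, lr))
      if (!is.null(early_stop_patience) &&
          since_best >= early_stop_patience) {
        stopped_at <- step
        if (verbose)
          message(sprintf("early stop at step %d (eval loss stalled)", step))
        break
      }
    }
  })
  structure(list(params = params, config = model_cfg,
                 train_config = train_cfg, mask_config = mask_cfg,
                 dialect = spec$dialect, trace = trace,
                 stopped_at = stopped_at),
            class = "ablm")
}

eval_mlm_loss <- function(params, model_cfg, corpus, mask_cfg, spec, seed) {
  with_seed(seed, {
    tot <- 0; n <- 0
    for (ex in corpus) {
      m <- dynamic_mask(ex, mask_cfg, spec)
      keep <- seq_len(ex$n_real)
      labs <- m$labels[keep]
      if (!any(!is.na(labs))) next
      fw <- .enc_forward(params, m$token_ids[keep], model_cfg$n_layers,
                         model_cfg$n_heads, FALSE, FALSE)
      k <- sum(!is.na(labs))
      tot <- tot + mlm_loss(fw, labs) * k
      n <- n + k
    }
    if (n == 0) NA_real_ else tot / n
  })
}

#' @export
print.ablm <- function(x, ...) {
  cat("Masked-language-model encoder fit\n")
  print(x$config)
  if (nrow(x$trace))
    cat(sprintf("Trained %d steps; loss %.4f -> %.4f\n",
                max(x$trace$step), x$trace$loss[1],
                x$trace$loss[nrow(x$trace)]))
  invisible(x)
}

#' @export
summary.ablm <- function(object, ...) {
  tr <- object$trace
  out <- list(config = object$config,
              steps = if (nrow(tr)) max(tr$step) else 0L,
              initial_loss = if (nrow(tr)) tr$loss[1] else NA_real_,
              final_loss = if (nrow(tr)) tr$loss[nrow(tr)] else NA_real_,
              n_parameters = sum(vapply(object$params, length, 0L)))
  class(out) <- "summary.ablm"
  out
}

#' @export
print.summary.ablm <- function(x, ...) {
  print(x$config)
  cat(sprintf("%d parameters; %d steps; train loss %.4f -> %.4f\n",
              x$n_parameters, x$steps, x$initial_loss, x$final_loss))
  invisible(x)
}

#' @export
coef.ablm <- function(object, ...) object$params

#' @export
plot.ablm <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$step, tr$loss, type = "l", xlab = "step",
                 ylab = "MLM loss", main = "Training loss", ...)
  if (any(!is.na(tr$eval_loss)))
    graphics::lines(tr$step[!is.na(tr$eval_loss)],
                    tr$eval_loss[!is.na(tr$eval_loss)], lty = 2)
  invisible(x)
}

#' Predict token distributions for an encoded example
#'
#' @param object An `ablm` fit.
#' @param newdata An `encoded_example`.
#' @param type `"logits"` or `"probs"` (softmax rows).
#' @param ... Unused.
#' @return A tokens x vocab matrix over the real (non-pad) tokens.
#' @export
predict.ablm <- function(object, newdata, type = c("logits", "probs"), ...) {
  type <- match.arg(type)
  fw <- model_forward(object, newdata)
  if (type == "logits") return(fw$logits)
  p <- exp(fw$logits - apply(fw$logits, 1, max))
  p / rowSums(p)
}

#' Save or load an encoder checkpoint (JSON, full precision)
#'
#' @param model An `ablm` fit.
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(config = unclass(model$config),
              train_config = unclass(model$train_config),
              mask_config = unclass(model$mask_config),
              dialect = model$dialect,
              trace = model$trace,
              params = lapply(model$params, function(m)
                list(dim = dim(m), data = as.numeric(m))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p)
    matrix(p$data, p$dim[1], p$dim[2]))
  cfg <- do.call(model_config, obj$config[c("n_layers", "n_heads",
                 "hidden_size", "intermediate_size", "max_positions",
                 "vocab_size", "seed")])
  tc <- do.call(train_config, obj$train_config[c("total_steps", "batch_size",
                "peak_lr", "warmup_steps", "weight_decay", "seed")])
  mc <- do.call(masking_config, obj$mask_config)
  structure(list(params = params, config = cfg, train_config = tc,
                 mask_config = mc, dialect = obj$dialect,
                 trace = as.data.frame(obj$trace)),
            class = "ablm")
}

#' Write a loss trace as TSV (step, loss, lr)
#' @param model An `ablm` fit.
#' @param path Output path.
#' @export
write_trace <- function(model, path) {
  utils::write.table(model$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
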
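# specificity classification: identity clustering, balanced datasets,
# classifier fine-tuning

#' Ungapped pairwise identity of two paired records
#'
#' Fraction of matching positions between the concatenated heavy+light
#' sequences, compared positionally and divided by the longer length (the
#' length difference counts as mismatch).
#'
#' @param a,b [paired_record()] objects.
#' @return Identity in `[0, 1]`.
#' @export
pair_identity <- function(a, b) {
  s1 <- chars(paste0(a$heavy$sequence, a$light$sequence))
  s2 <- chars(paste0(b$heavy$sequence, b$light$sequence))
  n <- min(length(s1), length(s2))
  sum(s1[seq_len(n)] == s2[seq_len(n)]) / max(length(s1), length(s2))
}

#' Greedy identity clustering, keeping representatives
#'
#' Iterates records in input order; a record joins the first existing
#' cluster whose representative it matches at `threshold` identity or
#' better, otherwise it founds a new cluster. Only representatives are
#' returned, removing near-duplicate lineage expansions before
#' classification.
#'
#' @param records List of [paired_record()].
#' @param threshold Identity threshold in `(0, 1]` (e.g. 0.95 or 0.99).
#' @return The representative records, in input order.
#' @export
cluster_by_identity <- function(records, threshold) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  reps <- list()
  for (r in records) {
    hit <- FALSE
    for (rep_ in reps)
      if (pair_identity(r, rep_) >= threshold) { hit <- TRUE; break }
    if (!hit) reps[[length(reps) + 1L]] <- r
  }
  reps
}

#' Build a balanced, identity-clustered classification dataset
#'
#' Each class source is shuffled (seeded), greedily clustered at the
#' identity threshold, and downsampled to the smallest class size so
#' classes are balanced; a stratified test split of `test_fraction` per
#' class is then held out, deterministically given the seed.
#'
#' @param class_sources Named list of record lists, one element per class.
#' @param threshold Clustering identity threshold.
#' @param test_fraction Held-out fraction per class (e.g. 0.05 or 0.10).
#' @param seed Integer seed.
#' @return An object of class `classification_dataset` with `train`,
#'   `train_labels`, `test`, `test_labels`, `classes`.
#' @export
build_classification_dataset <- function(class_sources, threshold = 0.95,
                                         test_fraction = 0.1, seed = 1) {
  if (is.null(names(class_sources)) || any(names(class_sources) == ""))
    stopf("'class_sources' must be a named list")
  check_prob(test_fraction, "test_fraction")
  classes <- names(class_sources)
  with_seed(seed, {
    clustered <- lapply(classes, function(k) {
      src <- class_sources[[k]]
      if (length(src) == 0) stopf("class '%s' has no records", k)
      reps <- cluster_by_identity(src[sample.int(length(src))], threshold)
      if (length(reps) == 0) stopf("class '%s' empty after clustering", k)
      reps
    })
    names(clustered) <- classes
    m <- min(vapply(clustered, length, 0L))
    n_test <- round(m * test_fraction)
    train <- list(); train_labels <- character(0)
    test <- list(); test_labels <- character(0)
    for (k in classes) {
      sel <- clustered[[k]][sample.int(length(clustered[[k]]), m)]
      te_idx <- if (n_test > 0) seq_len(n_test) else integer(0)
      test <- c(test, sel[te_idx])
      test_labels <- c(test_labels, rep(k, length(te_idx)))
      tr <- if (length(te_idx)) sel[-te_idx] else sel
      train <- c(train, tr)
      train_labels <- c(train_labels, rep(k, length(tr)))
    }
    structure(list(train = train, train_labels = train_labels,
                   test = test, test_labels = test_labels,
                   classes = classes, clustering_identity = threshold,
                   test_fraction = test_fraction, seed = seed),
              class = "classification_dataset")
  })
}

#' @export
print.classification_dataset <- function(x, ...) {
  cat(sprintf(
    "Classification dataset: %d classes (%s), %d train / %d test, clustered at %.0f%% identity\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    length(x$train), length(x$test), 100 * x$clustering_identity))
  invisible(x)
}

classifier_predict <- function(params, examples, cfg) {
  t(vapply(examples, function(ex) {
    as.numeric(.enc_cls_forward(params, crop_ids(ex), cfg$n_layers,
                                cfg$n_heads)$probs)
  }, numeric(ncol(params$cls_W))))
}

#' Fine-tune an encoder with a sequence-classification head
#'
#' Attaches a first-token-pooled head (dense + tanh + class logits) to a
#' pretrained encoder (or to a freshly initialized one when `pretrained` is
#' `NULL`) and trains the whole network with cross-entropy, Adam, and a
#' linear warmup (fraction `warmup_ratio` of total steps) followed by
#' linear decay. The run is repeated once per seed on the same split;
#' held-out accuracy is recorded every `eval_every` steps.
#'
#' @param pretrained An `ablm` fit, checkpoint path, or `NULL` (random
#'   encoder; requires `model_cfg`).
#' @param dataset A [build_classification_dataset()] result.
#' @param spec A [tokenizer_spec()].
#' @param epochs Training epochs (reference recipe: 1).
#' @param lr Peak learning rate.
#' @param warmup_ratio Warmup fraction of total steps.
#' @param batch_size Sequences per step.
#' @param seeds Integer vector; one fine-tuning run per seed.
#' @param eval_every Held-out evaluation interval (steps).
#' @param model_cfg [model_config()] for `pretrained = NULL`.
#' @param keep_models Keep the fine-tuned parameter sets in the result.
#' @return An object of class `ablm_classifier_runs`: per-run
#'   [compute_metrics()] results and accuracy traces (raw and
#'   [smooth_trace()]-smoothed).
#' @export
fine_tune_classifier <- function(pretrained, dataset, spec, epochs = 1,
                                 lr = 5e-5, warmup_ratio = 0.1,
                                 batch_size = 8, seeds = 1:5,
                                 eval_every = 10, model_cfg = NULL,
                                 keep_models = FALSE) {
  stopifnot(inherits(dataset, "classification_dataset"))
  if (inherits(pretrained, "character")) pretrained <- load_checkpoint(pretrained)
  if (is.null(pretrained) && is.null(model_cfg))
    stopf("either a pretrained encoder or a model_cfg is required")
  cfg <- if (!is.null(pretrained)) pretrained$config else model_cfg
  classes <- dataset$classes
  n_classes <- length(classes)
  y_train <- match(dataset$train_labels, classes)
  y_test <- dataset$test_labels

  enc_train <- encode_corpus(dataset$train, spec)
  enc_test <- encode_corpus(dataset$test, spec)
  n <- length(enc_train)
  steps_total <- max(1L, epochs * ceiling(n / batch_size))

  runs <- list()
  for (seed in seeds) {
    run <- with_seed(seed, {
      params <- if (!is.null(pretrained)) pretrained$params
                else init_params(model_config(
                  n_layers = cfg$n_layers, n_heads = cfg$n_heads,
                  hidden_size = cfg$hidden_size,
                  intermediate_size = cfg$intermediate_size,
                  max_positions = cfg$max_positions,
                  vocab_size = cfg$vocab_size, seed = seed))
      head <- init_params(model_config(
        n_layers = 0, n_heads = cfg$n_heads, hidden_size = cfg$hidden_size,
        intermediate_size = cfg$intermediate_size,
        max_positions = cfg$max_positions, vocab_size = cfg$vocab_size,
        seed = seed + 5000L), classifier_classes = n_classes)
      params$pool_W <- head$pool_W; params$pool_b <- head$pool_b
      params$cls_W <- head$cls_W; params$cls_b <- head$cls_b

      sched <- train_config(steps_total, batch_size, peak_lr = lr,
                            warmup_steps = max(1L, round(warmup_ratio *
                                                           steps_total)))
      st <- adam_state(params)
      next_batch <- batch_stream(n, batch_size)
      trace <- data.frame(step = integer(0), accuracy = numeric(0))
      eval_acc <- function() {
        probs <- classifier_predict(params, enc_test, cfg)
        mean(classes[max.col(probs, ties.method = "first")] == y_test)
      }
      for (step in seq_len(steps_total)) {
        idx <- next_batch()
        res <- .enc_cls_batch_grad(params, lapply(enc_train[idx], crop_ids),
                                   as.integer(y_train[idx]),
                                   cfg$n_layers, cfg$n_heads)
        if (!is.finite(res$loss)) stopf("classifier diverged at step %d", step)
        upd <- adam_update(params, res$grads, st, lr_schedule(step, sched))
        params <- upd$params; st <- upd$state
        if (step %% eval_every == 0 || step == steps_total)
          trace[nrow(trace) + 1L, ] <- list(step, eval_acc())
      }
      trace$smoothed <- smooth_trace(trace$accuracy)
      probs <- classifier_predict(params, enc_test, cfg)
      pred <- classes[max.col(probs, ties.method = "first")]
      scores <- if (n_classes == 2) probs[, 2] else NULL
      list(seed = seed,
           metrics = compute_metrics(y_test, pred, scores, classes),
           trace = trace,
           params = if (keep_models) params else NULL)
    })
    runs[[length(runs) + 1L]] <- run
  }
  structure(list(runs = runs, classes = classes, epochs = epochs, lr = lr,
                 batch_size = batch_size, steps_total = steps_total),
            class = "ablm_classifier_runs")
}

#' @export
print.ablm_classifier_runs <- function(x, ...) {
  acc <- vapply(x$runs, function(r) r$metrics$accuracy, 0)
  cat(sprintf(
    "Classifier fine-tuning: %d run(s), %d steps each; test accuracy %.3f (range %.3f-%.3f)\n",
    length(x$runs), x$steps_total, mean(acc), min(acc), max(acc)))
  invisible(x)
}

#' @export
summary.ablm_classifier_runs <- function(object, ...) {
  rows <- lapply(object$runs, function(r) {
    m <- r$metrics
    data.frame(seed = r$seed, accuracy = m$accuracy,
               f1 = if (m$task == "binary") m$f1 else m$macro_f1,
               auc = m$auc, aupr = m$aupr, mcc = m$mcc)
  })
  do.call(rbind, rows)
}

#' Write per-run metrics and accuracy traces as TSV
#' @param x An `ablm_classifier_runs` object.
#' @param metrics_path,trace_path Output paths (either may be `NULL`).
#' @export
write_classifier_tables <- function(x, metrics_path = NULL,
                                    trace_path = NULL) {
  if (!is.null(metrics_path))
    utils::write.table(summary(x), metrics_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(trace_path)) {
    tr <- do.call(rbind, lapply(x$runs, function(r)
      cbind(seed = r$seed, r$trace)))
    utils::write.table(tr, trace_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}
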
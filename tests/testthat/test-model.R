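# encoder and MLM objective: losses, gradients, schedule, determinism

test_that("mlm_loss matches closed forms", {
  labels <- c(NA, 6L, NA, 10L)
  uniform <- matrix(0, 4, 25)
  expect_equal(mlm_loss(uniform, labels), log(25), tolerance = 1e-9)

  confident <- matrix(-1e4, 4, 25)
  confident[2, 6] <- 0; confident[4, 10] <- 0
  expect_equal(mlm_loss(confident, labels), 0, tolerance = 1e-9)

  # hand-built two-position case: p(true) = 0.5 and 0.25
  two <- matrix(log(1e-9), 2, 25)
  two[1, c(6, 7)] <- log(0.5)
  two[2, 6] <- log(0.25); two[2, 7] <- log(0.75)
  expect_equal(mlm_loss(two, c(6L, 6L)), (log(2) + log(4)) / 2,
               tolerance = 1e-6)

  expect_error(mlm_loss(uniform, rep(NA_integer_, 4)), "labeled")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_model_config(seed = 11)
  params <- ablm:::init_params(cfg, classifier_classes = 2, sd = 0.1)
  ids <- c(1L, 7L, 12L, 20L, 9L, 2L)
  labels <- c(NA, 7L, NA, 18L, NA, NA)
  loss_at <- function(p)
    ablm:::.enc_mlm_batch_grad(p, list(ids), list(labels),
          cfg$n_layers, cfg$n_heads)$loss
  res <- ablm:::.enc_mlm_batch_grad(params, list(ids), list(labels),
               cfg$n_layers, cfg$n_heads)
  eps <- 1e-6
  set.seed(12)
  for (nm in c("tok_emb", "pos_emb", "L1_Wq", "L1_Wo", "L1_ln1_g",
               "L1_Wf1", "L1_Wf2", "lnf_g", "head_W")) {
    g <- res$grads[[nm]]
    for (k in sample(length(g), 4)) {
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- params; p3[[nm]][k] <- p3[[nm]][k] - eps
      num <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
      expect_equal(g[k], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, k))
    }
  }
})

test_that("batch loss equals a brute-force recomputation from logits", {
  cfg <- tiny_model_config(seed = 13)
  params <- ablm:::init_params(cfg, sd = 0.1)
  set.seed(14)
  for (rep in 1:25) {
    B <- sample(1:4, 1)
    ids_list <- lapply(seq_len(B), function(b)
      sample(1:25, sample(4:12, 1), replace = TRUE))
    lab_list <- lapply(ids_list, function(ids) {
      l <- rep(NA_integer_, length(ids))
      k <- sample(seq_along(ids), max(1, length(ids) %/% 3))
      l[k] <- ids[k]; l
    })
    res <- ablm:::.enc_mlm_batch_grad(params, ids_list, lab_list,
                 cfg$n_layers, cfg$n_heads)
    # oracle: per-sequence forward + direct -ln softmax, pooled over labels
    tot <- 0; n <- 0
    for (b in seq_len(B)) {
      fw <- model_forward(structure(list(params = params, config = cfg),
                                    class = "ablm"), ids_list[[b]])
      k <- sum(!is.na(lab_list[[b]]))
      tot <- tot + mlm_loss(fw, lab_list[[b]]) * k
      n <- n + k
    }
    expect_equal(res$loss, tot / n, tolerance = 1e-6)
  }
})

test_that("softmax rows and attention rows are stochastic", {
  cfg <- tiny_model_config(seed = 15)
  model <- structure(list(params = ablm:::init_params(cfg, sd = 0.1),
                          config = cfg), class = "ablm")
  ids <- sample(1:25, 20, replace = TRUE)
  fw <- model_forward(model, ids, want_hidden = TRUE, want_attention = TRUE)
  probs <- exp(fw$logits - apply(fw$logits, 1, max))
  probs <- probs / rowSums(probs)
  expect_equal(rowSums(probs), rep(1, 20), tolerance = 1e-6)
  for (A in fw$attention)
    for (h in seq_len(dim(A)[3]))
      expect_equal(rowSums(A[, , h]), rep(1, 20), tolerance = 1e-6)
  expect_length(fw$hidden, cfg$n_layers + 1)
  expect_equal(dim(fw$hidden[[1]]), c(20L, cfg$hidden_size))
})

test_that("learning rate schedule hits its endpoints", {
  tc <- train_config(total_steps = 100, warmup_steps = 30, peak_lr = 4e-4)
  expect_equal(lr_schedule(0, tc), 0)
  expect_equal(lr_schedule(30, tc), 4e-4)
  expect_equal(lr_schedule(100, tc), 0)
  expect_equal(lr_schedule(65, tc), 4e-4 * 35 / 70)
  expect_error(train_config(10, warmup_steps = 20), "exceed")
})

test_that("a tiny model overfits a single batch", {
  spec <- tokenizer_spec("roberta")
  set.seed(16)
  corpus <- lapply(1:4, function(i) encode(ablm:::rand_aa(30), spec))
  cfg <- tiny_model_config(seed = 16)
  tc <- train_config(total_steps = 20, batch_size = 4, peak_lr = 1e-3,
                     warmup_steps = 2, seed = 16)
  fit <- train_mlm(corpus, cfg, tc, spec = spec)
  expect_lt(tail(fit$trace$loss, 1), fit$trace$loss[1])
})

test_that("early stopping halts when evaluation loss stalls", {
  spec <- tokenizer_spec("roberta")
  set.seed(21)
  # tiny train set overfits fast; disjoint eval loss soon stops improving
  corpus <- lapply(1:2, function(i) encode(ablm:::rand_aa(25), spec))
  eval_c <- lapply(1:4, function(i) encode(ablm:::rand_aa(25), spec))
  fit <- train_mlm(corpus, tiny_model_config(21),
                   train_config(300, batch_size = 2, peak_lr = 3e-3,
                                warmup_steps = 5, seed = 21),
                   spec = spec, eval_corpus = eval_c, eval_every = 10,
                   early_stop_patience = 3)
  expect_false(is.na(fit$stopped_at))
  expect_lt(fit$stopped_at, 300)
  expect_equal(max(fit$trace$step), fit$stopped_at)
  expect_error(train_mlm(corpus, tiny_model_config(21),
                         train_config(5, batch_size = 2),
                         spec = spec, early_stop_patience = 2),
               "eval_corpus")
})

test_that("training is deterministic given seeds", {
  spec <- tokenizer_spec("roberta")
  set.seed(17)
  corpus <- lapply(1:6, function(i) encode(ablm:::rand_aa(25), spec))
  cfg <- tiny_model_config(seed = 17)
  tc <- train_config(total_steps = 8, batch_size = 3, peak_lr = 1e-3,
                     seed = 17)
  f1 <- train_mlm(corpus, cfg, tc, spec = spec)
  f2 <- train_mlm(corpus, cfg, tc, spec = spec)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$trace$loss, f2$trace$loss)
})

test_that("checkpoints round-trip the fitted model", {
  spec <- tokenizer_spec("roberta")
  set.seed(18)
  corpus <- lapply(1:4, function(i) encode(ablm:::rand_aa(20), spec))
  fit <- train_mlm(corpus, tiny_model_config(18),
                   train_config(3, batch_size = 2, seed = 18), spec = spec)
  f <- tempfile(fileext = ".json")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_equal(back$params, fit$params, tolerance = 1e-12)
  expect_equal(back$config$hidden_size, fit$config$hidden_size)
  # reloaded checkpoints can seed further training
  more <- train_mlm(corpus, fit$config,
                    train_config(2, batch_size = 2, seed = 19),
                    spec = spec, init = f)
  expect_s3_class(more, "ablm")
})

test_that("the fit object exposes the standard methods", {
  spec <- tokenizer_spec("roberta")
  set.seed(20)
  corpus <- lapply(1:4, function(i) encode(ablm:::rand_aa(20), spec))
  fit <- train_mlm(corpus, tiny_model_config(20),
                   train_config(3, batch_size = 2, seed = 20), spec = spec)
  expect_output(print(fit), "encoder fit")
  s <- summary(fit)
  expect_gt(s$n_parameters, 1000)
  expect_type(coef(fit), "list")
  pr <- predict(fit, corpus[[1]], type = "probs")
  expect_equal(rowSums(pr), rep(1, corpus[[1]]$n_real), tolerance = 1e-9)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
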
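# probing suite against stub models with closed-form behaviour

spec_r <- tokenizer_spec("roberta")

probe_pair <- function(h_mut = c(7, 12, 22), l_mut = c(3, 9, 16)) {
  fixture_pair("PR1", h_mut = h_mut, l_mut = l_mut)
}

test_that("per-position CEL is ln(25) under uniform logits and 0 under an oracle", {
  ex <- encode(probe_pair(), spec_r)
  cel <- per_position_cel(stub_model("uniform"), ex, spec_r)
  expect_length(cel, 60)
  expect_true(all(abs(cel - log(25)) < 1e-9))
  expect_identical(attr(cel, "regions")[1], "FR1")

  truth <- ex$token_ids[seq_len(ex$n_real)]
  oracle <- stub_model("custom", logits_fn = function(ids) {
    m <- matrix(-1e4, length(ids), 25)
    m[cbind(seq_along(truth), truth)] <- 0
    m
  })
  cel0 <- per_position_cel(oracle, ex, spec_r)
  expect_true(all(abs(cel0) < 1e-9))
})

test_that("per-position CEL matches hand-computed softmax values", {
  ch <- chain_record("ACD", "ACD", "heavy", "HV01", "HJ01",
                     region_map = rep("CDR1", 3))
  ex <- encode(ch, spec_r)
  logits <- matrix(0, 5, 25)
  logits[2, 6] <- 1; logits[3, 7] <- -1; logits[4, 8] <- 0.5
  stub <- stub_model("custom", logits_fn = function(ids) logits)
  cel <- per_position_cel(stub, ex, spec_r)
  expected <- c(-log(exp(1) / (exp(1) + 24)),
                -log(exp(-1) / (exp(-1) + 24)),
                -log(exp(0.5) / (exp(0.5) + 24)))
  expect_equal(as.numeric(cel), expected, tolerance = 1e-6)
})

test_that("region CEL summaries are per-sequence medians", {
  cels <- list(c(1, 2, 9, 5, 5, 5), c(2, 2, 2, 2, 2, 2))
  regs <- list(c("FR1", "FR1", "FR1", "CDR3", "CDR3", "CDR3"),
               c("FR1", "FR1", "CDR3", "CDR3", "FR4", "FR4"))
  tab <- summarize_region_cel(cels, regs, c("mutated", "unmutated"))
  expect_equal(tab$median_cel[tab$sequence == "1" & tab$region == "FR1"], 2)
  expect_equal(tab$median_cel[tab$sequence == "1" & tab$region == "CDR3"], 5)
  expect_true(all(tab$median_cel[tab$sequence == "2"] == 2))
  expect_false("FR4" %in% tab$region[tab$sequence == "1"])  # absent region omitted

  # brute-force check on random plantings
  set.seed(21)
  cels <- lapply(1:10, function(i) runif(30))
  regs <- lapply(1:10, function(i)
    sample(c("FR1", "CDR1", "CDR3"), 30, replace = TRUE))
  tab <- summarize_region_cel(cels, regs, rep("mutated", 10))
  for (i in sample(nrow(tab), 8)) {
    row <- tab[i, ]
    j <- as.integer(row$sequence)
    expect_equal(row$median_cel,
                 median(cels[[j]][regs[[j]] == as.character(row$region)]))
  }
})

test_that("chain embeddings are position means of final hidden states", {
  ex <- encode(probe_pair(), spec_r)
  H <- 8
  const <- stub_model("custom", hidden_size = H,
                      hidden_fn = function(ids)
                        list(matrix(0, length(ids), H),
                             matrix(2.5, length(ids), H)))
  emb <- extract_chain_embeddings(const, list(ex), "heavy")
  expect_equal(dim(emb), c(1L, H))
  expect_true(all(emb == 2.5))

  # hand-built states: row = arithmetic mean over the chain span
  vary <- stub_model("custom", hidden_size = 2,
                     hidden_fn = function(ids) {
                       m <- matrix(0, length(ids), 2)
                       m[, 1] <- seq_along(ids)
                       list(m, m)
                     })
  emb2 <- extract_chain_embeddings(vary, list(ex), "light")
  expect_equal(emb2[1, 1], mean(ex$light_span[1]:ex$light_span[2]))

  lab <- attr(emb2, "labels")
  expect_equal(lab$v_gene, "LV01")
  expect_equal(lab$partner_v_gene, "HV01")

  # single-residue chain equals that position's state
  one <- chain_record("A", "A", "light", "LV01", "LJ01",
                      region_map = "CDR3")
  ex1 <- encode(one, spec_r)
  emb3 <- extract_chain_embeddings(vary, list(ex1), "light")
  expect_equal(emb3[1, 1], 2)  # token position 2
})

test_that("kNN purity behaves at its analytic extremes", {
  set.seed(22)
  blobs <- rbind(matrix(rnorm(200, 0), 100, 2),
                 matrix(rnorm(200, 50), 100, 2))
  labels <- rep(c("a", "b"), each = 100)
  expect_equal(embedding_cluster_purity(blobs, labels, k = 10), 1.0)

  rand_lab <- sample(rep(c("a", "b"), each = 200))
  noise <- matrix(rnorm(800), 400, 2)
  p <- embedding_cluster_purity(noise, rand_lab, k = 10)
  expect_lt(abs(p - 0.5), 0.05)

  expect_error(embedding_cluster_purity(noise[1:5, ], rand_lab[1:5], k = 10),
               "more rows")
})

test_that("kNN purity tie-breaking follows row order", {
  emb <- matrix(1, 6, 3)  # all rows identical: every distance ties at 0
  labels <- c("a", "a", "b", "b", "b", "a")
  k <- 3
  # brute-force oracle with the first-come tie rule
  oracle <- mean(vapply(1:6, function(i) {
    nbr <- setdiff(1:6, i)[1:k]
    mean(labels[nbr] == labels[i])
  }, 0))
  expect_equal(embedding_cluster_purity(emb, labels, k = k), oracle)
})

test_that("uniform-logit mutation masking gives 4 / 72 / 4 likelihoods", {
  pairs <- list(probe_pair(), probe_pair(h_mut = c(2, 8, 14, 21)))
  s <- mutation_mask_probe(stub_model("uniform"), pairs, spec_r, "heavy",
                           "native")
  expect_equal(s$n_pairs, 2)
  expect_equal(s$n_positions, 7)
  expect_equal(s$likelihood_correct, 4.0, tolerance = 1e-9)
  expect_equal(s$likelihood_other_nongermline, 72.0, tolerance = 1e-9)
  expect_equal(s$likelihood_germline, 4.0, tolerance = 1e-9)
  expect_equal(s$mean_cel, log(25), tolerance = 1e-9)
})

test_that("likelihood decomposition sums to 100 per masked position", {
  set.seed(23)
  noisy <- stub_model("custom", logits_fn = function(ids)
    matrix(rnorm(length(ids) * 25), length(ids), 25))
  for (cond in c("native", "germline_reverted", "none")) {
    s <- mutation_mask_probe(noisy, list(probe_pair()), spec_r, "light", cond)
    expect_equal(s$likelihood_correct + s$likelihood_other_nongermline +
                   s$likelihood_germline + s$likelihood_special, 100,
                 tolerance = 1e-6)
  }
})

test_that("a germline-confident model is maximally surprised by mutations", {
  pairs <- list(probe_pair())
  germ_ids <- ablm:::aa_to_ids(pairs[[1]]$heavy$germline_sequence, spec_r)
  stub <- stub_model("custom", logits_fn = function(ids) {
    m <- matrix(-1e4, length(ids), 25)
    span <- 2:(1 + length(germ_ids))
    m[cbind(span, germ_ids)] <- 0
    m[-span, 1] <- 0
    m
  })
  s <- mutation_mask_probe(stub, pairs, spec_r, "heavy", "native")
  expect_equal(s$likelihood_correct, 0, tolerance = 1e-6)
  expect_equal(s$mean_cel, -log(1e-12), tolerance = 1e-6)  # CEL floor guard
})

test_that("the mutation filter keeps only pairs mutated in both chains", {
  pairs <- list(probe_pair(),                       # 3 + 3
                probe_pair(h_mut = c(1, 2), l_mut = c(3, 6, 9)),  # 2 + 3
                probe_pair(h_mut = c(1, 5, 9), l_mut = 2))        # 3 + 1
  s <- mutation_mask_probe(stub_model("uniform"), pairs, spec_r, "heavy",
                           "native", min_mutations = 3)
  expect_equal(s$n_pairs, 1)
  expect_error(
    mutation_mask_probe(stub_model("uniform"), pairs, spec_r, "heavy",
                        "native", min_mutations = 5),
    "no pairs")
})

test_that("germline-reverted and absent partners change the encoding", {
  p <- probe_pair()
  rev_light <- germline_revert(p$light)
  expect_false(identical(rev_light$sequence, p$light$sequence))
  # condition 'none' encodes the masked chain alone
  s <- mutation_mask_probe(stub_model("uniform"), list(p), spec_r, "heavy",
                           "none")
  expect_equal(s$n_positions, 3)
})

test_that("uniform attention gives a cross-chain CDR ratio of exactly 1", {
  exs <- lapply(list(probe_pair(), probe_pair(h_mut = 4)),
                encode, spec = spec_r)
  s <- cross_chain_attention_summary(stub_model("uniform"), exs)
  expect_equal(s$attention_ratio, 1.0, tolerance = 1e-9)
  expect_equal(s$pct_attention_cdr + s$pct_attention_fr, 100,
               tolerance = 1e-9)
  expect_equal(s$pct_attention_cdr, s$pct_positions_cdr, tolerance = 1e-9)
})

test_that("attention aimed at CDRs drives the CDR share to 100%", {
  ex <- encode(probe_pair(), spec_r)
  cdr_tokens <- which(ex$region_map[seq_len(ex$n_real)] %in%
                        c("CDR1", "CDR2", "CDR3"))
  stub <- stub_model("custom", n_layers = 1, n_heads = 2,
                     attention_fn = function(ids) {
    A <- matrix(0, length(ids), length(ids))
    A[, cdr_tokens] <- 1 / length(cdr_tokens)
    list(array(rep(A, 2), c(length(ids), length(ids), 2)))
  })
  s <- cross_chain_attention_summary(stub, list(ex))
  expect_equal(s$pct_attention_cdr, 100, tolerance = 1e-9)
  expect_error(
    cross_chain_attention_summary(stub, list(encode(fixture_chain(), spec_r))),
    "paired")
})

test_that("per-antibody attention maps are symmetrized means with conserved mass", {
  ex <- encode(probe_pair(), spec_r)
  m <- per_mab_attention_map(stub_model("uniform"), ex)
  L <- ex$n_real
  expect_true(all(abs(m$map - 1 / L) < 1e-12))
  expect_equal(sd(m$v_heavy), 0)
  expect_equal(sum(m$v_heavy), sum(m$v_light), tolerance = 1e-9)
  expect_equal(sum(m$v_heavy), sum(m$map), tolerance = 1e-9)

  # single nonzero entry: halved and averaged over layers x heads
  hv1 <- ex$heavy_span[1]; lv1 <- ex$light_span[1]
  stub <- stub_model("custom", n_layers = 2, n_heads = 2,
                     attention_fn = function(ids) {
    A0 <- array(0, c(length(ids), length(ids), 2))
    A1 <- A0
    A1[hv1, lv1, 1] <- 0.8
    list(A1, A0)
  })
  m2 <- per_mab_attention_map(stub, ex)
  expect_equal(sum(m2$map != 0), 1)
  expect_equal(m2$map[1, 1], 0.8 / 2 / 4)

  f <- tempfile(fileext = ".tsv")
  write_attention_map(m2, f)
  expect_true(file.exists(f))
})
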
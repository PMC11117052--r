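# shared fixtures: handcrafted records, tiny configs, and a cache of
# study-scale trained models reused across test files

aa_seq <- function(...) paste0(...)

# a small handcrafted chain with known regions and mutations
fixture_chain <- function(chain = "heavy",
                          germ = "AAAAACCCCCDDDDDEEEEEFFFFFGGGGG",
                          mutate_at = integer(0),
                          regions = rep(c("FR1", "CDR1", "FR2", "CDR2",
                                          "FR3", "CDR3"), each = 5),
                          productive = TRUE) {
  s <- strsplit(germ, "")[[1]]
  for (p in mutate_at) s[p] <- if (s[p] == "W") "Y" else "W"
  chain_record(paste(s, collapse = ""), germ, chain,
               v_id = if (chain == "heavy") "HV01" else "LV01",
               j_id = if (chain == "heavy") "HJ01" else "LJ01",
               d_id = if (chain == "heavy") "HD01" else NA_character_,
               region_map = regions, productive = productive)
}

fixture_pair <- function(id = "P1", h_mut = integer(0), l_mut = integer(0),
                         h_germ = "AAAAACCCCCDDDDDEEEEEFFFFFGGGGG",
                         l_germ = "HHHHHIIIIIKKKKKLLLLLMMMMMNNNNN",
                         specificity = "none") {
  paired_record(id,
                fixture_chain("heavy", h_germ, h_mut),
                fixture_chain("light", l_germ, l_mut),
                specificity = specificity)
}

tiny_model_config <- function(seed = 1)
  model_config(n_layers = 1, n_heads = 2, hidden_size = 16,
               intermediate_size = 32, max_positions = 64, vocab_size = 25,
               seed = seed)

# study conditions shared by the probe-recovery tests: a 2,000-pair
# repertoire with simulator defaults, desk-scale encoder, and a fixed
# training recipe. Models are trained lazily and cached per (variant, seed)
# so several tests can share them within one session.
STUDY <- list(n_pairs = 2000, steps = 500, batch = 8, lr = 1e-3)

.model_cache <- new.env(parent = emptyenv())

study_data <- function(seed) {
  key <- paste0("data", seed)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  db <- generate_germline_db(seed = seed)
  reps <- build_repertoire(db, repertoire_config(n_pairs = STUDY$n_pairs,
                                                 seed = seed))
  fl <- filter_pairs(reps)
  split <- split_dataset(fl$records, seed = seed)
  out <- list(db = db,
              train = subset_split(fl$records, split, "train"),
              test = subset_split(fl$records, split, "test"))
  .model_cache[[key]] <- out
  out
}

study_model <- function(variant = c("paired", "shuffled", "unpaired"),
                        seed = 1) {
  variant <- match.arg(variant)
  key <- paste0(variant, seed)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  spec <- tokenizer_spec("roberta")
  d <- study_data(seed)
  corpus <- switch(variant,
    paired = encode_corpus(d$train, spec),
    shuffled = encode_corpus(make_shuffled(d$train,
                                           seed = seed + 500)$records, spec),
    unpaired = encode_corpus(make_unpaired(d$train)$chains, spec))
  bs <- STUDY$batch * if (variant == "unpaired") 2L else 1L
  fit <- train_mlm(corpus, model_config(seed = seed),
                   train_config(STUDY$steps, batch_size = bs,
                                peak_lr = STUDY$lr, seed = seed),
                   spec = spec)
  .model_cache[[key]] <- fit
  fit
}
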
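# configuration-driven end-to-end runs: simulate -> prepare -> train three
# corpus variants -> probe -> classify -> report

#' Default experiment configuration
#'
#' Desk-scale settings for a complete run on one CPU. Any field can be
#' overridden via the `config` argument of [run_experiment()] (or a
#' JSON/YAML file with the same structure). One global `seed` fans out to
#' per-stage seeds as `seed * 100 + stage index` so stages are
#' independently reproducible.
#'
#' @param outdir Output directory.
#' @param seed Global seed.
#' @return A named list of configuration fields.
#' @export
default_experiment_config <- function(outdir = "ablm_run", seed = 1) {
  list(outdir = outdir, seed = seed,
       db = list(n_heavy_v = 4, n_heavy_d = 2, n_heavy_j = 2,
                 n_light_v = 4, n_light_j = 2),
       repertoire = list(n_pairs = 300),
       model = list(n_layers = 2, n_heads = 4, hidden_size = 64,
                    intermediate_size = 256),
       train = list(total_steps = 60, batch_size = 8, peak_lr = 1e-3),
       probes = list(n_region_cel = 5, n_attention = 10),
       classify = list(enabled = FALSE, test_fraction = 0.1,
                       threshold = 0.95, epochs = 1, lr = 1e-3,
                       batch_size = 8, n_seeds = 2))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

read_experiment_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  merge_config(default_experiment_config(), config %||% list())
}

stage_seed <- function(cfg, idx) cfg$seed * 100L + idx

outputs_exist <- function(paths) length(paths) > 0 && all(file.exists(paths))

#' Run the full paired/shuffled/unpaired experiment
#'
#' Executes the pipeline in dependency order: simulate a paired repertoire;
#' filter and split it; derive the shuffled and unpaired training corpora
#' from the same filtered records and split; train the three encoder
#' variants; run the region-CEL, mutation-mask and cross-chain attention
#' probes on the natively paired test split; optionally fine-tune a
#' specificity classifier when the repertoire carries motif classes. Stages
#' whose outputs already exist are skipped when `resume = TRUE`.
#'
#' @param config A configuration list (see [default_experiment_config()])
#'   or a path to a JSON/YAML file of overrides.
#' @param resume Skip stages whose outputs exist.
#' @param verbose Print stage progress.
#' @return A `run_manifest` describing inputs, outputs, seeds and
#'   timestamps of every stage.
#' @export
run_experiment <- function(config = list(), resume = TRUE, verbose = TRUE) {
  cfg <- read_experiment_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(cfg$outdir, ...)
  say <- function(...) if (verbose) message(sprintf(...))

  cfg_path <- path("config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(config = cfg,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed, stages = list(),
                   batch_ratio_unpaired_over_paired =
                     cfg$train$batch_size * 2 / cfg$train$batch_size)
  stamp <- function(name, outputs, skipped = FALSE) {
    manifest$stages[[name]] <<- list(outputs = outputs, skipped = skipped,
                                     seed = NULL,
                                     timestamp = format(Sys.time()))
  }
  spec <- tokenizer_spec("roberta")

  # stage 1: simulate
  airr_path <- path("repertoire.airr.tsv")
  if (resume && outputs_exist(airr_path)) {
    say("simulate: outputs exist, skipping")
    stamp("simulate", airr_path, skipped = TRUE)
  } else {
    say("simulate: %d pairs", cfg$repertoire$n_pairs)
    db <- do.call(generate_germline_db,
                  c(cfg$db, list(seed = stage_seed(cfg, 1L))))
    rep_cfg <- do.call(repertoire_config,
                       c(cfg$repertoire, list(seed = stage_seed(cfg, 1L))))
    reps <- build_repertoire(db, rep_cfg)
    write_airr(reps, airr_path)
    write_fasta(reps, path("repertoire.fasta"))
    stamp("simulate", airr_path)
  }

  # stage 2: prepare
  filt_path <- path("filtered.airr.tsv")
  split_path <- path("split.json")
  if (resume && outputs_exist(c(filt_path, split_path))) {
    say("prepare: outputs exist, skipping")
    stamp("prepare", c(filt_path, split_path), skipped = TRUE)
  } else {
    if (!file.exists(airr_path))
      stopf("stage 'prepare' needs %s; run the simulate stage first", airr_path)
    reps <- read_airr(airr_path)
    fl <- filter_pairs(reps)
    write_airr(fl$records, filt_path)
    split <- split_dataset(fl$records, seed = stage_seed(cfg, 2L))
    jsonlite::write_json(list(split = unclass(split), filter = fl$report),
                         split_path, auto_unbox = TRUE)
    stamp("prepare", c(filt_path, split_path))
  }

  # stage 3: train paired / shuffled / unpaired
  ckpt <- function(v) path(sprintf("model_%s.json", v))
  trained <- list()
  reps <- read_airr(filt_path)
  split_obj <- jsonlite::read_json(split_path, simplifyVector = TRUE)$split
  train_recs <- subset_split(reps, split_obj, "train")
  eval_recs <- subset_split(reps, split_obj, "eval")
  variants <- list(
    paired = function() encode_corpus(train_recs, spec),
    shuffled = function()
      encode_corpus(make_shuffled(train_recs,
                                  seed = stage_seed(cfg, 3L))$records, spec),
    unpaired = function() encode_corpus(make_unpaired(train_recs)$chains, spec))
  for (v in names(variants)) {
    if (resume && outputs_exist(ckpt(v))) {
      say("train %s: checkpoint exists, skipping", v)
      trained[[v]] <- load_checkpoint(ckpt(v))
      stamp(paste0("train_", v), ckpt(v), skipped = TRUE)
      next
    }
    say("train %s: %d steps", v, cfg$train$total_steps)
    corpus <- variants[[v]]()
    bs <- cfg$train$batch_size * if (v == "unpaired") 2L else 1L
    tc <- train_config(cfg$train$total_steps, batch_size = bs,
                       peak_lr = cfg$train$peak_lr,
                       seed = stage_seed(cfg, 4L))
    mc <- do.call(model_config, c(cfg$model, list(seed = stage_seed(cfg, 4L))))
    fit <- train_mlm(corpus, mc, tc, spec = spec)
    save_checkpoint(fit, ckpt(v))
    write_trace(fit, path(sprintf("trace_%s.tsv", v)))
    trained[[v]] <- fit
    stamp(paste0("train_", v), ckpt(v))
  }

  # stage 4: probes on the natively paired test split
  probe_paths <- path(c("region_cel.tsv", "mutation_mask.tsv",
                        "attention_summary.json"))
  if (resume && outputs_exist(probe_paths)) {
    say("probe: outputs exist, skipping")
    stamp("probe", probe_paths, skipped = TRUE)
  } else {
    test_recs <- subset_split(reps, split_obj, "test")
    say("probe: %d test pairs", length(test_recs))
    enc_test <- encode_corpus(test_recs, spec)
    n_cel <- min(cfg$probes$n_region_cel, length(enc_test))
    cel_rows <- NULL
    if (n_cel > 0) {
      cels <- lapply(enc_test[seq_len(n_cel)], function(ex)
        per_position_cel(trained$paired, ex, spec))
      status <- vapply(test_recs[seq_len(n_cel)], function(p)
        if (length(p$heavy$mutation_positions) +
            length(p$light$mutation_positions) == 0) "unmutated"
        else "mutated", "")
      cel_rows <- summarize_region_cel(
        cels, lapply(cels, attr, "regions"), status,
        ids = vapply(test_recs[seq_len(n_cel)], `[[`, "", "record_id"))
      utils::write.table(cel_rows, probe_paths[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    mm_rows <- list()
    for (v in names(trained)) {
      conds <- if (v == "unpaired") "none" else c("native", "germline_reverted")
      for (cond in conds) {
        s <- tryCatch(
          mutation_mask_probe(trained[[v]], test_recs, spec, "heavy", cond),
          error = function(e) NULL)
        if (!is.null(s))
          mm_rows[[length(mm_rows) + 1L]] <- data.frame(
            model = v, condition = s$condition, n_pairs = s$n_pairs,
            mean_cel = s$mean_cel,
            likelihood_correct = s$likelihood_correct,
            likelihood_other_nongermline = s$likelihood_other_nongermline)
      }
    }
    utils::write.table(do.call(rbind, mm_rows), probe_paths[2], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    n_att <- min(cfg$probes$n_attention, length(enc_test))
    att <- cross_chain_attention_summary(trained$paired,
                                         enc_test[seq_len(n_att)])
    jsonlite::write_json(unclass(att), probe_paths[3], auto_unbox = TRUE,
                         digits = NA)
    stamp("probe", probe_paths)
  }

  # stage 5: specificity classification (needs motif classes)
  if (isTRUE(cfg$classify$enabled)) {
    cls_path <- path("classifier_metrics.tsv")
    if (resume && outputs_exist(cls_path)) {
      say("classify: outputs exist, skipping")
      stamp("classify", cls_path, skipped = TRUE)
    } else {
      labels <- vapply(reps, `[[`, "", "specificity")
      classes <- setdiff(unique(labels), NA)
      if (length(classes) < 2) {
        say("classify: fewer than 2 specificity classes; stage flagged")
        manifest$stages$classify <- list(outputs = character(0),
                                         skipped = TRUE,
                                         reason = "fewer than 2 classes",
                                         timestamp = format(Sys.time()))
      } else {
        say("classify: %s", paste(classes, collapse = " vs "))
        sources <- lapply(classes, function(k) reps[labels == k])
        names(sources) <- classes
        ds <- build_classification_dataset(
          sources, cfg$classify$threshold, cfg$classify$test_fraction,
          seed = stage_seed(cfg, 5L))
        runs <- fine_tune_classifier(
          trained$paired, ds, spec, epochs = cfg$classify$epochs,
          lr = cfg$classify$lr, batch_size = cfg$classify$batch_size,
          seeds = seq_len(cfg$classify$n_seeds))
        write_classifier_tables(runs, cls_path,
                                path("classifier_trace.tsv"))
        stamp("classify", cls_path)
      }
    }
  }

  manifest_path <- path("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Experiment run (seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                if (isTRUE(st$skipped)) "skipped (outputs present)" else "done"))
  }
  invisible(x)
}

#' Aggregate a completed run into a markdown report
#'
#' Collects the probe tables and classification metrics written by
#' [run_experiment()] into one summary document; missing stages are flagged
#' rather than failing.
#'
#' @param manifest A `run_manifest`.
#' @param path Output markdown path (defaults to `report.md` in the run
#'   directory).
#' @return The report text, invisibly; also written to `path`.
#' @export
report <- function(manifest, path = NULL) {
  outdir <- manifest$config$outdir
  path <- path %||% file.path(outdir, "report.md")
  lines <- c("# Paired antibody language model run report", "",
             sprintf("- Seed: %d", manifest$seed),
             sprintf("- Config hash: %s", manifest$config_hash),
             sprintf("- Unpaired/paired batch ratio: %s",
                     manifest$batch_ratio_unpaired_over_paired), "")
  tsv_section <- function(file, title) {
    f <- file.path(outdir, file)
    if (!file.exists(f))
      return(c(sprintf("## %s", title), "", "*Stage incomplete: missing*", ""))
    df <- utils::read.delim(f)
    c(sprintf("## %s", title), "",
      paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(r, collapse = " | ")), "")
  }
  lines <- c(lines,
             tsv_section("mutation_mask.tsv",
                         "Masked-mutation CEL: native vs germline-reverted partner"),
             tsv_section("region_cel.tsv", "Region-wise median CEL"),
             tsv_section("classifier_metrics.tsv", "Specificity classification"))
  att_f <- file.path(outdir, "attention_summary.json")
  lines <- c(lines, "## Cross-chain attention", "")
  if (file.exists(att_f)) {
    att <- jsonlite::read_json(att_f, simplifyVector = TRUE)
    lines <- c(lines, sprintf(
      "%.1f%% of cross-chain attention on CDRs (%.1f%% of positions); ratio %.2f",
      att$pct_attention_cdr, att$pct_positions_cdr, att$attention_ratio), "")
  } else lines <- c(lines, "*Stage incomplete: missing*", "")
  writeLines(lines, path)
  invisible(paste(lines, collapse = "\n"))
}
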
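# repertoire assembly: duplicates, nonproductives, pairing rules, motifs, IO

test_that("duplicate and nonproductive injection counts are exact", {
  db <- generate_germline_db(seed = 1)
  cfg <- repertoire_config(n_pairs = 100, duplicate_fraction = 0.1,
                           nonproductive_fraction = 0, seed = 3)
  reps <- build_repertoire(db, cfg)
  expect_length(reps, 100)
  key <- vapply(reps, function(p)
    paste(p$heavy$sequence, p$light$sequence), "")
  expect_equal(sum(duplicated(key)), 10)
  expect_equal(anyDuplicated(vapply(reps, `[[`, "", "record_id")), 0)

  cfg2 <- repertoire_config(n_pairs = 100, duplicate_fraction = 0,
                            nonproductive_fraction = 0.05, seed = 3)
  reps2 <- build_repertoire(db, cfg2)
  bad <- Filter(function(p) !p$heavy$productive || !p$light$productive, reps2)
  expect_length(bad, 5)
  for (p in bad)
    expect_true(grepl("\\*", p$heavy$sequence) || grepl("\\*", p$light$sequence))
  good <- Filter(function(p) p$heavy$productive && p$light$productive, reps2)
  for (p in good[1:10])
    expect_false(grepl("\\*", paste0(p$heavy$sequence, p$light$sequence)))
})

test_that("light V gene choice follows the pairing matrix", {
  db <- generate_germline_db(seed = 2)
  cfg <- repertoire_config(n_pairs = 10000, naive_fraction = 1,
                           duplicate_fraction = 0, nonproductive_fraction = 0,
                           pairing_noise = 0, seed = 4)
  reps <- build_repertoire(db, cfg)
  hv <- vapply(reps, function(p) p$heavy$v_id, "")
  lv <- vapply(reps, function(p) p$light$v_id, "")
  tab <- prop.table(table(hv, lv), margin = 1)
  expect_lt(max(abs(tab - db$pairing_matrix[rownames(tab), colnames(tab)])),
            0.03)
})

test_that("identical configs give byte-identical AIRR exports", {
  db <- generate_germline_db(seed = 5)
  cfg <- repertoire_config(n_pairs = 40, seed = 6)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_airr(build_repertoire(db, cfg), f1)
  write_airr(build_repertoire(db, cfg), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("AIRR export round-trips sequences, regions and mutations", {
  db <- generate_germline_db(seed = 7)
  reps <- build_repertoire(db, repertoire_config(n_pairs = 25, seed = 8))
  f <- tempfile(fileext = ".tsv")
  write_airr(reps, f)
  back <- read_airr(f)
  expect_length(back, length(reps))
  for (i in c(1, 10, 25)) {
    expect_identical(back[[i]]$record_id, reps[[i]]$record_id)
    for (side in c("heavy", "light")) {
      expect_identical(back[[i]][[side]]$sequence, reps[[i]][[side]]$sequence)
      expect_identical(back[[i]][[side]]$germline_sequence,
                       reps[[i]][[side]]$germline_sequence)
      expect_identical(back[[i]][[side]]$region_map,
                       reps[[i]][[side]]$region_map)
      expect_identical(back[[i]][[side]]$mutation_positions,
                       reps[[i]][[side]]$mutation_positions)
    }
  }
})

test_that("FASTA export writes one annotated record per chain", {
  db <- generate_germline_db(seed = 9)
  reps <- build_repertoire(db, repertoire_config(n_pairs = 5, seed = 9))
  f <- tempfile(fileext = ".fasta")
  write_fasta(reps, f)
  lines <- readLines(f)
  headers <- grep("^>", lines, value = TRUE)
  expect_length(headers, 10)
  expect_match(headers[1], "^>P\\d+\\|heavy\\|HV\\d+\\|HJ\\d+\\|\\d+\\|none$")
})

test_that("class motifs are planted in both CDR3s before mutation", {
  db <- generate_germline_db(seed = 10)
  cfg <- repertoire_config(
    n_pairs = 60, naive_fraction = 1, duplicate_fraction = 0,
    nonproductive_fraction = 0,
    motif_spec = list(classA = list(heavy = "WGGW", light = "WS"),
                      classB = list(heavy = "FPPF", light = "FT")),
    seed = 11)
  reps <- build_repertoire(db, cfg)
  labs <- vapply(reps, `[[`, "", "specificity")
  expect_setequal(unique(labs), c("classA", "classB"))
  for (p in reps[labs == "classA"][1:5]) {
    cdr3 <- which(p$heavy$region_map == "CDR3")
    expect_identical(substr(p$heavy$sequence, cdr3[1], cdr3[1] + 3), "WGGW")
    expect_identical(substr(p$heavy$germline_sequence, cdr3[1], cdr3[1] + 3),
                     "WGGW")
    lcdr3 <- which(p$light$region_map == "CDR3")
    expect_identical(substr(p$light$sequence, lcdr3[1], lcdr3[1] + 1),
                     substr("WS", 1, min(2, length(lcdr3))))
  }
})

test_that("config JSON round-trips", {
  cfg <- repertoire_config(n_pairs = 10, shm_rate = 4,
                           motif_spec = list(a = list(heavy = "WW",
                                                      light = "YY")),
                           seed = 42)
  f <- tempfile(fileext = ".json")
  write_repertoire_config(cfg, f)
  back <- read_repertoire_config(f)
  expect_equal(back$n_pairs, cfg$n_pairs)
  expect_equal(back$shm_rate, cfg$shm_rate)
  expect_equal(back$motif_spec, cfg$motif_spec)
  expect_equal(unname(back$class_fractions), unname(cfg$class_fractions))
})
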
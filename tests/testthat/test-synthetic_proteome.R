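test_that("generator_spec validates its inputs", {
  expect_error(generator_spec(n_per_class = c(BANANA = 5L)), "labels")
  expect_error(generator_spec(background_n = -1L), "non-negative")
  expect_error(generator_spec(ambiguity = 1.5), "ambiguity")
  s <- generator_spec()
  expect_equal(sum(s$sp_mix), 1)
  expect_equal(unname(s$n_per_class["CLASSICAL"]), 10L)
})

test_that("generation is byte-identical for the same seed", {
  spec <- generator_spec(seed = 21,
                         n_per_class = c(CLASSICAL = 2L, PERK = 2L),
                         background_n = 3L)
  a <- generate_proteome(spec)
  b <- generate_proteome(spec)
  expect_identical(a, b)
  fa <- tempfile(); fb <- tempfile()
  write_proteome(a$records, fa)
  write_proteome(b$records, fb)
  expect_identical(readLines(fa), readLines(fb))
  # different seed differs
  c2 <- generate_proteome(generator_spec(
    seed = 22, n_per_class = c(CLASSICAL = 2L, PERK = 2L),
    background_n = 3L))
  expect_false(identical(a$records$sequence, c2$records$sequence))
})

test_that("background-only proteomes contain no candidates", {
  spec <- generator_spec(seed = 23, n_per_class = c(CLASSICAL = 0L),
                         background_n = 30L)
  sim <- generate_proteome(spec)
  expect_equal(nrow(sim$records), 30L)
  tab <- classify_proteome(sim$records)
  expect_true(all(tab$label == "NON_EXT"))
})

test_that("planted motif coordinates are re-detected exactly", {
  sim <- small_sim()
  for (i in seq_len(nrow(sim$records))) {
    s <- sim$records$sequence[i]
    tr <- sim$truth[i, ]
    det <- scan_sp_runs(s)
    want <- parse_truth_coords(tr$sp_coords)
    expect_equal(det$start, unname(want[, "start"]), label = tr$record_id)
    expect_equal(det$end, unname(want[, "end"]), label = tr$record_id)
    dety <- scan_yxy(s)
    wanty <- parse_truth_coords(tr$yxy_coords)
    expect_equal(dety$start, unname(wanty[, "start"]), label = tr$record_id)
  }
})

test_that("generated FASTA round-trips through sequence_io unchanged", {
  sim <- small_sim()
  fa <- tempfile(fileext = ".fasta")
  write_proteome(sim$records, fa)
  back <- read_proteome(fa)
  expect_equal(back$id, sim$records$id)
  expect_equal(back$sequence, sim$records$sequence)
})

test_that("planted signal peptides are found and planted negatives rejected", {
  sim <- small_sim()
  truth <- sim$truth
  has_sp <- grepl("SIGNAL_PEPTIDE", truth$region_coords)
  calls <- lapply(sim$records$sequence, predict_signal_peptide)
  got <- vapply(calls, nrow, 0L) > 0
  # planted positives: recall (every planted SP found at its coordinates)
  expect_true(all(got[has_sp]))
  for (i in which(has_sp)) {
    m <- regmatches(truth$region_coords[i],
                    regexpr("SIGNAL_PEPTIDE:[0-9]+-[0-9]+",
                            truth$region_coords[i]))
    want_end <- as.integer(sub(".*-", "", m))
    expect_equal(calls[[i]]$end, want_end, label = truth$record_id[i])
  }
  # background proteins are constructed signal-peptide negatives
  bg <- truth$planted_label == "NON_EXT"
  expect_true(all(!got[bg]))
})

test_that("signal-peptide heuristic reaches 95% recall and specificity at scale", {
  spec <- generator_spec(seed = 31,
                         n_per_class = c(CLASSICAL = 40L),
                         background_n = 40L)
  sim <- generate_proteome(spec)
  got <- vapply(sim$records$sequence,
                function(s) nrow(predict_signal_peptide(s)) > 0, TRUE)
  pos <- sim$truth$planted_label == "CLASSICAL"
  recall <- mean(got[pos])
  specificity <- mean(!got[!pos])
  expect_gte(recall, 0.95)
  expect_gte(specificity, 0.95)
})

test_that("ambiguity only creates the two allowed confusion pairs", {
  allowed <- c("SHORT->CLASSICAL", "CLASSICAL->SHORT",
               "OTHER_CHIMERIC->POTENTIAL", "POTENTIAL->OTHER_CHIMERIC")
  for (seed in c(41, 42)) {
    spec <- generator_spec(
      seed = seed, ambiguity = 1,
      n_per_class = c(SHORT = 6L, OTHER_CHIMERIC = 6L, CLASSICAL = 3L,
                      POTENTIAL = 3L),
      background_n = 2L)
    sim <- generate_proteome(spec)
    tab <- classify_proteome(sim$records)
    m <- merge(tab, sim$truth, by.x = "id", by.y = "record_id")
    wrong <- m[m$label != m$planted_label, ]
    if (nrow(wrong) > 0) {
      pairs <- paste0(wrong$planted_label, "->", wrong$label)
      expect_true(all(pairs %in% allowed), label = paste(pairs, collapse = ","))
    }
  }
  succeed()
})
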
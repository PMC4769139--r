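test_that("amino_acid_composition computes exact fractions", {
  c1 <- amino_acid_composition("PPPP")
  expect_equal(unname(c1$fractions["P"]), 1)
  expect_equal(c1$hrgp6_fraction, 1)
  c2 <- amino_acid_composition("PAVSGT")
  expect_equal(c2$hrgp6_fraction, 1)
  expect_equal(c2$past_fraction, 4 / 6)
  expect_equal(amino_acid_composition("WWWW")$hrgp6_fraction, 0)
  # X in denominator, in no class
  c3 <- amino_acid_composition("PX")
  expect_equal(c3$hrgp6_fraction, 0.5)
  expect_equal(sum(c3$fractions), 1, tolerance = 1e-9)
  expect_error(amino_acid_composition(""), "empty")
})

test_that("find_hrgp_regions basics and validation", {
  r <- find_hrgp_regions(strrep("P", 100))
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(0L, 100L))
  expect_equal(r$score, 1)
  expect_equal(nrow(find_hrgp_regions(strrep("W", 100))), 0L)
  # shorter than window: whole-sequence window
  expect_equal(nrow(find_hrgp_regions(strrep("P", 20))), 1L)
  expect_error(find_hrgp_regions("PPPP", window = 5), "window")
  expect_error(find_hrgp_regions(strrep("P", 60), threshold = 0), "threshold")
  expect_error(find_hrgp_regions(strrep("P", 60), threshold = 1.2),
               "threshold")
})

test_that("find_hrgp_regions covers exactly the oracle window union", {
  set.seed(404)
  block <- paste(rep("SPPPPA", 9), collapse = "")
  cases <- c(
    paste0(strrep("W", 50), block, strrep("W", 50)),
    vapply(1:40, function(i) {
      random_aa(sample(60:300, 1),
                alphabet = c("P", "A", "V", "S", "G", "T", "W", "K", "E"))
    }, ""))
  for (s in cases) {
    reg <- find_hrgp_regions(s)
    mask <- logical(nchar(s))
    if (nrow(reg) > 0) {
      for (i in seq_len(nrow(reg))) mask[(reg$start[i] + 1):reg$end[i]] <- TRUE
    }
    expect_equal(mask, oracle_hrgp_mask(s))
    # merged regions pairwise disjoint
    if (nrow(reg) > 1) {
      expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
    }
  }
})

test_that("find_hrgp_regions is monotone in threshold", {
  set.seed(405)
  covered <- function(s, thr) {
    r <- find_hrgp_regions(s, threshold = thr)
    if (nrow(r) == 0) 0L else sum(r$end - r$start)
  }
  for (k in 1:20) {
    s <- random_aa(200, alphabet = c("P", "A", "S", "W", "K", "L"))
    lens <- vapply(c(0.3, 0.5, 0.7, 0.9), function(t) covered(s, t), 0L)
    expect_true(all(diff(lens) <= 0))
  }
})

test_that("signal-peptide heuristic accepts the canonical construction", {
  pos <- paste0("MKTLLVLALLAVALA", strrep("SPPPA", 20))
  call <- predict_signal_peptide(pos)
  expect_equal(nrow(call), 1L)
  expect_equal(c(call$start, call$end), c(0L, 15L))
  expect_true(call$score > 0 && call$score <= 1)
  # no h-region
  expect_equal(nrow(predict_signal_peptide(paste0("MD", strrep("D", 40)))), 0L)
  # length guard: absent, not an error
  expect_equal(nrow(predict_signal_peptide("MKTLLVLALL")), 0L)
  # must start with Met
  expect_equal(nrow(predict_signal_peptide(
    paste0("KKTLLVLALLAVALA", strrep("SPPPA", 20)))), 0L)
})

test_that("transmembrane prediction finds hydrophobic segments", {
  s <- paste0(strrep("D", 30), strrep("I", 30), strrep("D", 30))
  tm <- predict_transmembrane(s)
  expect_equal(nrow(tm), 1L)
  expect_true(tm$start <= 30 && tm$end >= 60)
  expect_equal(nrow(predict_transmembrane(strrep("D", 80))), 0L)
  expect_equal(nrow(predict_transmembrane("DDD")), 0L)  # shorter than window
  # two separated leucine blocks give exactly two regions
  s2 <- paste0(strrep("E", 20), strrep("L", 25), strrep("D", 40),
               strrep("L", 25), strrep("E", 20))
  expect_equal(nrow(predict_transmembrane(s2)), 2L)
})

test_that("transmembrane windows match the brute-force hydropathy oracle", {
  set.seed(406)
  for (k in 1:60) {
    s <- random_aa(sample(40:250, 1))
    tm <- predict_transmembrane(s)
    mask <- logical(nchar(s))
    if (nrow(tm) > 0) {
      for (i in seq_len(nrow(tm))) mask[(tm$start[i] + 1):tm$end[i]] <- TRUE
    }
    expect_equal(mask, oracle_tm_mask(s))
  }
})

test_that("TM regions overlapping a signal peptide are suppressed", {
  s <- paste0("MKTLLVLALLAVALA", strrep("SPPPA", 30))
  sp <- predict_signal_peptide(s)
  expect_equal(nrow(sp), 1L)
  tm_plain <- predict_transmembrane(s)
  tm_masked <- predict_transmembrane(s, exclude = sp)
  expect_true(nrow(tm_plain) >= 1)  # the h-region looks like a TM
  expect_equal(nrow(tm_masked), 0L)
})

test_that("GPI omega-site heuristic", {
  body <- paste0("MKTLLVLALLAVALA", strrep("SPPPA", 30))
  pos <- paste0(body, "SASA", strrep("L", 10))
  call <- predict_gpi_omega(pos)
  expect_equal(nrow(call), 1L)
  expect_equal(call$end - call$start, 1L)
  expect_equal(nrow(predict_gpi_omega(paste0(body, strrep("E", 10)))), 0L)
  # tail too short
  expect_equal(nrow(predict_gpi_omega(paste0(body, "SASA", "LLLL"))), 0L)
  expect_equal(nrow(predict_gpi_omega("SHORTSEQ")), 0L)
})

test_that("external region adapter parses, validates and overrides", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("record_id\tregion\tstart\tend\tscore",
               "p1\tSIGNAL_PEPTIDE\t0\t22\t0.98"), tsv)
  ext <- load_external_regions(tsv)
  expect_equal(nrow(ext), 1L)
  expect_equal(ext$source, "EXTERNAL")
  expect_equal(ext$end, 22L)

  writeLines("record_id\tregion\tstart\tend\tscore", tsv)
  expect_equal(nrow(load_external_regions(tsv)), 0L)

  writeLines(c("record_id\tregion\tstart\tend\tscore",
               "p1\tSIGNAL_PEPTIDE\t30\t10\t0.9"), tsv)
  expect_error(load_external_regions(tsv), "line 2")
  writeLines(c("record_id\tregion\tstart\tend\tscore",
               "p1\tBANANA\t0\t10\t0.9"), tsv)
  expect_error(load_external_regions(tsv), "BANANA")

  # external wins over heuristic of the same type for the same record
  heur <- predict_signal_peptide(
    paste0("MKTLLVLALLAVALA", strrep("SPPPA", 20)), record_id = "p1")
  writeLines(c("record_id\tregion\tstart\tend\tscore",
               "p1\tSIGNAL_PEPTIDE\t0\t22\t0.98"), tsv)
  merged <- extscan:::merge_region_calls(heur, load_external_regions(tsv))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$source, "EXTERNAL")
  expect_equal(merged$end, 22L)
})
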
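# Rule-level tests build evidence through the real pipeline on constructed
# sequences, so they exercise classify_protein exactly as classify_proteome
# does.

classify_seq <- function(seq, id = "q", config = classifier_config(),
                         refs = load_reference_domains()) {
  rec <- list(id = id, sequence = seq, length = nchar(seq))
  prof <- motif_profile(seq, id)
  reg <- profile_regions(seq, id, config$hrgp_window, config$hrgp_threshold,
                         config$tm_window, config$tm_threshold)
  hom <- if (prof$sp_total >= config$min_runs) {
    assign_domain_families(seq, refs, config$min_normalized, id)
  } else {
    extscan:::empty_homology()
  }
  classify_protein(rec, prof, reg, hom, config)
}

sp_block <- function(n) paste(rep("SPPPPAT", n), collapse = "")

test_that("constructed examples fire the intended rules", {
  refs <- load_reference_domains()
  # classical: signal peptide + 20 SP4 repeats with YXY, no homology
  classical <- paste0("MKTLLVLALLAVALA",
                      paste(rep("SPPPPATYVYGT", 20), collapse = ""))
  c1 <- classify_seq(classical, refs = refs)
  expect_equal(c1$label, "CLASSICAL")
  expect_equal(utils::tail(c1$rule_trace, 1), "R6")
  expect_true(c1$evidence$signal_peptide)

  # short: length 150, HRGP region, 3 SP3 runs
  short <- paste0("MKTLLVLALLAVALA", paste(rep("SPPPAT", 3), collapse = ""),
                  strrep("AVGT", 29))
  expect_equal(nchar(short), 149L)
  c2 <- classify_seq(short, refs = refs)
  expect_equal(c2$label, "SHORT")

  # long chimeric: one SP block plus a long non-HRGP remainder
  long <- paste0("MK", sp_block(30), "L", strrep("LEKDRQNFIW", 230))
  expect_gt(nchar(long), 2000L)
  c3 <- classify_seq(long, refs = refs)
  expect_equal(c3$label, "LONG_CHIMERIC")
  expect_equal(utils::tail(c3$rule_trace, 1), "R1")

  # potential: 2 SPPP in an HRGP-poor, signal-peptide-free protein
  pot <- paste0("MDE", strrep("LEKDRQNFIW", 10), "TASPPPAT",
                strrep("LEKDRQNFIW", 10), "TASPPPAT",
                strrep("LEKDRQNFIW", 10))
  c4 <- classify_seq(pot, refs = refs)
  expect_equal(c4$label, "POTENTIAL")
  expect_equal(utils::tail(c4$rule_trace, 1), "R8")

  # LRX: signal peptide + LRR exemplar copy + C-terminal SP block
  lrr <- refs$sequence[refs$family == "LRR"]
  lrx <- paste0("MKTLLVLALLAVALA", lrr, "LEKDRQ", sp_block(12))
  c5 <- classify_seq(lrx, refs = refs)
  expect_equal(c5$label, "LRX")
  expect_equal(utils::tail(c5$rule_trace, 1), "R2")

  # PERK: N-terminal SP block, TM stretch, kinase copy
  kin <- refs$sequence[refs$family == "KINASE"]
  perk <- paste0("MK", sp_block(12), strrep("L", 25), kin, "LEKDRQ")
  c6 <- classify_seq(perk, refs = refs)
  expect_equal(c6$label, "PERK")

  # FH: FH2 copy + scattered SP blocks
  fh2 <- refs$sequence[refs$family == "FH2"]
  fh <- paste0("MDE", fh2, "LEKDRQ", sp_block(3), "LEKDRQ", sp_block(3))
  c7 <- classify_seq(fh, refs = refs)
  expect_equal(c7$label, "FH_EXT")

  # non-candidate
  c8 <- classify_seq(strrep("MKLE", 40), refs = refs)
  expect_equal(c8$label, "NON_EXT")
  expect_equal(c8$rule_trace, "R0")
})

test_that("SHORT eligibility flips exactly at the configured length bound", {
  refs <- load_reference_domains()
  # 3 SP runs (< classical_min_sp) + HRGP padding; foreign run is tiny, so
  # the protein is SHORT below the bound and POTENTIAL at it
  core <- paste0("MKT", paste(rep("SPPPAT", 3), collapse = ""))
  for (target in c(199L, 200L)) {
    seq <- paste0(core, strrep("A", target - nchar(core)))
    expect_equal(nchar(seq), target)
    got <- classify_seq(seq, refs = refs)$label
    expect_equal(got, if (target < 200L) "SHORT" else "POTENTIAL",
                 label = paste("length", target))
  }
  # the bound itself is configurable
  seq199 <- paste0(core, strrep("A", 199L - nchar(core)))
  cfg <- classifier_config(short_max_len = 199L)
  expect_equal(classify_seq(seq199, config = cfg, refs = refs)$label,
               "POTENTIAL")
})

test_that("LONG_CHIMERIC eligibility flips exactly at the length bound", {
  refs <- load_reference_domains()
  core <- paste0("MK", sp_block(25), "L")
  filler <- "LEKDRQNFIW"
  for (target in c(2000L, 2001L)) {
    pad <- target - nchar(core)
    seq <- paste0(core, strrep(filler, ceiling(pad / 10)))
    seq <- substr(seq, 1, target)
    expect_equal(nchar(seq), target)
    got <- classify_seq(seq, refs = refs)$label
    # > 2000 aa: long chimeric; at exactly 2000 the same architecture is an
    # ordinary (other) chimeric EXT
    expect_equal(got, if (target > 2000L) "LONG_CHIMERIC" else
      "OTHER_CHIMERIC", label = paste("length", target))
  }
})

test_that("classify_protein validates evidence identity", {
  prof <- motif_profile("SPPPATSPPPAT", "other_id")
  rec <- list(id = "q", sequence = "SPPPATSPPPAT", length = 12L)
  expect_error(
    classify_protein(rec, prof, extscan:::empty_regions(),
                     extscan:::empty_homology()),
    "mismatch")
})

test_that("classify_proteome is a deterministic partition matching input order", {
  sim <- small_sim()
  refs <- load_reference_domains()
  t1 <- classify_proteome(sim$records, references = refs)
  t2 <- classify_proteome(sim$records, references = refs)
  expect_identical(t1, t2)
  expect_equal(t1$id, sim$records$id)
  expect_true(all(t1$label %in% c("CLASSICAL", "SHORT", "LRX", "PERK",
                                  "FH_EXT", "LONG_CHIMERIC",
                                  "OTHER_CHIMERIC", "POTENTIAL", "NON_EXT")))
  expect_true(all(nzchar(t1$rule_trace)))
  cz <- class_census(t1)
  expect_equal(sum(cz$counts), nrow(sim$records))
})

test_that("empty and trivial proteomes classify cleanly", {
  refs <- load_reference_domains()
  empty <- extscan:::read_proteome_empty()
  out <- classify_proteome(empty, references = refs)
  expect_equal(nrow(out), 0L)
  one <- data.frame(id = "p", description = "", sequence = strrep("MKLE", 30),
                    length = 120L, internal_stop = FALSE,
                    stringsAsFactors = FALSE)
  out1 <- classify_proteome(one, references = refs)
  expect_equal(out1$label, "NON_EXT")
})

test_that("raising classical_min_coverage never increases the CLASSICAL count", {
  sim <- small_sim()
  refs <- load_reference_domains()
  n_classical <- vapply(c(0.4, 0.5, 0.7, 0.9, 0.99), function(cov) {
    tab <- classify_proteome(
      sim$records, classifier_config(classical_min_coverage = cov),
      references = refs)
    sum(tab$label == "CLASSICAL")
  }, 0L)
  expect_true(all(diff(n_classical) <= 0))
})
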
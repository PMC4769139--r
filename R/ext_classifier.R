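# Rule-based EXT classification. Evidence from motif_engine,
# region_profiler and homology_search is combined by a fixed, ordered rule
# list; the first matching rule wins and the evaluation order is part of
# the contract (an LRX under 200 aa must not become SHORT, so architecture
# rules precede length rules).

#' Classifier configuration
#'
#' All thresholds the classifier and its region/homology passes use; no
#' hidden constants live in the rule code.
#'
#' @param short_max_len Short-EXT length bound: SHORT requires
#'   `length < short_max_len` (default 200 aa).
#' @param long_min_len Long-chimeric bound: requires `length > long_min_len`
#'   (default 2000 aa).
#' @param classical_min_coverage Minimum fraction of the protein covered by
#'   HRGP domains for CLASSICAL (default 0.5; the "repeats throughout"
#'   notion is qualitative, so this stand-in is config-exposed).
#' @param classical_min_sp Minimum number of SP_n runs for CLASSICAL
#'   (default 4).
#' @param perk_nterm_bias PERK fallback: minimum fraction of SP runs in the
#'   N-terminal half when no confident TM call separates the EXT and kinase
#'   parts (default 0.7).
#' @param min_normalized Homology normalized-score threshold (default 0.25).
#' @param foreign_min_len Minimum contiguous non-HRGP, non-signal-peptide
#'   stretch counted as a "foreign" segment for OTHER_CHIMERIC (default
#'   150 aa).
#' @param hrgp_window,hrgp_threshold,tm_window,tm_threshold Pass-throughs
#'   to [find_hrgp_regions()] and [predict_transmembrane()].
#' @param min_runs Candidate screen threshold (default 2 SP_n runs).
#' @return List of class `ext_classifier_config`.
#' @export
classifier_config <- function(short_max_len = 200L, long_min_len = 2000L,
                              classical_min_coverage = 0.5,
                              classical_min_sp = 4L,
                              perk_nterm_bias = 0.7,
                              min_normalized = 0.25,
                              foreign_min_len = 150L,
                              hrgp_window = 50L, hrgp_threshold = 0.6,
                              tm_window = 19L, tm_threshold = 1.6,
                              min_runs = 2L) {
  cfg <- list(short_max_len = as.integer(short_max_len),
              long_min_len = as.integer(long_min_len),
              classical_min_coverage = classical_min_coverage,
              classical_min_sp = as.integer(classical_min_sp),
              perk_nterm_bias = perk_nterm_bias,
              min_normalized = min_normalized,
              foreign_min_len = as.integer(foreign_min_len),
              hrgp_window = as.integer(hrgp_window),
              hrgp_threshold = hrgp_threshold,
              tm_window = as.integer(tm_window),
              tm_threshold = tm_threshold,
              min_runs = as.integer(min_runs))
  bad <- vapply(cfg, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                logical(1))
  if (any(bad)) stop("all thresholds must be positive scalars: ",
                     paste(names(cfg)[bad], collapse = ", "), call. = FALSE)
  if (cfg$short_max_len >= cfg$long_min_len) {
    stop("short_max_len must be < long_min_len", call. = FALSE)
  }
  structure(cfg, class = "ext_classifier_config")
}

# hrgp coverage = total HRGP_DOMAIN length / protein length
hrgp_coverage_of <- function(regions, len) {
  h <- regions[regions$region == "HRGP_DOMAIN", , drop = FALSE]
  if (nrow(h) == 0) return(0)
  sum(h$end - h$start) / len
}

# longest contiguous stretch covered by neither HRGP domains nor the signal
# peptide ("foreign" segment length)
max_foreign_run <- function(regions, len) {
  cov <- regions[regions$region %in% c("HRGP_DOMAIN", "SIGNAL_PEPTIDE"), ,
                 drop = FALSE]
  if (nrow(cov) == 0) return(len)
  ord <- order(cov$start)
  gaps <- integer(0)
  pos <- 0L
  for (i in ord) {
    if (cov$start[i] > pos) gaps <- c(gaps, cov$start[i] - pos)
    pos <- max(pos, cov$end[i])
  }
  if (pos < len) gaps <- c(gaps, len - pos)
  if (length(gaps) == 0) 0L else max(gaps)
}

best_family_hit <- function(homology, family) {
  h <- homology[homology$family == family, , drop = FALSE]
  if (nrow(h) == 0) NULL else h[1, ]
}

#' Classify a single protein from precomputed evidence
#'
#' Applies the fixed rule order (first match wins):
#' \describe{
#'   \item{R0}{fewer than `min_runs` SP_n runs: NON_EXT.}
#'   \item{R1}{length > `long_min_len` with chimeric character (a non-EXT
#'     domain hit, or HRGP coverage below `classical_min_coverage`):
#'     LONG_CHIMERIC. Pure repeat giants stay eligible for CLASSICAL.}
#'   \item{R2}{LRR homology located before the SP-motif span: LRX.}
#'   \item{R3}{kinase homology after the SP-motif span, with a TM segment
#'     between them or N-terminal SP bias >= `perk_nterm_bias`: PERK.}
#'   \item{R4}{FH2 homology: FH_EXT.}
#'   \item{R5}{length < `short_max_len` with an HRGP domain: SHORT.}
#'   \item{R6}{HRGP coverage >= `classical_min_coverage`, SP runs >=
#'     `classical_min_sp`, no non-EXT domain hit: CLASSICAL. A signal
#'     peptide is recorded as evidence but not required (classical EXTs
#'     without one are known).}
#'   \item{R7}{HRGP domain plus foreign material (non-EXT domain hit, TM
#'     outside HRGP, or a contiguous non-HRGP stretch >=
#'     `foreign_min_len`): OTHER_CHIMERIC.}
#'   \item{R8}{otherwise: POTENTIAL.}
#' }
#'
#' @param record One-row `ext_proteome` slice (or list with `id`,
#'   `sequence`, `length`).
#' @param profile `ext_motif_profile` for the record.
#' @param regions Region data frame (heuristics merged with any external
#'   calls) for the record.
#' @param homology Homology-hit data frame for the record.
#' @param config [classifier_config()].
#' @return List of class `ext_classification`: `record_id`, `label`,
#'   `evidence` (named list), `rule_trace` (rules evaluated, the fired one
#'   last).
#' @export
classify_protein <- function(record, profile, regions, homology,
                             config = classifier_config()) {
  id <- record$id
  if (profile$record_id != id ||
      (nrow(regions) > 0 && any(regions$record_id != id)) ||
      (nrow(homology) > 0 && any(homology$record_id != id))) {
    stop("evidence record_id mismatch for '", id, "'", call. = FALSE)
  }
  len <- record$length
  hrgp <- regions[regions$region == "HRGP_DOMAIN", , drop = FALSE]
  tm <- regions[regions$region == "TM", , drop = FALSE]
  sp_call <- regions[regions$region == "SIGNAL_PEPTIDE", , drop = FALSE]
  gpi <- regions[regions$region == "GPI_OMEGA", , drop = FALSE]
  coverage <- hrgp_coverage_of(regions, len)
  lrr <- best_family_hit(homology, "LRR")
  kin <- best_family_hit(homology, "KINASE")
  fh2 <- best_family_hit(homology, "FH2")
  nonext_hit <- any(homology$family %in% NONEXT_FAMILIES)
  foreign_run <- max_foreign_run(regions, len)
  tm_outside_hrgp <- nrow(tm) > 0 && (nrow(hrgp) == 0 ||
    any(vapply(seq_len(nrow(tm)), function(i) {
      !any(tm$start[i] < hrgp$end & hrgp$start < tm$end)
    }, logical(1))))

  evidence <- list(
    candidate = profile$sp_total >= config$min_runs,
    length = len, sp_total = profile$sp_total,
    sp3 = unname(profile$counts["SP3"]), sp4 = unname(profile$counts["SP4"]),
    sp5plus = unname(profile$counts["SP5PLUS"]), yxy = profile$yxy_count,
    signal_peptide = nrow(sp_call) > 0, gpi = nrow(gpi) > 0,
    tm_count = nrow(tm), hrgp_coverage = coverage,
    hrgp_present = nrow(hrgp) > 0,
    sp_position_bias = profile$sp_position_bias,
    lrr_score = if (is.null(lrr)) 0 else lrr$normalized_score,
    kinase_score = if (is.null(kin)) 0 else kin$normalized_score,
    fh2_score = if (is.null(fh2)) 0 else fh2$normalized_score,
    foreign_run = foreign_run)

  trace <- character(0)
  fire <- function(rule, label) {
    structure(list(record_id = id, label = label,
                   evidence = evidence, rule_trace = c(trace, rule)),
              class = "ext_classification")
  }

  trace_step <- function(rule) trace <<- c(trace, rule)

  if (!evidence$candidate) return(fire("R0", "NON_EXT"))
  trace_step("R0")

  span <- profile$sp_span
  if (len > config$long_min_len &&
      (nonext_hit || coverage < config$classical_min_coverage)) {
    return(fire("R1", "LONG_CHIMERIC"))
  }
  trace_step("R1")

  if (!is.null(lrr) && lrr$q_end <= span[1]) {
    return(fire("R2", "LRX"))
  }
  trace_step("R2")

  if (!is.null(kin) && kin$q_start >= span[2]) {
    tm_between <- nrow(tm) > 0 &&
      any((tm$start + tm$end) / 2 >= span[2] &
          (tm$start + tm$end) / 2 <= kin$q_start)
    if (tm_between ||
        (!is.na(profile$sp_position_bias) &&
         profile$sp_position_bias >= config$perk_nterm_bias)) {
      return(fire("R3", "PERK"))
    }
  }
  trace_step("R3")

  if (!is.null(fh2)) return(fire("R4", "FH_EXT"))
  trace_step("R4")

  if (len < config$short_max_len && nrow(hrgp) > 0) {
    return(fire("R5", "SHORT"))
  }
  trace_step("R5")

  if (coverage >= config$classical_min_coverage &&
      profile$sp_total >= config$classical_min_sp && !nonext_hit) {
    return(fire("R6", "CLASSICAL"))
  }
  trace_step("R6")

  if (nrow(hrgp) > 0 &&
      (nonext_hit || tm_outside_hrgp ||
       foreign_run >= config$foreign_min_len)) {
    return(fire("R7", "OTHER_CHIMERIC"))
  }
  trace_step("R7")

  fire("R8", "POTENTIAL")
}

#' Classify every protein in a proteome
#'
#' Orchestrates motif scanning, region heuristics (with optional external
#' overrides) and homology search per record, then applies
#' [classify_protein()]. Non-candidates (fewer than `min_runs` SP_n runs)
#' short-circuit to NON_EXT without region or homology work. Fully
#' deterministic given the inputs and config; output order matches input.
#'
#' @param records `ext_proteome` data frame.
#' @param config [classifier_config()].
#' @param references Reference bundle from [load_reference_domains()]
#'   (default: the bundled synthetic exemplars).
#' @param external_regions Optional region data frame from
#'   [load_external_regions()]; external calls override heuristics.
#' @return Data frame of class `ext_classtable`, one row per record, with
#'   the documented TSV columns (id, label, length, sp3, sp4, sp5plus, yxy,
#'   signal_peptide, gpi, tm_count, hrgp_coverage, lrr_score, kinase_score,
#'   fh2_score, rule_trace) plus sp_total.
#' @export
classify_proteome <- function(records, config = classifier_config(),
                              references = NULL, external_regions = NULL) {
  if (is.null(references)) references <- load_reference_domains()
  if (nrow(records) == 0) {
    out <- classification_row(NULL)
    class(out) <- c("ext_classtable", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    prof <- motif_profile(rec$sequence, rec$id)
    if (prof$sp_total < config$min_runs) {
      cl <- classify_protein(rec, prof, empty_regions(), empty_homology(),
                             config)
    } else {
      reg <- profile_regions(rec$sequence, rec$id,
                             config$hrgp_window, config$hrgp_threshold,
                             config$tm_window, config$tm_threshold)
      if (!is.null(external_regions)) {
        ext <- external_regions[external_regions$record_id == rec$id, ,
                                drop = FALSE]
        reg <- merge_region_calls(reg, ext)
      }
      hom <- assign_domain_families(rec$sequence, references,
                                    config$min_normalized, rec$id)
      cl <- classify_protein(rec, prof, reg, hom, config)
    }
    classification_row(cl)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- classification_row(NULL)[0, ]
  class(out) <- c("ext_classtable", "data.frame")
  out
}

classification_row <- function(cl) {
  if (is.null(cl)) {
    ev <- list(length = 0L, sp3 = 0L, sp4 = 0L, sp5plus = 0L,
               sp_total = 0L, yxy = 0L, signal_peptide = FALSE, gpi = FALSE,
               tm_count = 0L, hrgp_coverage = 0, lrr_score = 0,
               kinase_score = 0, fh2_score = 0)
    cl <- list(record_id = character(0), label = character(0),
               evidence = ev, rule_trace = character(0))
    return(data.frame(id = character(0), label = character(0),
                      length = integer(0), sp3 = integer(0), sp4 = integer(0),
                      sp5plus = integer(0), sp_total = integer(0),
                      yxy = integer(0), signal_peptide = logical(0),
                      gpi = logical(0), tm_count = integer(0),
                      hrgp_coverage = numeric(0), lrr_score = numeric(0),
                      kinase_score = numeric(0), fh2_score = numeric(0),
                      rule_trace = character(0), stringsAsFactors = FALSE))
  }
  ev <- cl$evidence
  data.frame(id = cl$record_id, label = cl$label, length = ev$length,
             sp3 = ev$sp3, sp4 = ev$sp4, sp5plus = ev$sp5plus,
             sp_total = ev$sp_total, yxy = ev$yxy,
             signal_peptide = ev$signal_peptide, gpi = ev$gpi,
             tm_count = ev$tm_count,
             hrgp_coverage = round(ev$hrgp_coverage, 6),
             lrr_score = round(ev$lrr_score, 6),
             kinase_score = round(ev$kinase_score, 6),
             fh2_score = round(ev$fh2_score, 6),
             rule_trace = paste(cl$rule_trace, collapse = ","),
             stringsAsFactors = FALSE)
}
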
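# Structural region heuristics: composition-biased HRGP domains, signal
# peptides, transmembrane segments, GPI omega-sites, and an adapter for
# external predictor output. Coordinates 0-based half-open.

empty_regions <- function() {
  data.frame(record_id = character(0), region = character(0),
             start = integer(0), end = integer(0), score = numeric(0),
             source = character(0), stringsAsFactors = FALSE)
}

region_row <- function(record_id, region, start, end, score,
                       source = "HEURISTIC") {
  data.frame(record_id = record_id, region = region,
             start = as.integer(start), end = as.integer(end),
             score = score, source = source, stringsAsFactors = FALSE)
}

#' Amino-acid composition of a sequence
#'
#' Exact residue fractions, plus the two pooled bias fractions the EXT
#' screen uses: `past_fraction` over \{P,A,S,T\} and `hrgp6_fraction` over
#' \{P,A,V,S,G,T\}. `X` counts in the denominator but in no named class.
#'
#' @param sequence Non-empty amino-acid string.
#' @return List of class `ext_composition`: `fractions` (named, sums to 1),
#'   `past_fraction`, `hrgp6_fraction`, `length`.
#' @export
amino_acid_composition <- function(sequence) {
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  tab <- table(factor(ch, levels = unique(c(AA20, "X", "*", unique(ch)))))
  fractions <- as.numeric(tab) / n
  names(fractions) <- names(tab)
  structure(list(fractions = fractions,
                 past_fraction = sum(fractions[names(fractions) %in% PAST4]),
                 hrgp6_fraction = sum(fractions[names(fractions) %in% HRGP6]),
                 length = n),
            class = "ext_composition")
}

#' Find composition-biased HRGP domains
#'
#' Slides a window (step 1) over the sequence; windows whose combined
#' P/A/V/S/G/T fraction reaches `threshold` are merged into maximal
#' `HRGP_DOMAIN` regions. The region score is the mean window fraction over
#' contributing windows. Sequences shorter than the window are evaluated as
#' one whole-sequence window. Raising the threshold can only shrink the
#' covered length (monotonicity).
#'
#' @param sequence Amino-acid string.
#' @param window Window size in residues (>= 10), default 50.
#' @param threshold Fraction in (0, 1], default 0.6.
#' @param record_id Identifier for the output rows.
#' @return Region data frame (possibly empty).
#' @export
find_hrgp_regions <- function(sequence, window = 50L, threshold = 0.6,
                              record_id = "query") {
  if (window < 10L) stop("window must be >= 10 residues", call. = FALSE)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  n <- nchar(sequence)
  if (n == 0L) return(empty_regions())
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ind <- as.integer(ch %in% HRGP6)
  if (n < window) {
    frac <- mean(ind)
    if (frac >= threshold) {
      return(region_row(record_id, "HRGP_DOMAIN", 0L, n, frac))
    }
    return(empty_regions())
  }
  cs <- c(0L, cumsum(ind))
  nw <- n - window + 1L
  frac <- (cs[(window + 1L):(n + 1L)] - cs[1:nw]) / window
  ok <- which(frac >= threshold)
  if (length(ok) == 0) return(empty_regions())
  # merge windows that overlap into maximal regions
  brk <- c(0L, which(diff(ok) > window), length(ok))
  rows <- lapply(seq_len(length(brk) - 1L), function(k) {
    grp <- ok[(brk[k] + 1L):brk[k + 1L]]
    region_row(record_id, "HRGP_DOMAIN",
               grp[1] - 1L, grp[length(grp)] - 1L + window,
               mean(frac[grp]))
  })
  do.call(rbind, rows)
}

#' Heuristic signal-peptide prediction
#'
#' A documented stand-in for neural predictors (no external binary at test
#' time; see [load_external_regions()] for overriding with real predictor
#' output). Positive when, within the first 30 residues, all of:
#' (a) the protein starts with Met;
#' (b) an h-region of >= 7 consecutive hydrophobic residues
#'     (A/I/L/F/V/M/W/C) starts at position <= 8;
#' (c) a cleavage site 15-30 residues in has small residues (A/G/S/C/T) at
#'     the -3 and -1 positions relative to the cut.
#' The earliest valid cut is used; the returned interval is `[0, cleavage)`.
#' The score averages three margin terms mapped to [0,1]: h-region length
#' over 10, h-region earliness, and cut-site smallness (1 when both -3/-1
#' are small, which is required anyway); it is never compared with external
#' predictor scores.
#'
#' @param sequence Amino-acid string; proteins shorter than 18 residues
#'   return no call (absent, not an error).
#' @param record_id Identifier for the output row.
#' @return One-row region data frame, or an empty one when absent.
#' @export
predict_signal_peptide <- function(sequence, record_id = "query") {
  n <- nchar(sequence)
  if (n < 18L) return(empty_regions())
  ch <- strsplit(substr(sequence, 1L, min(n, 30L)), "", fixed = TRUE)[[1]]
  if (ch[1] != "M") return(empty_regions())
  hydro <- ch %in% HYDROPHOBIC
  # longest hydrophobic run starting at position <= 8 (0-based)
  r <- rle(hydro)
  starts <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  hruns <- which(r$values & r$lengths >= 7L & starts <= 8L)
  if (length(hruns) == 0) return(empty_regions())
  h_start <- starts[hruns[1]]
  h_len <- r$lengths[hruns[1]]
  cuts <- 15:min(30L, n, length(ch))
  small <- vapply(cuts, function(c0) {
    ch[c0 - 2L] %in% SMALL_CLEAVAGE && ch[c0] %in% SMALL_CLEAVAGE
  }, logical(1))  # ch[c0] is residue index c0-1 (the -1 position), 0-based cut c0
  if (!any(small)) return(empty_regions())
  cleavage <- cuts[which(small)[1]]
  score <- mean(c(min(1, h_len / 10), 1 - h_start / 9, 1))
  region_row(record_id, "SIGNAL_PEPTIDE", 0L, cleavage, round(score, 4))
}

#' Kyte-Doolittle transmembrane segment prediction
#'
#' Averages the Kyte-Doolittle hydropathy index over a sliding window
#' (default 19 residues, threshold 1.6, the original membrane-segment
#' convention). Maximal stretches of above-threshold window centers are
#' merged and extended to the window bounds. Regions overlapping a supplied
#' signal-peptide call are suppressed (an SP h-region is hydrophobic too).
#'
#' @param sequence Amino-acid string; shorter than `window` returns empty.
#' @param window Window size (odd recommended), default 19.
#' @param threshold Mean hydropathy cutoff, default 1.6.
#' @param exclude Optional region data frame (e.g. a signal-peptide call);
#'   TM regions overlapping any row are dropped.
#' @param record_id Identifier for output rows.
#' @return Region data frame of `TM` rows; score is the max window mean
#'   within the region rescaled to [0,1] by `pmin(mean/4.5, 1)`.
#' @export
predict_transmembrane <- function(sequence, window = 19L, threshold = 1.6,
                                  exclude = NULL, record_id = "query") {
  n <- nchar(sequence)
  if (n < window) return(empty_regions())
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  h <- KYTE_DOOLITTLE[ch]
  h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  nw <- n - window + 1L
  means <- (cs[(window + 1L):(n + 1L)] - cs[1:nw]) / window
  ok <- means > threshold
  if (!any(ok)) return(empty_regions())
  r <- rle(ok)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  rows <- lapply(which(r$values), function(k) {
    region_row(record_id, "TM",
               starts[k] - 1L, stops[k] - 1L + window,
               round(min(max(means[starts[k]:stops[k]]) / 4.5, 1), 4))
  })
  tm <- do.call(rbind, rows)
  if (!is.null(exclude) && nrow(exclude) > 0 && nrow(tm) > 0) {
    keep <- vapply(seq_len(nrow(tm)), function(i) {
      !any(tm$start[i] < exclude$end & exclude$start < tm$end)
    }, logical(1))
    tm <- tm[keep, , drop = FALSE]
  }
  tm
}

#' Heuristic GPI omega-site prediction
#'
#' Positive when the final 25 residues contain a candidate omega-site with a
#' small residue (S/G/A/N/D/C) at both the omega and omega+2 positions,
#' followed within 12 residues by a hydrophobic tail of >= 8 residues
#' reaching the C-terminus. The most N-terminal valid omega is reported as a
#' length-1 interval.
#'
#' @param sequence Amino-acid string; shorter than 25 residues returns empty.
#' @param record_id Identifier for the output row.
#' @return One-row `GPI_OMEGA` region data frame, or empty when absent.
#' @export
predict_gpi_omega <- function(sequence, record_id = "query") {
  n <- nchar(sequence)
  if (n < 25L) return(empty_regions())
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  # start of the maximal all-hydrophobic suffix (0-based); n if none
  hydro <- ch %in% HYDROPHOBIC
  tail_start <- n
  while (tail_start > 0 && hydro[tail_start]) tail_start <- tail_start - 1L
  tail_len <- n - tail_start
  if (tail_len < 8L) return(empty_regions())
  for (omega in (n - 25L):(n - 3L)) {      # 0-based omega index
    if (ch[omega + 1L] %in% SMALL_OMEGA &&
        ch[omega + 3L] %in% SMALL_OMEGA &&
        tail_start >= omega + 2L &&
        tail_start - (omega + 2L) <= 12L) {
      score <- round(min(tail_len / 12, 1), 4)
      return(region_row(record_id, "GPI_OMEGA", omega, omega + 1L, score))
    }
  }
  empty_regions()
}

#' Load external region predictions (SignalP / big-PI adapters)
#'
#' Reads a TSV of predictions from external tools so that real predictor
#' output can override the built-in heuristics. Columns: `record_id`,
#' `region` (SIGNAL_PEPTIDE, TM, HRGP_DOMAIN or GPI_OMEGA), `start`, `end`
#' (0-based half-open), `score`. On conflict with heuristic calls of the
#' same region type for the same record, external rows win.
#'
#' @param path TSV file path (header row required).
#' @return Region data frame with `source = "EXTERNAL"`.
#' @export
load_external_regions <- function(path) {
  if (!file.exists(path)) stop("external region file not found: ", path,
                               call. = FALSE)
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (nrow(raw) == 0) return(empty_regions())
  need <- c("record_id", "region", "start", "end", "score")
  if (!all(need %in% names(raw))) {
    stop("external region file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(raw))) {
    if (!raw$region[i] %in% REGION_KINDS) {
      stop("unknown region token '", raw$region[i], "' at line ", i + 1L,
           call. = FALSE)
    }
    if (is.na(raw$start[i]) || is.na(raw$end[i]) ||
        raw$start[i] < 0 || raw$start[i] >= raw$end[i]) {
      stop("malformed interval at line ", i + 1L, call. = FALSE)
    }
  }
  region_row(raw$record_id, raw$region, raw$start, raw$end, raw$score,
             source = "EXTERNAL")
}

# Merge heuristic and external calls: EXTERNAL wins per (record, region type).
merge_region_calls <- function(heuristic, external) {
  if (is.null(external) || nrow(external) == 0) return(heuristic)
  if (nrow(heuristic) > 0) {
    key_h <- paste(heuristic$record_id, heuristic$region)
    key_e <- unique(paste(external$record_id, external$region))
    heuristic <- heuristic[!key_h %in% key_e, , drop = FALSE]
  }
  rbind(heuristic, external)
}

#' All heuristic regions for one sequence
#'
#' Convenience wrapper running the four heuristics in order (signal peptide
#' first so TM calls overlapping it can be suppressed).
#'
#' @inheritParams predict_signal_peptide
#' @param hrgp_window,hrgp_threshold,tm_window,tm_threshold Pass-throughs.
#' @return Region data frame.
#' @export
profile_regions <- function(sequence, record_id = "query",
                            hrgp_window = 50L, hrgp_threshold = 0.6,
                            tm_window = 19L, tm_threshold = 1.6) {
  sp <- predict_signal_peptide(sequence, record_id)
  rbind(sp,
        predict_transmembrane(sequence, tm_window, tm_threshold,
                              exclude = sp, record_id = record_id),
        find_hrgp_regions(sequence, hrgp_window, hrgp_threshold, record_id),
        predict_gpi_omega(sequence, record_id))
}
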
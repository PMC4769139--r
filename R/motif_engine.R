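# Repeat-motif scanners: SP_n runs, YXY cross-linking motifs, AGP dipeptides
# and user patterns. All coordinates are 0-based half-open.

empty_hits <- function() {
  data.frame(record_id = character(0), kind = character(0),
             start = integer(0), end = integer(0), text = character(0),
             run_length = integer(0), stringsAsFactors = FALSE)
}

hit_frame <- function(record_id, kind, start, end, seq, run_length = NA_integer_) {
  if (length(start) == 0) return(empty_hits())
  data.frame(record_id = record_id, kind = kind,
             start = as.integer(start), end = as.integer(end),
             text = substring(seq, start + 1L, end),
             run_length = as.integer(run_length), stringsAsFactors = FALSE)
}

#' Scan a sequence for Ser-Pro_n repeat motifs
#'
#' Finds every maximal run of a serine followed by three or more consecutive
#' prolines ("maximal munch": `SPPPPP` is one SP5PLUS hit, never SP4 plus a
#' leftover). Hits are non-overlapping and reported left to right; the kind
#' is assigned from the proline run length n: 3 -> `SP3`, 4 -> `SP4`,
#' >= 5 -> `SP5PLUS` (the "SP5 or more" bin). Since hydroxylation is
#' post-translational, every Pro is treated as potential Hyp.
#'
#' @param sequence Upper-case amino-acid string.
#' @param record_id Identifier copied into the hit table.
#' @return Motif-hit data frame (`record_id`, `kind`, `start`, `end`,
#'   `text`, `run_length`), 0-based half-open coordinates.
#' @examples
#' scan_sp_runs("SPPPSPPPP")  # one SP3 then one SP4
#' @export
scan_sp_runs <- function(sequence, record_id = "query") {
  m <- gregexpr("SP{3,}", sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_hits())
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  hit_frame(record_id, run_kind(len - 1L), start, start + len, sequence,
            run_length = len - 1L)
}

run_kind <- function(n) {
  ifelse(n >= 5L, "SP5PLUS", ifelse(n == 4L, "SP4", "SP3"))
}

#' Scan for Tyr-X-Tyr cross-linking motifs
#'
#' Reports a hit at every index i with Tyr at i and i+2 (X is any residue
#' except a gap; `X` the unknown residue never counts as Tyr). Overlapping
#' hits are all reported (`YAYAY` has two): each Tyr pair is a potential
#' isodityrosine cross-link.
#'
#' @inheritParams scan_sp_runs
#' @return Motif-hit data frame of kind `YXY`.
#' @export
scan_yxy <- function(sequence, record_id = "query") {
  n <- nchar(sequence)
  if (n < 3L) return(empty_hits())
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  i <- which(ch[1:(n - 2L)] == "Y" & ch[3:n] == "Y") - 1L
  hit_frame(record_id, "YXY", i, i + 3L, sequence)
}

#' Scan for a fixed-word motif or the AGP dipeptide set
#'
#' Fixed words (e.g. `QAAA`) are counted as non-overlapping left-to-right
#' occurrences. With `kind = "AGP_DIPEPTIDE"` and no pattern, all six
#' AGP-typical dipeptides (AP, PA, SP, TP, VP, GP) are scanned and tagged.
#'
#' @inheritParams scan_sp_runs
#' @param pattern Fixed amino-acid word; ignored when scanning the AGP set.
#' @param kind `"CUSTOM"` (default) or `"AGP_DIPEPTIDE"`.
#' @return Motif-hit data frame.
#' @examples
#' scan_pattern("QAAAQAAA", "QAAA")  # 2 hits
#' @export
scan_pattern <- function(sequence, pattern = NULL,
                         kind = c("CUSTOM", "AGP_DIPEPTIDE"),
                         record_id = "query") {
  kind <- match.arg(kind)
  if (kind == "AGP_DIPEPTIDE") {
    hits <- do.call(rbind, lapply(AGP_DIPEPTIDES, function(p) {
      scan_fixed_word(sequence, p, "AGP_DIPEPTIDE", record_id)
    }))
    return(hits[order(hits$start, hits$end), , drop = FALSE])
  }
  if (is.null(pattern) || !nzchar(pattern)) {
    stop("empty motif pattern", call. = FALSE)
  }
  scan_fixed_word(sequence, toupper(pattern), "CUSTOM", record_id)
}

scan_fixed_word <- function(sequence, word, kind, record_id) {
  m <- gregexpr(word, sequence, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(empty_hits())
  start <- as.integer(m) - 1L
  # gregexpr(fixed) already returns non-overlapping left-to-right matches
  hit_frame(record_id, kind, start, start + nchar(word), sequence)
}

#' Per-protein motif profile
#'
#' Aggregates SP-run and YXY hits into the positional evidence the
#' classifier consumes: per-kind counts, the span from the first SP hit to
#' the last, the fraction of the protein that span covers, and the fraction
#' of SP hits whose midpoint lies in the N-terminal half (PERK-like bias).
#'
#' @inheritParams scan_sp_runs
#' @return A list of class `ext_motif_profile`: `record_id`, `counts`
#'   (named integer vector over kinds), `sp_total`, `yxy_count`, `sp_span`
#'   (c(start, end) or NULL), `sp_coverage` (NA when no SP hit),
#'   `sp_position_bias`, `length`, plus the raw `sp_hits`/`yxy_hits` tables.
#' @export
motif_profile <- function(sequence, record_id = "query") {
  sp <- scan_sp_runs(sequence, record_id)
  yxy <- scan_yxy(sequence, record_id)
  n <- nchar(sequence)
  counts <- setNames(integer(length(MOTIF_KINDS)), MOTIF_KINDS)
  tab <- table(sp$kind)
  counts[names(tab)] <- as.integer(tab)
  counts["YXY"] <- nrow(yxy)
  sp_total <- nrow(sp)
  if (sp_total > 0) {
    span <- c(min(sp$start), max(sp$end))
    coverage <- (span[2] - span[1]) / n
    mid <- (sp$start + sp$end) / 2
    bias <- mean(mid < n / 2)
  } else {
    span <- NULL; coverage <- NA_real_; bias <- NA_real_
  }
  structure(list(record_id = record_id, counts = counts,
                 sp_total = sp_total, yxy_count = nrow(yxy),
                 sp_span = span, sp_coverage = coverage,
                 sp_position_bias = bias, length = n,
                 sp_hits = sp, yxy_hits = yxy),
            class = "ext_motif_profile")
}

#' Candidate screen: two or more SP_n repeats
#'
#' The initial proteome screen: a protein is a candidate EXT iff it carries
#' at least two maximal Ser-Pro(>=3) runs (equivalently, two Ser anchors
#' each followed by >= 3 Pro). Anchor counting, not substring counting:
#' `SPPPPPP` is a single run and does not pass.
#'
#' @param profile An `ext_motif_profile`.
#' @param min_runs Screen threshold (default 2).
#' @return Logical.
#' @export
is_candidate <- function(profile, min_runs = 2L) {
  stopifnot(inherits(profile, "ext_motif_profile"))
  profile$sp_total >= min_runs
}

#' Motif summary table for a whole proteome
#'
#' @param records `ext_proteome` data frame.
#' @return Data frame with one row per record: id, length, sp3, sp4,
#'   sp5plus, sp_total, yxy, sp_coverage, sp_position_bias.
#' @export
motif_summary <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(id = character(0), length = integer(0),
                      sp3 = integer(0), sp4 = integer(0),
                      sp5plus = integer(0), sp_total = integer(0),
                      yxy = integer(0), sp_coverage = numeric(0),
                      sp_position_bias = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    p <- motif_profile(records$sequence[i], records$id[i])
    data.frame(id = p$record_id, length = p$length,
               sp3 = unname(p$counts["SP3"]), sp4 = unname(p$counts["SP4"]),
               sp5plus = unname(p$counts["SP5PLUS"]),
               sp_total = p$sp_total, yxy = p$yxy_count,
               sp_coverage = p$sp_coverage,
               sp_position_bias = p$sp_position_bias,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
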
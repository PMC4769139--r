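# Class-level aggregate statistics over a classified proteome: class
# census, pooled SP_n repeat-type frequencies, and mean YXY counts per
# class grouping.

#' SP_n repeat-type frequencies over a label set
#'
#' Pools SP3/SP4/SP5PLUS run counts over all proteins whose label is in
#' `restrict_to` (default: classical EXTs, where SP4 dominance is the
#' observation of interest) and normalizes to sum 1. The restriction set is
#' a parameter so the whole-proteome reading is equally computable.
#'
#' @param classtable `ext_classtable` from [classify_proteome()] (needs
#'   columns `label`, `sp3`, `sp4`, `sp5plus`).
#' @param restrict_to Character vector of labels to pool over.
#' @return Named numeric `c(f_sp3, f_sp4, f_sp5)`, or `NULL` (absent) when
#'   the pooled run count is zero.
#' @export
spn_frequencies <- function(classtable, restrict_to = "CLASSICAL") {
  sel <- classtable[classtable$label %in% restrict_to, , drop = FALSE]
  counts <- c(sum(sel$sp3), sum(sel$sp4), sum(sel$sp5plus))
  total <- sum(counts)
  if (total == 0) return(NULL)
  setNames(counts / total, c("f_sp3", "f_sp4", "f_sp5"))
}

#' Mean YXY motif counts in classical vs non-classical EXTs
#'
#' Arithmetic mean of per-protein YXY counts in the classical group (label
#' CLASSICAL) and in the non-classical group (every other EXT label:
#' SHORT, LRX, PERK, FH_EXT, LONG_CHIMERIC, OTHER_CHIMERIC). Potential EXTs
#' and non-EXTs are excluded. A group with no members reports NA (absent).
#' Per-group denominators are used (each mean divides by its own group
#' size).
#'
#' @param classtable `ext_classtable` (needs `label` and `yxy`).
#' @return Named numeric `c(mean_classical, mean_nonclassical)`; NA for an
#'   empty group.
#' @export
mean_yxy <- function(classtable) {
  cls <- classtable$yxy[classtable$label == "CLASSICAL"]
  non <- classtable$yxy[classtable$label %in% setdiff(EXT_LABELS, "CLASSICAL")]
  c(mean_classical = if (length(cls)) mean(cls) else NA_real_,
    mean_nonclassical = if (length(non)) mean(non) else NA_real_)
}

#' Class census of a classified proteome
#'
#' Per-label counts plus the determined-EXT total (all seven EXT classes;
#' potential EXTs and non-EXTs are counted separately, mirroring the
#' "determined as EXTs" vs "potential EXTs" split) and the candidate total
#' (everything that passed the SP_n screen).
#'
#' @param classtable `ext_classtable` (needs `label`).
#' @return List of class `ext_class_summary`: `counts` (named integer over
#'   all nine labels), `ext_total`, `candidate_total`, `n`.
#' @export
class_census <- function(classtable) {
  counts <- setNames(integer(length(CLASS_LABELS)), CLASS_LABELS)
  tab <- table(factor(classtable$label, levels = CLASS_LABELS))
  counts[names(tab)] <- as.integer(tab)
  structure(list(counts = counts,
                 ext_total = sum(counts[EXT_LABELS]),
                 candidate_total = sum(counts) - counts[["NON_EXT"]],
                 n = nrow(classtable)),
            class = "ext_class_summary")
}

#' @export
print.ext_class_summary <- function(x, ...) {
  cat("Proteins screened:", x$n, "\n")
  cat("Candidates (>= 2 SP_n runs):", x$candidate_total, "\n")
  cat("Determined EXTs:", x$ext_total, "\n")
  for (lbl in CLASS_LABELS) {
    cat(sprintf("  %-15s %d\n", lbl, x$counts[[lbl]]))
  }
  invisible(x)
}

#' Human-readable summary report
#'
#' Census, SP_n frequencies (classical pool) and YXY group means, with
#' means printed to one decimal; full precision is preserved in the TSV
#' outputs.
#'
#' @param classtable `ext_classtable`.
#' @return Character vector of report lines, invisibly printed.
#' @export
summary_report <- function(classtable) {
  cz <- class_census(classtable)
  freqs <- spn_frequencies(classtable)
  yxy <- mean_yxy(classtable)
  lines <- c(sprintf("proteins\t%d", cz$n),
             sprintf("candidates\t%d", cz$candidate_total),
             sprintf("ext_total\t%d", cz$ext_total),
             sprintf("count_%s\t%d", names(cz$counts), cz$counts))
  if (!is.null(freqs)) {
    lines <- c(lines, sprintf("%s\t%.4f", names(freqs), freqs))
  }
  lines <- c(lines,
             sprintf("mean_yxy_classical\t%s",
                     ifelse(is.na(yxy[1]), "NA", sprintf("%.1f", yxy[1]))),
             sprintf("mean_yxy_nonclassical\t%s",
                     ifelse(is.na(yxy[2]), "NA", sprintf("%.1f", yxy[2]))))
  lines
}
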
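# Local-alignment homology evidence: exact Smith-Waterman against a small
# bundled set of domain exemplars (LRR, kinase, FH2, representative EXTs).
# Replaces a BLAST-vs-Arabidopsis step with a dependency-free, reproducible
# equivalent; the bundle is user-replaceable FASTA.

.extscan_env <- new.env(parent = emptyenv())

# BLOSUM62 from Biostrings with the X (and *) rows/columns set to -1:
# unknown residues score -1 against everything, including themselves.
blosum62_x <- function() {
  if (!is.null(.extscan_env$blosum)) return(.extscan_env$blosum)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  keep <- c(AA20, "X", "*")
  m <- m[keep, keep]
  m["X", ] <- -1; m[, "X"] <- -1
  m["*", ] <- -1; m[, "*"] <- -1
  storage.mode(m) <- "double"
  .extscan_env$blosum <- m
  m
}

encode_aa <- function(sequence, alphabet) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(ch, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx - 1L
}

#' Exact Smith-Waterman local alignment
#'
#' Optimal local alignment with affine gaps (a gap of length k costs
#' `gap_open + k * gap_extend`) under BLOSUM62, with `X` scoring -1 against
#' everything. The score floor is 0; an empty alignment (score 0, empty
#' intervals) is returned when no residue pair scores positively. One
#' optimal alignment is reported with deterministic tie-breaking (diagonal
#' preferred over up over left during traceback).
#'
#' @param a,b Non-empty amino-acid strings.
#' @param gap_open,gap_extend Gap existence/extension penalties (default
#'   11/1, the ubiquitous protein-search default).
#' @param score_only If TRUE skip traceback and return just the score.
#' @return List with `score`, `a_interval`, `b_interval` (0-based
#'   half-open), or a numeric score when `score_only`.
#' @examples
#' smith_waterman("ACDE", "ACDE")$score  # sum of BLOSUM62 diagonal = 24
#' @export
smith_waterman <- function(a, b, gap_open = 11, gap_extend = 1,
                           score_only = FALSE) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  m <- blosum62_x()
  ea <- encode_aa(a, rownames(m))
  eb <- encode_aa(b, rownames(m))
  if (score_only) return(.sw_score(ea, eb, m, gap_open, gap_extend))
  r <- .sw_align(ea, eb, m, gap_open, gap_extend)
  list(score = r$score,
       a_interval = c(r$a_start, r$a_end),
       b_interval = c(r$b_start, r$b_end))
}

#' Load a reference-domain bundle
#'
#' Reads a FASTA whose headers carry `family=<TOKEN>` tags (one of LRR,
#' KINASE, FH2, CLASSICAL_EXT, SHORT_EXT, OTHER) and optional free-text
#' provenance. The shipped default bundle is constructed (synthetic) domain
#' exemplars -- see `system.file("extdata", "reference_domains_synthetic.fasta",
#' package = "extscan")` -- and can be replaced by any user FASTA with the
#' same header convention.
#'
#' @param path FASTA path; default = the bundled synthetic exemplars.
#' @return Data frame: `ref_id`, `family`, `sequence`, `provenance`,
#'   `self_score` (Smith-Waterman self-alignment score used for
#'   normalization).
#' @export
load_reference_domains <- function(path = default_reference_path()) {
  recs <- read_proteome(path)
  fam <- sub(".*family=([A-Z0-9_]+).*", "\\1", recs$description)
  bad <- !fam %in% REF_FAMILIES
  if (any(bad)) {
    stop("reference header without a valid family= tag: ", recs$id[bad][1L],
         call. = FALSE)
  }
  self <- vapply(recs$sequence, function(s) {
    smith_waterman(s, s, score_only = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(ref_id = recs$id, family = fam, sequence = recs$sequence,
             provenance = recs$description, self_score = self,
             stringsAsFactors = FALSE)
}

#' @rdname load_reference_domains
#' @export
default_reference_path <- function() {
  system.file("extdata", "reference_domains_synthetic.fasta",
              package = "extscan", mustWork = TRUE)
}

empty_homology <- function() {
  data.frame(record_id = character(0), ref_id = character(0),
             family = character(0), raw_score = numeric(0),
             normalized_score = numeric(0),
             q_start = integer(0), q_end = integer(0),
             r_start = integer(0), r_end = integer(0),
             stringsAsFactors = FALSE)
}

#' Assign domain families to a query protein
#'
#' Aligns the query against every reference exemplar and keeps, per family,
#' the best hit whose score normalized by the reference self-score reaches
#' `min_normalized`. Query intervals locate the family on the query, which
#' the classifier uses for N-/C-terminal architecture checks.
#'
#' @param sequence Query amino-acid string.
#' @param references Data frame from [load_reference_domains()].
#' @param min_normalized Normalized-score threshold in [0,1], default 0.25.
#' @param record_id Identifier for the output rows.
#' @return Homology-hit data frame (one row per family with a passing hit):
#'   `record_id`, `ref_id`, `family`, `raw_score`, `normalized_score`,
#'   `q_start`, `q_end`, `r_start`, `r_end`.
#' @export
assign_domain_families <- function(sequence, references,
                                   min_normalized = 0.25,
                                   record_id = "query") {
  if (is.null(references) || nrow(references) == 0) {
    stop("empty reference set", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(references)), function(i) {
    al <- smith_waterman(sequence, references$sequence[i])
    norm <- al$score / references$self_score[i]
    data.frame(record_id = record_id, ref_id = references$ref_id[i],
               family = references$family[i], raw_score = al$score,
               normalized_score = norm,
               q_start = al$a_interval[1], q_end = al$a_interval[2],
               r_start = al$b_interval[1], r_end = al$b_interval[2],
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$normalized_score >= min_normalized, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_homology())
  # best per family, deterministic: score desc then ref_id
  hits <- hits[order(hits$family, -hits$normalized_score, hits$ref_id), ,
               drop = FALSE]
  hits <- hits[!duplicated(hits$family), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
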
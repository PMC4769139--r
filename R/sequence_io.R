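# Proteome FASTA input/output and GFF3 motif-track output.

#' Read a predicted proteome from a FASTA file
#'
#' Parses an amino-acid multi-FASTA into one validated record per entry.
#' Sequences are upper-cased; a single trailing stop symbol `*` is stripped;
#' internal stops are preserved but flagged. Residues outside the 20-letter
#' alphabet (B, Z, J, U, O) are mapped to `X` with a warning; `X` never
#' matches S, P or Y in any motif pattern downstream. Duplicate identifiers
#' are kept: later copies are suffixed `.2`, `.3`, ... with a warning, so
#' that repeated locus names (e.g. splice forms) do not silently shrink the
#' census.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return A `data.frame` of class `ext_proteome` with columns `id`,
#'   `description`, `sequence`, `length` (residues, excluding the stripped
#'   trailing stop) and `internal_stop` (logical).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKSPPPSPPP", ">p2", "mkv*"), fa)
#' read_proteome(fa)
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) {
    stop("proteome file not found: ", path, call. = FALSE)
  }
  aa <- Biostrings::readBStringSet(path)  # BString: tolerate *, lowercase
  headers <- names(aa)
  if (is.null(headers)) headers <- character(0)
  seqs <- toupper(as.character(aa))
  ids <- vapply(strsplit(headers, "[ \t]+"), function(x) {
    if (length(x) == 0L) "" else x[[1L]]
  }, character(1))
  desc <- mapply(function(h, id) {
    rest <- sub("^[^ \t]*[ \t]*", "", h)
    rest
  }, headers, ids, USE.NAMES = FALSE)

  if (any(!nzchar(ids))) {
    stop("FASTA entry with empty identifier at record ",
         which(!nzchar(ids))[1L], call. = FALSE)
  }
  empty <- !nzchar(gsub("\\*", "", seqs))
  if (any(empty)) {
    stop("FASTA entry with empty sequence: '", headers[empty][1L], "'",
         call. = FALSE)
  }

  # nucleotide sniff: warn, do not refuse
  pooled <- paste(seqs, collapse = "")
  nuc <- sum(strsplit(pooled, "")[[1]] %in% c("A","C","G","T","U","N"))
  if (nchar(pooled) > 0 && nuc / nchar(pooled) >= 0.95) {
    warning("input looks nucleotide-like (>=95% ACGTUN); ",
            "expected amino-acid FASTA", call. = FALSE)
  }

  # strip one trailing stop, flag internal stops
  seqs <- sub("\\*$", "", seqs)
  internal_stop <- grepl("\\*", seqs)
  if (any(internal_stop)) {
    warning(sum(internal_stop), " record(s) contain internal stop symbols",
            call. = FALSE)
  }

  # map non-standard residues to X
  nonstd <- grepl("[BZJUO]", seqs)
  if (any(nonstd)) {
    warning("non-standard residues (B/Z/J/U/O) mapped to X in ",
            sum(nonstd), " record(s)", call. = FALSE)
    seqs <- chartr("BZJUO", "XXXXX", seqs)
  }
  bad <- regmatches(seqs, regexpr("[^A-Z*]", seqs))
  if (length(unlist(bad)) > 0) {
    stop("invalid residue character '", unlist(bad)[1L], "' in input",
         call. = FALSE)
  }

  # duplicate ids: keep, suffix, warn
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids renamed with .2/.3 suffixes: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            call. = FALSE)
    ids <- make_unique_ids(ids)
  }

  out <- data.frame(id = ids, description = desc, sequence = seqs,
                    length = nchar(seqs), internal_stop = internal_stop,
                    stringsAsFactors = FALSE)
  class(out) <- c("ext_proteome", "data.frame")
  out
}

# a, a, b -> a, a.2, b
make_unique_ids <- function(ids) {
  counts <- new.env(parent = emptyenv())
  vapply(ids, function(id) {
    n <- if (is.null(counts[[id]])) 1L else counts[[id]] + 1L
    counts[[id]] <- n
    if (n == 1L) id else paste0(id, ".", n)
  }, character(1), USE.NAMES = FALSE)
}

#' Write protein records to FASTA
#'
#' Inverse of [read_proteome()]: `read_proteome(write_proteome(x))`
#' reproduces ids, descriptions and sequences exactly.
#'
#' @param records An `ext_proteome` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  headers <- ifelse(nzchar(records$description %||% ""),
                    paste(records$id, records$description),
                    records$id)
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write motif hits as a GFF3 feature track
#'
#' Serializes motif locations (the evidence usually rendered as colored
#' sequence highlighting) as protein-space GFF3. Internal 0-based half-open
#' coordinates are converted to GFF3's 1-based inclusive convention here and
#' only here. Lines are ordered by record id, then start, then end.
#'
#' @param records `ext_proteome` data frame (supplies sequence lengths).
#' @param hits Motif-hit data frame from the scanners (columns `record_id`,
#'   `kind`, `start`, `end`, and optionally `run_length`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_gff <- function(records, hits, path) {
  lens <- setNames(records$length, records$id)
  lines <- "##gff-version 3"
  if (nrow(hits) > 0) {
    unknown <- setdiff(hits$record_id, records$id)
    if (length(unknown) > 0) {
      stop("motif hit references unknown record id: ", unknown[1L],
           call. = FALSE)
    }
    beyond <- hits$end > lens[hits$record_id] | hits$start < 0 |
      hits$start >= hits$end
    if (any(beyond)) {
      stop("motif hit interval outside its sequence for record ",
           hits$record_id[beyond][1L], call. = FALSE)
    }
    ord <- order(hits$record_id, hits$start, hits$end, method = "radix")
    h <- hits[ord, , drop = FALSE]
    attrs <- sprintf("ID=%s.%d;kind=%s", h$record_id, seq_len(nrow(h)), h$kind)
    if ("run_length" %in% names(h)) {
      rl <- ifelse(is.na(h$run_length), "", sprintf(";run_length=%d", h$run_length))
      attrs <- paste0(attrs, rl)
    }
    lines <- c(lines, sprintf("%s\textscan\t%s\t%d\t%d\t.\t.\t.\t%s",
                              h$record_id, h$kind,
                              h$start + 1L, h$end, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
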
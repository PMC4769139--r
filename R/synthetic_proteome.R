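# Seeded synthetic proteomes with planted, labelled members of every EXT
# class, so the whole pipeline is testable without downloads. The stated
# world: at ambiguity 0 every planted protein clears the classifier
# thresholds it must clear by a >= 20% margin, and planted motif
# coordinates are exhaustive (the scanners re-detect exactly the planted
# hits, nothing else). Spacer/background material is therefore actively
# scrubbed of accidental SP runs, YXY triplets and HRGP-rich windows.

#' Synthetic proteome generator specification
#'
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param n_per_class Named counts of planted proteins per label (the seven
#'   EXT classes plus POTENTIAL). Default 10 each.
#' @param background_n Number of non-candidate background proteins
#'   (default 20).
#' @param background_len_range Length range of background proteins
#'   (default 150-600 aa).
#' @param ambiguity Fraction in [0,1]. 0 = unambiguous margins. Raising it
#'   only jitters the SHORT length across the 200 aa bound and the
#'   OTHER_CHIMERIC repeat-block composition across the HRGP threshold, so
#'   the only label confusions it can create are SHORT<->CLASSICAL and
#'   OTHER_CHIMERIC<->POTENTIAL.
#' @param sp_mix Probabilities of SP3/SP4/SP5PLUS repeats inside planted
#'   repeat blocks (default c(0.25, 0.65, 0.10): SP4-dominant, as in
#'   classical EXTs).
#' @param yxy_density Probability of inserting a YXY motif after a repeat
#'   unit (default 0.5).
#' @param classical_repeats Range of SP_n repeats in a classical block
#'   (default 15-30).
#' @return List of class `ext_generator_spec`.
#' @export
generator_spec <- function(seed = 1L,
                           n_per_class = NULL,
                           background_n = 20L,
                           background_len_range = c(150L, 600L),
                           ambiguity = 0,
                           sp_mix = c(SP3 = 0.25, SP4 = 0.65, SP5PLUS = 0.10),
                           yxy_density = 0.5,
                           classical_repeats = c(15L, 30L)) {
  planted <- setdiff(CLASS_LABELS, "NON_EXT")
  if (is.null(n_per_class)) {
    n_per_class <- setNames(rep(10L, length(planted)), planted)
  }
  if (is.null(names(n_per_class)) || !all(names(n_per_class) %in% planted)) {
    stop("n_per_class must be named with planted class labels", call. = FALSE)
  }
  full <- setNames(rep(0L, length(planted)), planted)
  full[names(n_per_class)] <- as.integer(n_per_class)
  if (any(full < 0) || background_n < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (ambiguity < 0 || ambiguity > 1) {
    stop("ambiguity must be in [0, 1]", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_per_class = full,
                 background_n = as.integer(background_n),
                 background_len_range = as.integer(background_len_range),
                 ambiguity = ambiguity,
                 sp_mix = sp_mix / sum(sp_mix),
                 yxy_density = yxy_density,
                 classical_repeats = as.integer(classical_repeats)),
            class = "ext_generator_spec")
}

# ---- low-level sequence builders -------------------------------------------

SPACER_ALPHABET <- c("A", "V", "G", "T")  # HRGP6 minus S/P: cannot seed
                                          # unplanned SP or YXY motifs
SCRUB_ALPHABET <- c("L", "E", "K", "D", "R", "Q", "N", "F", "I")  # non-HRGP6,
                                          # non-S/P/Y replacement residues

sample_background <- function(n) {
  paste(sample(names(BACKGROUND_COMPOSITION), n, replace = TRUE,
               prob = BACKGROUND_COMPOSITION), collapse = "")
}

# Signal peptide built so the heuristic finds exactly the planted cleavage:
# M + polar + all-Leu h-region + small(-3) + Gln(-2) + small(-1). Earlier
# cuts are blocked because every earlier -1/-3 position is Leu or Gln.
build_signal_peptide <- function() {
  cleavage <- sample(15:20, 1)
  h_len <- cleavage - 5L
  paste0("M", sample(c("K", "R", "N", "Q"), 1),
         strrep("L", h_len),
         sample(c("A", "G", "S"), 1), "Q", sample(c("A", "G", "S"), 1))
}

# One SP_n repeat block. Returns the string plus planted motif coordinates
# relative to the block start. Either a repeat count or a minimum length
# can be requested.
build_repeat_block <- function(n_repeats, sp_mix, yxy_density,
                               dilute = 0, min_len = 0L) {
  pieces <- character(0)
  sp <- list(); yxy <- list()
  pos <- 0L
  k <- 0L
  while (k < n_repeats || pos < min_len) {
    k <- k + 1L
    kind <- sample(names(sp_mix), 1, prob = sp_mix)
    n_pro <- switch(kind, SP3 = 3L, SP4 = 4L, SP5PLUS = sample(5:6, 1))
    run <- paste0("S", strrep("P", n_pro))
    sp[[length(sp) + 1L]] <- c(pos, pos + 1L + n_pro, n_pro)
    pieces <- c(pieces, run); pos <- pos + 1L + n_pro
    spacer_n <- sample(2:4, 1)
    spacer <- sample(SPACER_ALPHABET, spacer_n, replace = TRUE)
    if (dilute > 0) {
      swap <- runif(spacer_n) < dilute
      spacer[swap] <- sample(SCRUB_ALPHABET, sum(swap), replace = TRUE)
    }
    pieces <- c(pieces, paste(spacer, collapse = "")); pos <- pos + spacer_n
    if (runif(1) < yxy_density) {
      x <- sample(SPACER_ALPHABET, 1)
      yxy[[length(yxy) + 1L]] <- c(pos, pos + 3L)
      pieces <- c(pieces, paste0("Y", x, "Y")); pos <- pos + 3L
      guard <- sample(SPACER_ALPHABET, 2, replace = TRUE)  # >= 2 non-Y
      pieces <- c(pieces, paste(guard, collapse = "")); pos <- pos + 2L
    }
  }
  list(seq = paste(pieces, collapse = ""), sp = sp, yxy = yxy, len = pos)
}

shift_coords <- function(lst, offset) {
  lapply(lst, function(x) c(x[1] + offset, x[2] + offset, x[-(1:2)]))
}

# ---- scrubbing --------------------------------------------------------------

# Remove unplanned SP runs / YXY triplets by mutating residues outside the
# planted intervals; iterate until the scanners re-detect exactly the
# planted set. Replacement residues are motif-inert.
fix_unplanned_motifs <- function(seq, planted_sp, planted_yxy) {
  covered <- function(lst) {
    out <- logical(nchar(seq))
    for (x in lst) if (x[2] > x[1]) out[(x[1] + 1L):x[2]] <- TRUE
    out
  }
  key <- function(df) paste(df$start, df$end)
  planted_sp_key <- vapply(planted_sp, function(x) paste(x[1], x[2]), "")
  planted_yxy_key <- vapply(planted_yxy, function(x) paste(x[1], x[2]), "")
  for (iter in 1:50) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    prot_sp <- covered(planted_sp)
    prot_yxy <- covered(planted_yxy)
    det_sp <- scan_sp_runs(seq)
    det_yxy <- scan_yxy(seq)
    bad_sp <- det_sp[!key(det_sp) %in% planted_sp_key, , drop = FALSE]
    bad_yxy <- det_yxy[!key(det_yxy) %in% planted_yxy_key, , drop = FALSE]
    if (nrow(bad_sp) == 0 && nrow(bad_yxy) == 0) return(seq)
    if (nrow(bad_sp) > 0) {
      for (i in seq_len(nrow(bad_sp))) {
        idx <- (bad_sp$start[i] + 1L):bad_sp$end[i]
        free <- idx[!prot_sp[idx]]
        if (length(free) > 0) ch[free[1]] <- "A"
      }
    }
    if (nrow(bad_yxy) > 0) {
      for (i in seq_len(nrow(bad_yxy))) {
        ys <- c(bad_yxy$start[i] + 1L, bad_yxy$start[i] + 3L)  # the two Tyr
        free <- ys[!prot_yxy[ys]]
        if (length(free) > 0) ch[free[1]] <- "T"
      }
    }
    seq <- paste(ch, collapse = "")
  }
  stop("motif scrubbing failed to converge", call. = FALSE)
}

# Cap window HRGP6 composition outside planted-block spans so that
# non-HRGP material sits well below the domain threshold (unambiguous
# negatives). `protect` lists intervals that may legitimately stay rich
# (repeat blocks, planted motifs); only unprotected residues are mutated.
# Windows whose excess richness sits entirely in protected positions
# (block-edge windows) are left alone -- they merge into the block's own
# HRGP region, which is the planted state anyway.
cap_hrgp_windows <- function(seq, protect = list(), cap = 0.48,
                             window = 50L) {
  n <- nchar(seq)
  prot <- logical(n)
  for (x in protect) {
    if (x[2] > x[1]) prot[(min(x[1], n - 1L) + 1L):min(x[2], n)] <- TRUE
  }
  for (iter in 1:200) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    ind <- as.integer(ch %in% HRGP6)
    if (n < window) {
      offending <- if (mean(ind) >= cap) list(seq_len(n)) else list()
    } else {
      cs <- c(0L, cumsum(ind))
      nw <- n - window + 1L
      frac <- (cs[(window + 1L):(n + 1L)] - cs[1:nw]) / window
      offending <- lapply(which(frac >= cap), function(s) s:(s + window - 1L))
    }
    mutated <- FALSE
    for (idx in offending) {
      targets <- idx[!prot[idx] & ch[idx] %in% HRGP6]
      if (length(targets) == 0) next
      pick <- targets[seq(1, length(targets), by = 2)]
      ch[pick] <- sample(SCRUB_ALPHABET, length(pick), replace = TRUE)
      mutated <- TRUE
    }
    if (!mutated) return(paste(ch, collapse = ""))
    seq <- paste(ch, collapse = "")
  }
  stop("composition scrubbing failed to converge", call. = FALSE)
}

# Background N-termini are unambiguous signal-peptide negatives: break any
# hydrophobic run in the first 30 residues with a charged residue.
break_nterm_hydrophobics <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[1] <- "M"
  upto <- min(30L, length(ch))
  run <- 0L
  for (i in seq_len(upto)) {
    if (ch[i] %in% HYDROPHOBIC) run <- run + 1L else run <- 0L
    if (run >= 5L) { ch[i] <- sample(c("D", "E", "K", "R"), 1); run <- 0L }
  }
  paste(ch, collapse = "")
}

# ---- per-class templates ----------------------------------------------------

# Each builder returns list(seq, sp, yxy, regions) with 0-based coords.
# regions is a list of c(kind=..., start, end) entries encoded as
# list(region, start, end).

builder_env <- function(spec) {
  refs <- load_reference_domains()
  exemplar <- function(family) {
    r <- refs[refs$family == family, , drop = FALSE]
    r$sequence[1]
  }
  list(refs = refs, exemplar = exemplar, spec = spec)
}

build_classical <- function(env, short = FALSE) {
  spec <- env$spec
  sp_pep <- build_signal_peptide()
  off <- nchar(sp_pep)
  if (short) {
    # stay well under the 200 aa bound (>= 20% margin at ambiguity 0)
    blk <- build_repeat_block(8L, spec$sp_mix, spec$yxy_density,
                              min_len = 110L - off)
  } else {
    # stay well over it, and well over the coverage/SP-count thresholds
    blk <- build_repeat_block(spec$classical_repeats[1], spec$sp_mix,
                              spec$yxy_density,
                              min_len = sample(280:420, 1) - off)
  }
  seq <- paste0(sp_pep, blk$seq)
  if (short && spec$ambiguity > 0) {
    # ambiguity: pad with HRGP-type spacer so the length drifts across the
    # 200 aa SHORT bound while everything else stays classical-grade
    pad_n <- round(runif(1, 0, 90 * spec$ambiguity))
    seq <- paste0(seq, paste(sample(SPACER_ALPHABET, pad_n, TRUE),
                             collapse = ""))
  }
  list(seq = seq,
       sp = shift_coords(blk$sp, off), yxy = shift_coords(blk$yxy, off),
       regions = list(list("SIGNAL_PEPTIDE", 0L, off)))
}

build_lrx <- function(env) {
  spec <- env$spec
  sp_pep <- build_signal_peptide()
  lrr <- env$exemplar("LRR")
  blk <- build_repeat_block(sample(12:18, 1), spec$sp_mix,
                            yxy_density = 0.1)
  linker <- paste(sample(SCRUB_ALPHABET, 6, TRUE), collapse = "")
  off <- nchar(sp_pep) + nchar(lrr) + nchar(linker)
  list(seq = paste0(sp_pep, lrr, linker, blk$seq),
       sp = shift_coords(blk$sp, off), yxy = shift_coords(blk$yxy, off),
       regions = list(list("SIGNAL_PEPTIDE", 0L, nchar(sp_pep)),
                      list("DOMAIN_LRR", nchar(sp_pep),
                           nchar(sp_pep) + nchar(lrr))))
}

build_perk <- function(env) {
  spec <- env$spec
  head <- paste0("M", sample(c("K", "R", "E", "D"), 1))
  blk <- build_repeat_block(sample(12:18, 1), spec$sp_mix,
                            yxy_density = 0.15)
  tm <- paste(sample(c("L", "I", "V", "A", "F"), 25, TRUE,
                     prob = c(0.35, 0.25, 0.2, 0.15, 0.05)), collapse = "")
  kin <- env$exemplar("KINASE")
  tail <- paste(sample(SCRUB_ALPHABET, 15, TRUE), collapse = "")
  off <- nchar(head)
  tm_start <- off + blk$len
  kin_start <- tm_start + nchar(tm)
  list(seq = paste0(head, blk$seq, tm, kin, tail),
       sp = shift_coords(blk$sp, off), yxy = shift_coords(blk$yxy, off),
       regions = list(list("TM", tm_start, tm_start + nchar(tm)),
                      list("DOMAIN_KINASE", kin_start,
                           kin_start + nchar(kin))))
}

build_fh <- function(env) {
  spec <- env$spec
  head <- paste0("M", paste(sample(SCRUB_ALPHABET, 10, TRUE), collapse = ""))
  fh2 <- env$exemplar("FH2")
  sp <- list(); yxy <- list(); pieces <- character(0)
  pos <- nchar(head) + nchar(fh2)
  for (k in 1:3) {
    linker <- paste(sample(SCRUB_ALPHABET, sample(8:15, 1), TRUE),
                    collapse = "")
    blk <- build_repeat_block(sample(2:4, 1), spec$sp_mix,
                              yxy_density = 0.1)
    pieces <- c(pieces, linker, blk$seq)
    pos <- pos + nchar(linker)
    sp <- c(sp, shift_coords(blk$sp, pos))
    yxy <- c(yxy, shift_coords(blk$yxy, pos))
    pos <- pos + blk$len
  }
  list(seq = paste0(head, fh2, paste(pieces, collapse = "")),
       sp = sp, yxy = yxy,
       regions = list(list("DOMAIN_FH2", nchar(head),
                           nchar(head) + nchar(fh2))))
}

build_long_chimeric <- function(env) {
  spec <- env$spec
  head <- paste0("M", sample(c("K", "R", "E"), 1))
  blk <- build_repeat_block(sample(25:35, 1), spec$sp_mix,
                            yxy_density = 0.1)
  foreign <- sample_background(2200L)
  off <- nchar(head)
  seq <- paste0(head, blk$seq, "L", foreign)  # L guard: no run extension
  list(seq = seq,
       sp = shift_coords(blk$sp, off), yxy = shift_coords(blk$yxy, off),
       regions = list(),
       scrub_from = off + blk$len)
}

build_other_chimeric <- function(env) {
  spec <- env$spec
  sp_pep <- build_signal_peptide()
  blk <- build_repeat_block(sample(12:16, 1), spec$sp_mix,
                            yxy_density = 0.1,
                            dilute = 0.6 * spec$ambiguity)
  other <- env$exemplar("OTHER")
  foreign <- sample_background(120L)
  off <- nchar(sp_pep)
  list(seq = paste0(sp_pep, blk$seq, "L", other, foreign),
       sp = shift_coords(blk$sp, off), yxy = shift_coords(blk$yxy, off),
       regions = list(list("SIGNAL_PEPTIDE", 0L, off),
                      list("DOMAIN_OTHER", off + blk$len + 1L,
                           off + blk$len + 1L + nchar(other))),
       scrub_from = off + blk$len)
}

build_potential <- function(env) {
  bg <- sample_background(300L)
  bg <- break_nterm_hydrophobics(bg)
  # two isolated SPPP motifs with non-Pro guards
  p1 <- 100L; p2 <- 200L
  ch <- strsplit(bg, "", fixed = TRUE)[[1]]
  insert <- function(ch, pos) {
    c(ch[1:pos], strsplit("TASPPPAT", "")[[1]], ch[(pos + 1L):length(ch)])
  }
  ch <- insert(ch, p2); ch <- insert(ch, p1)
  seq <- paste(ch, collapse = "")
  sp <- list(c(p1 + 2L, p1 + 6L, 3L), c(p2 + 10L, p2 + 14L, 3L))
  list(seq = seq, sp = sp, yxy = list(), regions = list(), scrub_all = TRUE)
}

build_background <- function(env) {
  rng <- env$spec$background_len_range
  n <- sample(rng[1]:rng[2], 1)
  seq <- break_nterm_hydrophobics(sample_background(n))
  list(seq = seq, sp = list(), yxy = list(), regions = list(),
       scrub_all = TRUE)
}

# ---- top level --------------------------------------------------------------

#' Generate a synthetic proteome with planted ground truth
#'
#' Emits one protein per planted slot following the class templates
#' (classical: signal peptide + SP_n/YXY repeat block; SHORT: the same
#' under 200 aa; LRX: signal peptide + LRR exemplar + C-terminal repeat
#' block; PERK: N-terminal repeat block + TM stretch + kinase exemplar;
#' FH_EXT: FH2 exemplar + scattered repeat blocks; LONG_CHIMERIC: > 2,000
#' aa repeat block + foreign mass; OTHER_CHIMERIC: repeat block + foreign
#' globular segment; POTENTIAL: exactly two SPPP in scrubbed background)
#' plus composition-matched background negatives. Deterministic given
#' `spec$seed`; planted motif coordinates are exhaustive by construction.
#'
#' @param spec [generator_spec()].
#' @return List with `records` (`ext_proteome` data frame) and `truth`
#'   (data frame: `record_id`, `planted_label`, `sp_coords`, `yxy_coords`,
#'   `region_coords`; coordinate strings are `start-end` pairs joined by
#'   `;`, 0-based half-open).
#' @export
generate_proteome <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "ext_generator_spec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  env <- builder_env(spec)
  builders <- list(
    CLASSICAL = function() build_classical(env, short = FALSE),
    SHORT = function() build_classical(env, short = TRUE),
    LRX = function() build_lrx(env),
    PERK = function() build_perk(env),
    FH_EXT = function() build_fh(env),
    LONG_CHIMERIC = function() build_long_chimeric(env),
    OTHER_CHIMERIC = function() build_other_chimeric(env),
    POTENTIAL = function() build_potential(env))

  recs <- list(); truths <- list()
  idx <- 0L
  emit <- function(label, built) {
    idx <<- idx + 1L
    id <- sprintf("syn_%s_%03d", tolower(label), idx)
    seq <- built$seq
    # scrub: unplanned motifs everywhere; composition outside block spans
    seq <- fix_unplanned_motifs(seq, built$sp, built$yxy)
    if (isTRUE(built$scrub_all)) {
      seq <- cap_hrgp_windows(seq, protect = c(built$sp, built$yxy))
    } else if (!is.null(built$scrub_from)) {
      seq <- cap_hrgp_windows(
        seq, protect = list(c(0L, built$scrub_from)))
    }
    seq <- fix_unplanned_motifs(seq, built$sp, built$yxy)
    fmt <- function(lst) paste(vapply(lst, function(x) {
      paste0(x[1], "-", x[2])
    }, ""), collapse = ";")
    fmt_reg <- function(lst) paste(vapply(lst, function(x) {
      paste0(x[[1]], ":", x[[2]], "-", x[[3]])
    }, ""), collapse = ";")
    recs[[idx]] <<- data.frame(
      id = id, description = paste0("planted=", label),
      sequence = seq, length = nchar(seq), internal_stop = FALSE,
      stringsAsFactors = FALSE)
    truths[[idx]] <<- data.frame(
      record_id = id, planted_label = label,
      sp_coords = fmt(built$sp), yxy_coords = fmt(built$yxy),
      region_coords = fmt_reg(built$regions), stringsAsFactors = FALSE)
  }

  for (label in names(builders)) {
    for (k in seq_len(spec$n_per_class[[label]])) {
      emit(label, builders[[label]]())
    }
  }
  for (k in seq_len(spec$background_n)) {
    emit("NON_EXT", build_background(env))
  }

  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  truth <- do.call(rbind, c(truths, list(make.row.names = FALSE)))
  if (is.null(records)) {
    records <- read_proteome_empty()
    truth <- data.frame(record_id = character(0),
                        planted_label = character(0),
                        sp_coords = character(0), yxy_coords = character(0),
                        region_coords = character(0),
                        stringsAsFactors = FALSE)
  }
  class(records) <- c("ext_proteome", "data.frame")
  list(records = records, truth = truth)
}

read_proteome_empty <- function() {
  data.frame(id = character(0), description = character(0),
             sequence = character(0), length = integer(0),
             internal_stop = logical(0), stringsAsFactors = FALSE)
}

#' Parse truth coordinate strings back into interval lists
#'
#' @param coords A `sp_coords`/`yxy_coords` string from the truth table.
#' @return Integer matrix with columns start, end (0 rows when empty).
#' @export
parse_truth_coords <- function(coords) {
  if (is.na(coords) || !nzchar(coords)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(coords, ";", fixed = TRUE)[[1]], "-",
                    fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) as.integer(p[1:2])))
  colnames(m) <- c("start", "end")
  m
}
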
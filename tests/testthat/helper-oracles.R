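# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# enumerate every Ser position and extend the proline run by hand
oracle_sp_runs <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  hits <- list()
  for (i in seq_len(n)) {
    if (ch[i] != "S") next
    j <- i
    while (j < n && ch[j + 1L] == "P") j <- j + 1L
    run <- j - i
    if (run >= 3L) {
      hits[[length(hits) + 1L]] <- c(start = i - 1L, end = j, run = run)
    }
  }
  if (length(hits) == 0) {
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("start", "end", "run"))))
  }
  do.call(rbind, hits)
}

oracle_yxy_count <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cnt <- 0L
  for (i in seq_len(max(0L, n - 2L))) {
    if (ch[i] == "Y" && ch[i + 2L] == "Y") cnt <- cnt + 1L
  }
  cnt
}

HRGP6_ORACLE <- c("P", "A", "V", "S", "G", "T")

# covered positions (1-based logical mask) of threshold-passing windows
oracle_hrgp_mask <- function(seq, window = 50L, threshold = 0.6) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  mask <- logical(n)
  if (n < window) {
    if (mean(ch %in% HRGP6_ORACLE) >= threshold) mask[] <- TRUE
    return(mask)
  }
  for (s in seq_len(n - window + 1L)) {
    w <- ch[s:(s + window - 1L)]
    if (mean(w %in% HRGP6_ORACLE) >= threshold) {
      mask[s:(s + window - 1L)] <- TRUE
    }
  }
  mask
}

KD_ORACLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

# mask of positions covered by above-threshold hydropathy windows
oracle_tm_mask <- function(seq, window = 19L, threshold = 1.6) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  mask <- logical(n)
  if (n < window) return(mask)
  vals <- KD_ORACLE[ch]
  vals[is.na(vals)] <- 0
  for (s in seq_len(n - window + 1L)) {
    if (mean(vals[s:(s + window - 1L)]) > threshold) {
      mask[s:(s + window - 1L)] <- TRUE
    }
  }
  mask
}

# full-matrix affine-gap local alignment score; gap of length k costs
# open + k*extend; substitution matrix passed in explicitly
oracle_sw_score <- function(a, b, subst, open = 11, extend = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      s <- H[i - 1, j - 1] + subst[av[i - 1], bv[j - 1]]
      H[i, j] <- max(0, s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

oracle_blosum62x <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  keep <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
            "S","T","W","Y","V","X","*")
  m <- m[keep, keep]
  m["X", ] <- -1; m[, "X"] <- -1
  m["*", ] <- -1; m[, "*"] <- -1
  m
}

random_aa <- function(n, alphabet = c("A","R","N","D","C","Q","E","G","H",
                                      "I","L","K","M","F","P","S","T","W",
                                      "Y","V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# one small shared synthetic run for the heavier integration tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- generator_spec(
        seed = 11,
        n_per_class = stats::setNames(
          rep(2L, 8),
          c("CLASSICAL", "SHORT", "LRX", "PERK", "FH_EXT",
            "LONG_CHIMERIC", "OTHER_CHIMERIC", "POTENTIAL")),
        background_n = 4L)
      cache <<- generate_proteome(spec)
    }
    cache
  }
})

write_fasta_lines <- function(lines) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(lines, fa)
  fa
}
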
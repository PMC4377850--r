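# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# --- folding: exhaustive enumeration of nested structures (<= 12 nt) ------

oracle_pair_energy <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(-3)
  if (key %in% c("AU", "UA")) return(-2)
  if (key %in% c("GU", "UG")) return(-1)
  NA_real_
}

# enumerate every nested structure over seq[i..j] and return the minimum
# total energy (0 = open chain), honouring the minimum loop
oracle_fold_energy <- function(seq, min_loop = 3) {
  b <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  n <- length(b)
  best <- function(i, j) {
    if (i >= j) return(0)
    # option 1: leave i unpaired
    e <- best(i + 1, j)
    # option 2: pair i with some k
    for (k in (i + 1):j) {
      pe <- oracle_pair_energy(b[i], b[k])
      if (!is.na(pe) && k - i - 1 >= min_loop) {
        e <- min(e, pe + best(i + 1, k - 1) + best(k + 1, j))
      }
    }
    e
  }
  if (n < 2) return(0)
  best(1, n)
}

# --- conserved matching: brute-force mismatch counting --------------------

oracle_match <- function(tag, known_seq, max16 = 1, maxtot = 3) {
  a <- strsplit(tag, "")[[1]]
  b <- strsplit(known_seq, "")[[1]]
  m <- min(length(a), length(b))
  mm16 <- 0
  mmtot <- 0
  for (i in seq_len(m)) {
    if (a[i] != b[i]) {
      mmtot <- mmtot + 1
      if (i <= 16) mm16 <- mm16 + 1
    }
  }
  list(ok = mm16 <= max16 && mmtot <= maxtot, mm16 = mm16, mmtot = mmtot)
}

# --- Fisher exact: full hypergeometric enumeration at fixed margins -------

oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- duplex scoring: explicit rule trace (ungapped) -----------------------

oracle_duplex_score <- function(mirna, site, core_lo = 2, core_hi = 13) {
  m <- strsplit(mirna, "")[[1]]
  s <- rev(strsplit(site, "")[[1]])
  stopifnot(length(m) == length(s))
  total <- 0
  for (i in seq_along(m)) {
    pair <- paste0(m[i], s[i])
    pen <- if (pair %in% c("AU", "UA", "GC", "CG")) {
      0
    } else if (pair %in% c("GU", "UG")) {
      0.5
    } else {
      1
    }
    if (i >= core_lo && i <= core_hi) pen <- pen * 2
    total <- total + pen
  }
  total
}

# --- category rules: direct trace of the classification text --------------

oracle_category <- function(vec, site) {
  x <- vec[site]
  if (x == 0) return(NA_integer_)
  if (x == 1) return(4L)
  mx <- max(vec)
  med <- stats::median(vec[vec > 0])
  if (x == mx && sum(vec == mx) == 1) return(0L)
  if (x == mx) return(1L)
  if (x > med && x < mx) return(2L)
  3L
}

# --- random sequence helper ----------------------------------------------

random_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, "")
}

# perfect reverse complement in test code
rc <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}
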
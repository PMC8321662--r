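# Independent oracles used to check the package's own implementations.
# These deliberately share no code with the package internals.

# Type-7 (linear interpolation between order statistics) quantile,
# written from the order-statistic definition.
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# Brute-force two-tier fence classification from first principles.
oracle_classify <- function(x, k_pot = 1.5, k_ext = 3.0) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  iqr <- q3 - q1
  vapply(x, function(v) {
    if (v > q3 + k_ext * iqr || v < q1 - k_ext * iqr) 2L
    else if (v > q3 + k_pot * iqr || v < q1 - k_pot * iqr) 1L
    else 0L
  }, integer(1))
}

# Exhaustive window-enumeration motif scanner: tests every acceptor
# candidate against the constraint table by direct indexing.
oracle_scan <- function(sequence, kind = "full") {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  w <- if (kind == "full") 6L else 4L
  cons <- if (kind == "full") {
    list(`-5` = c("L", "V", "I"), `-3` = "R", `0` = c("S", "T"))
  } else {
    list(`-3` = "R", `0` = c("S", "T"))
  }
  hits <- integer(0)
  for (p in seq_len(n)) {
    if (p < w) next
    ok <- TRUE
    for (o in names(cons)) {
      idx <- p + as.integer(o)
      if (!(chars[idx] %in% cons[[o]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

random_aa_sequence <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}
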
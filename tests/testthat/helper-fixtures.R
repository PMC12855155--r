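# Shared fixture builders.  Everything is generated in code; no files are
# shipped.

# small labelled count matrix
cm <- function(x, sgb = NULL, samp = NULL) {
  m <- as.matrix(x)
  rownames(m) <- sgb %||% sprintf("SGB%02d", seq_len(nrow(m)))
  colnames(m) <- samp %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a fake partition table with the given label counts, in ncm_partition shape
fake_partition <- function(n_above, n_neutral, n_below, prefix = "SGB") {
  n <- n_above + n_neutral + n_below
  data.frame(
    sgb_id = sprintf("%s%04d", prefix, seq_len(n)),
    p = rep(1 / max(n, 1), n),
    F = rep(0.5, n), F_hat = rep(0.5, n),
    lower = rep(0.2, n), upper = rep(0.8, n),
    label = factor(rep(c("above", "neutral", "below"),
                       times = c(n_above, n_neutral, n_below)),
                   levels = c("above", "neutral", "below")),
    stringsAsFactors = FALSE)
}

# independent Wilson interval evaluation, written directly from the score
# interval definition (quadratic in the true proportion); used as an
# oracle against the vectorized implementation
wilson_direct <- function(phat, n, level = 0.95) {
  z <- qnorm((1 + level) / 2)
  center <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, center - half), min(1, center + half))
}

# quadrature of the Beta(a, b) density on [0, d], independent of pbeta.
# For a < 1 the x^(a-1) endpoint singularity is removed analytically by
# the substitution u = x^a before numerical integration.
beta_mass_quad <- function(p, Nm, d) {
  a <- Nm * p
  b <- Nm * (1 - p)
  if (a >= 1) {
    stats::integrate(function(x) dbeta(x, a, b), 0, d,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  } else {
    stats::integrate(function(u) (1 - u^(1 / a))^(b - 1), 0, d^a,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value /
      (a * beta(a, b))
  }
}

# brute-force tandem-run scanner: checks every window of the token list
brute_tandem <- function(classes, min_run = 2) {
  n <- length(classes)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (classes[i] == "CBM") {
      j <- i
      while (j < n && classes[j + 1L] == "CBM") j <- j + 1L
      if (j - i + 1L >= min_run)
        out[[length(out) + 1L]] <- c(start = i - 1L, length = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(out)) as.data.frame(do.call(rbind, out))
  else data.frame(start = integer(), length = integer())
}

# random architecture strings for fuzzing
random_archs <- function(n, seed) {
  withr::with_seed(seed, {
    pool <- c("CBM6", "CBM11", "CBM91", "GH51", "GH43_16", "GH13",
              "PL1", "CE1", "AA3", "SLH", "UNK")
    vapply(seq_len(n), function(i) {
      k <- sample(1:6, 1L)
      paste(sample(pool, k, replace = TRUE),
            collapse = sample(c("+", "|"), 1L))
    }, character(1L))
  })
}
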
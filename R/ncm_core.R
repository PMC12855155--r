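# Sloan neutral community model: occurrence-frequency statistics, Beta-CDF
# expected frequencies, Levenberg-Marquardt fit of the effective immigration
# parameter Nm, Wilson 95% bands and selection partitioning.

#' Prepare neutral-model inputs from a count-matrix slice
#'
#' For one group-timepoint slice the metacommunity relative abundance of
#' SGB i is p_i = sum_j a_ij / sum_ij a_ij (over all SGBs of the slice),
#' and its occurrence frequency F_i is the fraction of animals in which it
#' is detected (raw count >= 1).  The mean community size N is the
#' arithmetic mean of per-sample total counts and the detection limit is
#' d = 1/N.  SGBs undetected in the slice (F_i = 0) carry no occurrence
#' information and are excluded from the fit set; their identifiers are
#' returned in `dropped`.
#'
#' @param slice count matrix restricted to one group-timepoint
#'   (see [slice_group_timepoint()]).
#' @return object of class `ncm_input`: list with `sgb_ids`, `p`, `F`
#'   (fit set only), `n_samples`, `N`, `d`, and `dropped`.
#' @export
prepare_ncm_input <- function(slice) {
  validate_count_matrix(slice)
  if (ncol(slice) < 2L)
    stop("NCM input needs >=2 samples (animals) in the slice", call. = FALSE)
  total <- sum(slice)
  if (total == 0) stop("slice is all zero; cannot form NCM input",
                       call. = FALSE)
  N <- mean(colSums(slice))
  if (N < 2) stop("degenerate slice: mean community size N = ", N,
                  " (< 2 reads)", call. = FALSE)
  p_all <- rowSums(slice) / total
  F_all <- rowMeans(slice >= 1)
  keep <- F_all > 0
  structure(list(
    sgb_ids = rownames(slice)[keep],
    p = unname(p_all[keep]),
    F = unname(F_all[keep]),
    n_samples = ncol(slice),
    N = N,
    d = 1 / N,
    dropped = rownames(slice)[!keep]
  ), class = "ncm_input")
}

#' Neutral expected occurrence frequency
#'
#' Sloan's neutral prediction for the occurrence frequency of a taxon with
#' metacommunity relative abundance p, effective immigration parameter Nm
#' and detection limit d:
#' \deqn{\hat F = 1 - \mathrm{BetaCDF}(d;\ \alpha = Nm\,p,\ \beta = Nm(1-p))}
#'
#' @param p metacommunity relative abundances, strictly inside (0, 1).
#' @param Nm effective immigration parameter (> 0).
#' @param d detection limit in (0, 1), typically 1/N.
#' @return vector of predicted frequencies in \[0, 1\].
#' @export
expected_frequency <- function(p, Nm, d) {
  if (!is.numeric(Nm) || length(Nm) != 1L || !is.finite(Nm) || Nm <= 0)
    stop("Nm must be a single positive number", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || d <= 0 || d >= 1)
    stop("detection limit d must lie in (0, 1)", call. = FALSE)
  if (any(p <= 0) || any(p >= 1))
    stop("abundances p must lie strictly inside (0, 1)", call. = FALSE)
  1 - stats::pbeta(d, shape1 = Nm * p, shape2 = Nm * (1 - p))
}

#' Wilson score interval for occurrence frequencies
#'
#' The 95% (by default) Wilson score band for a binomial proportion with
#' point value `F_hat` observed over `n` animals:
#' center (F + z^2/2n) / (1 + z^2/n), half-width
#' z sqrt(F(1-F)/n + z^2/4n^2) / (1 + z^2/n).  Bounds are clipped to
#' \[0, 1\].
#'
#' @param F_hat proportions in \[0, 1\] (here: model-predicted
#'   frequencies).
#' @param n number of animals the proportion is taken over (>= 2).
#' @param level confidence level, default 0.95.
#' @return list with vectors `lower` and `upper`.
#' @export
wilson_band <- function(F_hat, n, level = 0.95) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("Wilson band requires n >= 2 animals", call. = FALSE)
  if (any(F_hat < 0) || any(F_hat > 1))
    stop("F_hat must lie in [0, 1]", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  denom <- 1 + z^2 / n
  center <- (F_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(F_hat * (1 - F_hat) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Fit the neutral community model to a prepared slice
#'
#' Minimizes the sum of squared differences between observed occurrence
#' frequencies and the Beta-CDF neutral prediction over Nm, using the
#' Levenberg-Marquardt algorithm on log(Nm) (which removes the positivity
#' constraint and conditions the problem).  Four starting values
#' log(Nm) in {2, 4, 6, 8} are tried and the best sum of squares kept; if
#' LM fails from every start, a bounded golden-section search over
#' log(Nm) is used as fallback.  Goodness of fit is the coefficient of
#' determination R^2 = 1 - SS_res/SS_tot, reported unclamped (it can be
#' negative).  The 95% Wilson band around the fitted curve is attached.
#'
#' @param inp `ncm_input` from [prepare_ncm_input()].
#' @param level confidence level for the Wilson band.
#' @param min_sgb minimum size of the fit set (default 10).
#' @param starts starting values for log(Nm).
#' @param init optional single starting value for log(Nm) overriding
#'   `starts` (used to warm-start bootstrap refits).
#' @return object of class `ncm_fit`: list with `Nm`, `r_squared`,
#'   `F_hat`, `band_lower`, `band_upper`, `converged`, `iterations`,
#'   `sse`, plus the input statistics (`n_samples`, `N`, `d`).
#' @export
fit_ncm <- function(inp, level = 0.95, min_sgb = 10,
                    starts = c(2, 4, 6, 8), init = NULL) {
  stopifnot(inherits(inp, "ncm_input"))
  F_obs <- inp$F
  p <- inp$p
  if (length(F_obs) < min_sgb)
    stop("fit set has ", length(F_obs), " SGBs; floor is ", min_sgb,
         call. = FALSE)
  d <- inp$d
  resid_fun <- function(theta) F_obs - expected_frequency(p, exp(theta), d)
  sse_fun <- function(theta) sum(resid_fun(theta)^2)
  if (!is.null(init)) starts <- init

  best <- NULL
  for (theta0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = list(theta = theta0),
                         fn = function(par) resid_fun(par$theta),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- fit$deviance
    if (is.null(best) || sse < best$sse)
      best <- list(theta = fit$par$theta, sse = sse,
                   iterations = fit$niter, converged = fit$info %in% 1:4)
  }
  if (is.null(best)) {
    # golden-section fallback on log(Nm)
    opt <- stats::optimize(sse_fun, interval = c(-5, 30), tol = 1e-10)
    best <- list(theta = opt$minimum, sse = opt$objective,
                 iterations = NA_integer_, converged = TRUE)
  }

  Nm <- exp(best$theta)
  F_hat <- expected_frequency(p, Nm, d)
  ss_tot <- sum((F_obs - mean(F_obs))^2)
  if (ss_tot == 0) {
    warning("all observed frequencies identical; R^2 undefined")
    r2 <- NaN
  } else {
    r2 <- 1 - best$sse / ss_tot
  }
  band <- wilson_band(F_hat, inp$n_samples, level = level)
  structure(list(
    Nm = Nm, r_squared = r2, F_hat = F_hat,
    band_lower = band$lower, band_upper = band$upper,
    converged = best$converged, iterations = best$iterations,
    sse = best$sse, level = level,
    n_samples = inp$n_samples, N = inp$N, d = d,
    sgb_ids = inp$sgb_ids
  ), class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  SGBs fitted: %d over %d animals (N = %.1f reads, d = %.3g)\n",
              length(x$F_hat), x$n_samples, x$N, x$d))
  cat(sprintf("  Nm = %.1f,  R^2 = %.4f  (converged: %s)\n",
              x$Nm, x$r_squared, x$converged))
  invisible(x)
}

#' Partition SGBs relative to the neutral prediction
#'
#' Labels each fitted SGB by where its observed occurrence frequency falls
#' relative to the 95% Wilson band around the neutral curve: strictly
#' above the upper bound = `above` (positive selection), strictly below
#' the lower bound = `below` (negative selection), otherwise `neutral`
#' (stochastic assembly).  Frequencies exactly on a bound are neutral.
#'
#' @param inp `ncm_input` the fit was prepared from.
#' @param fit matching `ncm_fit`.
#' @return object of class `ncm_partition`: data frame with columns
#'   `sgb_id`, `p`, `F`, `F_hat`, `lower`, `upper`, `label`, plus a
#'   `proportions` attribute giving the above/neutral/below fractions.
#' @export
classify_partitions <- function(inp, fit) {
  stopifnot(inherits(inp, "ncm_input"), inherits(fit, "ncm_fit"))
  if (!isTRUE(fit$converged))
    stop("cannot partition on a non-converged fit", call. = FALSE)
  if (length(inp$F) != length(fit$F_hat))
    stop("input and fit describe different SGB sets", call. = FALSE)
  label <- ifelse(inp$F > fit$band_upper, "above",
                  ifelse(inp$F < fit$band_lower, "below", "neutral"))
  out <- data.frame(
    sgb_id = inp$sgb_ids,
    p = inp$p,
    F = inp$F,
    F_hat = fit$F_hat,
    lower = fit$band_lower,
    upper = fit$band_upper,
    label = factor(label, levels = c("above", "neutral", "below")),
    stringsAsFactors = FALSE
  )
  prop <- prop.table(table(out$label))
  attr(out, "proportions") <- c(above = unname(prop["above"]),
                                neutral = unname(prop["neutral"]),
                                below = unname(prop["below"]))
  class(out) <- c("ncm_partition", "data.frame")
  out
}

#' Fit and partition one slice in a single call
#'
#' Convenience wrapper: [prepare_ncm_input()] + [fit_ncm()] +
#' [classify_partitions()].
#'
#' @inheritParams prepare_ncm_input
#' @inheritParams fit_ncm
#' @return list with `input`, `fit` and `partition`.
#' @export
ncm_analyze_slice <- function(slice, level = 0.95, min_sgb = 10) {
  inp <- prepare_ncm_input(slice)
  fit <- fit_ncm(inp, level = level, min_sgb = min_sgb)
  list(input = inp, fit = fit, partition = classify_partitions(inp, fit))
}
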
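# Animal-level bootstrap for Nm and R^2, DerSimonian-Laird random-effects
# pooling across timepoints, and whole-study orchestration.

#' Animal-level bootstrap of a neutral-model fit
#'
#' Resamples the animal columns of a slice with replacement (keeping the
#' SGB set fixed), recomputes p, F, N and d from each resample and
#' refits the model.  Replicates where the resample has fewer than
#' `min_sgb` fittable SGBs, or where the fit does not converge, are
#' dropped and counted.  Refits are warm-started from the full-data
#' estimate of log(Nm).
#'
#' @param slice count matrix for one group-timepoint.
#' @param B number of bootstrap replicates (study default 1000).
#' @param seed integer seed; the replicate column draws are fully
#'   determined by it.
#' @param min_sgb minimum fit-set size per replicate.
#' @return list with two `ncm_bootstrap` objects, `Nm` and `r_squared`,
#'   each holding `statistic`, `estimate` (full-data value),
#'   `replicates`, `ci` (percentile 95%), `se`, `n_failed`, `seed`, and
#'   `failed_flag` (TRUE when more than 20% of replicates failed).
#' @export
bootstrap_ncm <- function(slice, B = 1000, seed = 1L, min_sgb = 10) {
  validate_count_matrix(slice)
  inp0 <- prepare_ncm_input(slice)
  fit0 <- fit_ncm(inp0, min_sgb = min_sgb)
  theta0 <- log(fit0$Nm)
  n <- ncol(slice)

  draws <- withr::with_seed(seed, {
    matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B)
  })
  nm <- r2 <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    res <- tryCatch({
      sub <- slice[, draws[, b], drop = FALSE]
      colnames(sub) <- sprintf("rep%03d", seq_len(n))
      inp <- prepare_ncm_input(sub)
      fit <- fit_ncm(inp, min_sgb = min_sgb, init = theta0)
      if (!isTRUE(fit$converged)) NULL else c(fit$Nm, fit$r_squared)
    }, error = function(e) NULL)
    if (!is.null(res)) { nm[b] <- res[1L]; r2[b] <- res[2L] }
  }

  mk <- function(name, est, reps) {
    keep <- reps[!is.na(reps)]
    n_failed <- B - length(keep)
    ci <- if (length(keep)) unname(stats::quantile(keep, c(0.025, 0.975),
                                                   type = 7))
          else c(NA_real_, NA_real_)
    structure(list(
      statistic = name, estimate = est, replicates = keep,
      ci = ci, se = if (length(keep) > 1) stats::sd(keep) else 0,
      n_failed = n_failed, B = B, seed = seed,
      failed_flag = n_failed > 0.2 * B
    ), class = "ncm_bootstrap")
  }
  out <- list(Nm = mk("Nm", fit0$Nm, nm),
              r_squared = mk("r_squared", fit0$r_squared, r2))
  if (out$Nm$failed_flag)
    warning("more than 20% of bootstrap replicates failed")
  out
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-timepoint estimates y_k with variances v_k: fixed-effect
#' weights w_k = 1/v_k give Q = sum w_k (y_k - y_FE)^2 and the moment
#' estimator tau^2 = max(0, (Q - (K-1)) / (sum w - sum w^2 / sum w));
#' random-effects weights 1/(v_k + tau^2) then give the pooled mean, its
#' SE and a normal-theory 95% CI.  With `scale = "log"` the inputs are
#' taken to be log-scale estimates (with log-scale variances) and the
#' pooled value and CI are exponentiated for reporting.
#'
#' @param estimates per-timepoint estimates (log-scale when
#'   `scale = "log"`).
#' @param variances per-timepoint squared standard errors, same scale.
#' @param scale `"linear"` or `"log"`.
#' @param level confidence level, default 0.95.
#' @return object of class `pooled_estimate`: list with `pooled`,
#'   `ci`, `se`, `tau_squared`, `Q`, `k`, `scale`, `method` ("DL"),
#'   per-timepoint `estimates`/`variances`, and (log scale) the pooled
#'   log-scale value `pooled_log`.
#' @export
pool_random_effects <- function(estimates, variances,
                                scale = c("linear", "log"),
                                level = 0.95) {
  scale <- match.arg(scale)
  k <- length(estimates)
  if (k < 1L) stop("need >= 1 estimate to pool", call. = FALSE)
  if (length(variances) != k)
    stop("estimates and variances differ in length", call. = FALSE)
  if (any(!is.finite(estimates)) || any(!is.finite(variances)) ||
      any(variances <= 0))
    stop("estimates must be finite and variances positive", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  note <- NULL
  if (k == 1L) {
    tau2 <- 0; Q <- 0
    mu <- estimates; se <- sqrt(variances)
    note <- "no heterogeneity estimable from a single timepoint"
  } else {
    w <- 1 / variances
    mu_fe <- sum(w * estimates) / sum(w)
    Q <- sum(w * (estimates - mu_fe)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (variances + tau2)
    mu <- sum(wr * estimates) / sum(wr)
    se <- sqrt(1 / sum(wr))
  }
  ci <- c(mu - z * se, mu + z * se)
  out <- list(pooled = mu, ci = ci, se = se, tau_squared = tau2, Q = Q,
              k = k, scale = scale, method = "DL",
              estimates = estimates, variances = variances, note = note)
  if (scale == "log") {
    out$pooled_log <- mu
    out$ci_log <- ci
    out$pooled <- exp(mu)
    out$ci <- exp(ci)
  }
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Random-effects (%s) pooled estimate over %d timepoint(s), %s scale\n",
    x$method, x$k, x$scale))
  cat(sprintf("  pooled = %.4g [95%% CI %.4g-%.4g], tau^2 = %.4g\n",
              x$pooled, x$ci[1], x$ci[2], x$tau_squared))
  invisible(x)
}

#' Run the full per-group neutral-model study
#'
#' For every feed-efficiency group x timepoint cell present in the
#' metadata: slice the count matrix, fit the neutral model, partition the
#' SGBs, and bootstrap Nm and R^2 at the animal level.  Per group, the
#' four (or fewer) timepoint estimates are then pooled by
#' DerSimonian-Laird random effects — Nm on the log scale (bootstrap SE
#' of log Nm from the log replicates), R^2 on the linear scale with the
#' reported CI clipped at 1.  Slices failing their preconditions are
#' recorded as skipped and the study continues.
#'
#' @param counts full study count matrix.
#' @param metadata validated sample metadata.
#' @param B bootstrap replicates per slice (study default 1000).
#' @param seed integer master seed.
#' @param min_sgb minimum fit-set size.
#' @param level confidence level for bands and intervals.
#' @return object of class `ncm_study`: list with `slices` (per-cell fit,
#'   partition and bootstraps), `pooled` (per group: `Nm` and
#'   `r_squared` pooled estimates), `skipped`, and the call parameters.
#' @export
run_ncm_study <- function(counts, metadata, B = 1000, seed = 1L,
                          min_sgb = 10, level = 0.95) {
  validate_count_matrix(counts)
  metadata <- validate_sample_metadata(metadata)
  groups <- intersect(FE_LEVELS, unique(metadata$fe_group))
  tps <- intersect(TIMEPOINT_LEVELS, unique(metadata$timepoint))
  if (!length(groups) || !length(tps))
    stop("metadata defines no group/timepoint cells", call. = FALSE)

  slices <- list(); skipped <- list(); pooled <- list()
  idx <- 0L
  for (g in groups) {
    nm_est <- nm_var <- r2_est <- r2_var <- numeric()
    for (tp in tps) {
      idx <- idx + 1L
      key <- paste(g, tp, sep = ".")
      sub_seed <- as.integer((as.double(seed) * 2003 +
                                idx * 5003) %% 2147483629)
      res <- tryCatch({
        sl <- slice_group_timepoint(counts, metadata, g, tp)
        inp <- prepare_ncm_input(sl)
        fit <- fit_ncm(inp, level = level, min_sgb = min_sgb)
        part <- classify_partitions(inp, fit)
        boot <- bootstrap_ncm(sl, B = B, seed = sub_seed,
                              min_sgb = min_sgb)
        list(input = inp, fit = fit, partition = part, bootstrap = boot)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[key]] <- conditionMessage(res)
        next
      }
      slices[[key]] <- res
      log_reps <- log(res$bootstrap$Nm$replicates)
      nm_est <- c(nm_est, log(res$fit$Nm))
      nm_var <- c(nm_var, max(stats::var(log_reps), 1e-12, na.rm = TRUE))
      r2_est <- c(r2_est, res$fit$r_squared)
      r2_var <- c(r2_var, max(res$bootstrap$r_squared$se^2, 1e-12))
    }
    if (length(nm_est)) {
      p_nm <- pool_random_effects(nm_est, nm_var, scale = "log",
                                  level = level)
      p_r2 <- pool_random_effects(r2_est, r2_var, scale = "linear",
                                  level = level)
      p_r2$ci <- pmin(p_r2$ci, 1)
      pooled[[g]] <- list(Nm = p_nm, r_squared = p_r2)
    }
  }
  structure(list(slices = slices, pooled = pooled, skipped = skipped,
                 B = B, seed = seed, level = level, min_sgb = min_sgb),
            class = "ncm_study")
}

#' @export
print.ncm_study <- function(x, ...) {
  cat("Neutral community model study report\n")
  cat(sprintf("  %d slice(s) analyzed, %d skipped, B = %d\n",
              length(x$slices), length(x$skipped), x$B))
  for (g in names(x$pooled)) {
    nm <- x$pooled[[g]]$Nm; r2 <- x$pooled[[g]]$r_squared
    cat(sprintf(
      "  %s: Nm = %.0f [95%% CI %.0f-%.0f];  R^2 = %.3f [95%% CI %.3f-%.3f]\n",
      g, nm$pooled, nm$ci[1], nm$ci[2],
      r2$pooled, r2$ci[1], r2$ci[2]))
  }
  invisible(x)
}

#' Serialize a study report to tidy tables and JSON
#'
#' Writes per-slice partition TSVs
#' (`<prefix>_partition_<GROUP>_<TP>.tsv`), a pooled-summary JSON
#' (`<prefix>_pooled.json`) and a run manifest.
#'
#' @param study `ncm_study` object.
#' @param prefix output path prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_ncm_study <- function(study, prefix) {
  stopifnot(inherits(study, "ncm_study"))
  paths <- character()
  for (key in names(study$slices)) {
    part <- study$slices[[key]]$partition
    path <- paste0(prefix, "_partition_", gsub("\\.", "_", key), ".tsv")
    utils::write.table(as.data.frame(part), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  pooled <- lapply(study$pooled, function(g) {
    lapply(g, function(p) list(
      pooled = p$pooled, ci_lower = p$ci[1], ci_upper = p$ci[2],
      tau_squared = p$tau_squared, k = p$k, scale = p$scale,
      method = p$method))
  })
  jpath <- paste0(prefix, "_pooled.json")
  jsonlite::write_json(pooled, jpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  mpath <- paste0(prefix, "_manifest.json")
  write_run_manifest(mpath, "run-study",
                     params = list(B = study$B, level = study$level,
                                   min_sgb = study$min_sgb),
                     seed = study$seed)
  invisible(c(paths, jpath, mpath))
}
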
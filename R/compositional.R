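# Compositional statistics: centered log-ratio transform (base 2),
# Aitchison distance, and CLR-difference log2 fold changes with bootstrap
# confidence intervals.

#' Centered log-ratio transform (base 2)
#'
#' Per sample, x = counts + pseudocount and CLR = log2(x) - mean(log2(x)).
#' Base 2 is used so that a difference of CLR means between groups is
#' directly a log2 fold change.  A pseudocount of 0 is only permitted
#' when the matrix contains no zeros.
#'
#' @param counts count matrix (features x samples).
#' @param pseudocount non-negative offset added to every cell (default 1).
#' @return matrix of CLR values with the same dimnames; each column sums
#'   to zero.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  validate_count_matrix(counts)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount == 0 && any(counts == 0))
    stop("pseudocount 0 requires a zero-free count matrix", call. = FALSE)
  lx <- log2(counts + pseudocount)
  sweep(lx, 2L, colMeans(lx), "-")
}

#' Aitchison distance matrix
#'
#' Pairwise Euclidean distances between sample columns of a CLR matrix —
#' the Aitchison distance of the underlying compositions.
#'
#' @param clr CLR matrix from [clr_transform()].
#' @return `dist` object over samples.
#' @export
aitchison_distance <- function(clr) {
  if (ncol(clr) < 2L) stop("need >= 2 samples", call. = FALSE)
  stats::dist(t(clr), method = "euclidean")
}

#' CLR-difference log2 fold changes with bootstrap intervals
#'
#' Per feature, log2FC = mean(CLR | group2) - mean(CLR | group1), where
#' group1 is the reference (first level, lexicographic unless `ref` is
#' given).  The 95% CI is a percentile bootstrap resampling samples
#' within each group; when metadata with animal identifiers is supplied,
#' resampling can instead be blocked on animals to respect the
#' repeated-measures design.
#'
#' @param clr CLR matrix (features x samples).
#' @param groups two-level factor/character vector over the samples.
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param ref optional reference level (defaults to the first
#'   lexicographic level).
#' @param blocks optional per-sample block labels (e.g. animal IDs):
#'   resampling then draws blocks with replacement within group, taking
#'   all samples of a drawn block.
#' @param level confidence level, default 0.95.
#' @return data frame of class `clr_effect`: `feature_id`, `log2fc`,
#'   `ci_lower`, `ci_upper`, `n_boot`, plus attributes `ref` and
#'   `ci_defined` (FALSE when a group has a single resampling unit).
#' @export
clr_log2fc <- function(clr, groups, B = 1000, seed = 1L, ref = NULL,
                       blocks = NULL, level = 0.95) {
  groups <- as.character(groups)
  if (length(groups) != ncol(clr))
    stop("groups must label every sample column", call. = FALSE)
  lev <- sort(unique(groups))
  if (length(lev) != 2L)
    stop("exactly two group levels required", call. = FALSE)
  if (is.null(ref)) ref <- lev[1L]
  if (!ref %in% lev) stop("unknown reference level ", ref, call. = FALSE)
  other <- setdiff(lev, ref)
  i1 <- which(groups == ref); i2 <- which(groups == other)

  unit1 <- if (is.null(blocks)) as.list(i1) else split(i1, blocks[i1])
  unit2 <- if (is.null(blocks)) as.list(i2) else split(i2, blocks[i2])
  ci_defined <- length(unit1) > 1L && length(unit2) > 1L
  if (!ci_defined)
    warning("a group has a single resampling unit; bootstrap CI undefined")

  est <- rowMeans(clr[, i2, drop = FALSE]) -
    rowMeans(clr[, i1, drop = FALSE])

  lo <- hi <- rep(NA_real_, nrow(clr))
  if (ci_defined && B > 0) {
    reps <- withr::with_seed(seed, {
      r <- matrix(NA_real_, nrow = nrow(clr), ncol = B)
      for (b in seq_len(B)) {
        j1 <- unlist(unit1[sample.int(length(unit1), replace = TRUE)])
        j2 <- unlist(unit2[sample.int(length(unit2), replace = TRUE)])
        r[, b] <- rowMeans(clr[, j2, drop = FALSE]) -
          rowMeans(clr[, j1, drop = FALSE])
      }
      r
    })
    qs <- apply(reps, 1L, stats::quantile,
                probs = c((1 - level) / 2, (1 + level) / 2), type = 7)
    lo <- qs[1L, ]; hi <- qs[2L, ]
  }
  out <- data.frame(feature_id = rownames(clr), log2fc = unname(est),
                    ci_lower = unname(lo), ci_upper = unname(hi),
                    n_boot = if (ci_defined) B else 0L,
                    stringsAsFactors = FALSE)
  attr(out, "ref") <- ref
  attr(out, "ci_defined") <- ci_defined
  class(out) <- c("clr_effect", "data.frame")
  out
}
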
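# animal-level bootstrap, DerSimonian-Laird pooling, study orchestration

test_that("bootstrap is seed-deterministic and degenerates correctly", {
  sim <- simulate_neutral_slice(300, 8, 2000, depth_mean = 2e4, seed = 1)
  b1 <- bootstrap_ncm(sim$counts, B = 25, seed = 42)
  b2 <- bootstrap_ncm(sim$counts, B = 25, seed = 42)
  expect_identical(b1$Nm$replicates, b2$Nm$replicates)
  b3 <- bootstrap_ncm(sim$counts, B = 25, seed = 43)
  expect_false(identical(b1$Nm$replicates, b3$Nm$replicates))
  expect_true(b1$Nm$ci[1] <= b1$Nm$ci[2])

  # identical columns: every resample is the same matrix, so the
  # replicate distribution of Nm collapses to a point
  one <- simulate_neutral_slice(60, 2, 500, depth_mean = 2000, seed = 5)
  dup <- one$counts[, c(1, 1, 1, 1, 1)]
  colnames(dup) <- sprintf("S%02d", 1:5)
  bd <- suppressWarnings(bootstrap_ncm(dup, B = 10, seed = 1))
  expect_equal(diff(bd$Nm$ci), 0)
  expect_equal(bd$Nm$se, 0)
})

test_that("DerSimonian-Laird pooling matches a hand-computed example", {
  # two timepoints, worked by hand from the moment estimator
  y <- c(1, 3); v <- c(0.5, 0.25)
  w <- 1 / v                       # 2, 4
  mu_fe <- sum(w * y) / sum(w)     # 14/6
  Q <- sum(w * (y - mu_fe)^2)      # 2*(1-7/3)^2 + 4*(3-7/3)^2
  tau2 <- max(0, (Q - 1) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  mu <- sum(wr * y) / sum(wr)
  se <- sqrt(1 / sum(wr))
  got <- pool_random_effects(y, v)
  expect_equal(got$pooled, mu, tolerance = 1e-12)
  expect_equal(got$tau_squared, tau2, tolerance = 1e-12)
  expect_equal(got$se, se, tolerance = 1e-12)
  expect_equal(got$ci, c(mu - qnorm(0.975) * se, mu + qnorm(0.975) * se),
               tolerance = 1e-12)
  # independent cross-check against the reference meta-analysis package
  ref <- metafor::rma(yi = y, vi = v, method = "DL")
  expect_equal(got$pooled, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(got$tau_squared, ref$tau2, tolerance = 1e-10)
})

test_that("pooling contracts: homogeneity, K = 1, symmetry, log scale", {
  eq <- pool_random_effects(rep(10, 4), rep(0.2, 4))
  expect_equal(eq$pooled, 10)
  expect_equal(eq$tau_squared, 0)

  k1 <- pool_random_effects(0.78, 0.01)
  expect_equal(k1$pooled, 0.78)
  expect_equal(k1$ci, 0.78 + c(-1, 1) * qnorm(0.975) * 0.1,
               tolerance = 1e-12)
  expect_match(k1$note, "single timepoint")

  sym <- pool_random_effects(c(1, 3), c(0.3, 0.3))
  expect_equal(sym$pooled, 2)

  lg <- pool_random_effects(log(c(5e3, 2e4, 1e4)), c(0.05, 0.08, 0.06),
                            scale = "log")
  expect_gte(lg$pooled, 5e3)
  expect_lte(lg$pooled, 2e4)
  expect_equal(lg$pooled, exp(lg$pooled_log))

  expect_error(pool_random_effects(c(1, 2), 0.1), "length")
  expect_error(pool_random_effects(c(1, 2), c(0.1, 0)), "positive")
})

test_that("bootstrap intervals narrow with more animals", {
  width <- function(n) {
    med <- vapply(1:3, function(s) {
      sim <- simulate_neutral_slice(400, n, 2000, depth_mean = 2e4,
                                    seed = 100 + s)
      bt <- bootstrap_ncm(sim$counts, B = 60, seed = s)
      diff(log(bt$Nm$ci))
    }, numeric(1))
    median(med)
  }
  expect_lt(width(20), width(5))
})

test_that("the study runner fits, partitions and pools every cell", {
  study <- simulate_study(n_animals_per_cell = 6, n_sgb = 300,
                          Nm_by_group = c(HFE = 2000, LFE = 2000),
                          depth_mean = 2e4, seed = 77)
  rep <- run_ncm_study(study$counts, study$metadata, B = 20, seed = 5)
  expect_length(rep$slices, 8)
  expect_length(rep$skipped, 0)
  expect_named(rep$pooled, c("HFE", "LFE"))
  for (g in c("HFE", "LFE")) {
    nm <- rep$pooled[[g]]$Nm
    per_tp <- exp(nm$estimates)
    expect_gte(nm$pooled, min(per_tp))
    expect_lte(nm$pooled, max(per_tp))
    expect_lte(rep$pooled[[g]]$r_squared$ci[2], 1)
  }

  # a cell whose samples are missing is skipped, not fatal
  md <- study$metadata[!(study$metadata$fe_group == "LFE" &
                           study$metadata$timepoint == "D180"), ]
  cnt <- study$counts[, md$sample_id]
  rep2 <- run_ncm_study(cnt, md, B = 10, seed = 5)
  expect_length(rep2$slices, 7)
  expect_named(rep2$skipped, "LFE.D180")
})

test_that("study outputs are written and the pooled JSON is reproducible", {
  study <- simulate_study(n_animals_per_cell = 5, timepoints = "D1",
                          n_sgb = 200, depth_mean = 1e4, seed = 13)
  dir <- withr::local_tempdir()
  rep1 <- run_ncm_study(study$counts, study$metadata, B = 10, seed = 2)
  rep2 <- run_ncm_study(study$counts, study$metadata, B = 10, seed = 2)
  p1 <- file.path(dir, "a"); p2 <- file.path(dir, "b")
  write_ncm_study(rep1, p1)
  write_ncm_study(rep2, p2)
  expect_identical(readLines(paste0(p1, "_pooled.json")),
                   readLines(paste0(p2, "_pooled.json")))
  expect_true(file.exists(paste0(p1, "_partition_HFE_D1.tsv")))
  part <- read.delim(paste0(p1, "_partition_HFE_D1.tsv"))
  expect_true(all(c("sgb_id", "p", "F", "F_hat", "lower", "upper",
                    "label") %in% colnames(part)))
})
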
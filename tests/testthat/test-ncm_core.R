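# neutral-model statistics, expected-frequency curve, fit, Wilson band,
# partitioning

test_that("slice statistics follow their definitions", {
  m <- cm(rbind(c(2, 3), c(0, 5)))
  inp <- prepare_ncm_input(m)
  expect_equal(inp$p, c(0.5, 0.5))
  expect_equal(inp$F, c(1.0, 0.5))
  expect_equal(inp$N, 5)
  expect_equal(inp$d, 0.2)
  expect_length(inp$dropped, 0)

  single <- prepare_ncm_input(cm(rbind(c(3, 4))))
  expect_equal(single$p, 1.0)

  withzero <- prepare_ncm_input(cm(rbind(c(2, 3), c(0, 0), c(1, 1))))
  expect_equal(withzero$dropped, "SGB02")
  expect_length(withzero$p, 2)
  # dropped rows are all-zero, so they carry no abundance mass
  expect_lte(sum(withzero$p), 1)
  expect_equal(withzero$p, c(5, 2) / 7)

  expect_error(prepare_ncm_input(cm(rbind(c(0, 0)))), "all zero")
  expect_error(prepare_ncm_input(cm(rbind(c(5, 5)))[, 1, drop = FALSE]),
               ">=2 samples")
})

test_that("expected frequency matches closed forms and quadrature", {
  # Nm = 2, p = 0.5 makes Beta(1, 1): uniform, so F = 1 - d
  expect_equal(expected_frequency(0.5, 2, 0.01), 0.99)
  # d -> 0 limit
  expect_gt(expected_frequency(0.3, 50, 1e-12), 1 - 1e-9)
  # quadrature oracle on the Beta density
  quad <- function(p, Nm, d) {
    dens <- function(x) dbeta(x, Nm * p, Nm * (1 - p))
    1 - integrate(dens, 0, d, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }
  expect_equal(expected_frequency(0.001, 200, 1e-4),
               quad(0.001, 200, 1e-4), tolerance = 1e-8)
  expect_error(expected_frequency(c(0, 0.5), 10, 0.01), "strictly inside")
})

test_that("expected frequency is monotone in p and in the detection limit", {
  # grids kept off the saturated tail where the curve is 1 to machine
  # precision
  d <- 1e-4
  p_grid <- 10^seq(-6, -3, length.out = 40)
  f <- expected_frequency(p_grid, 1000, d)
  expect_true(all(diff(f) > 0))
  d_grid <- 10^seq(-5, -2, length.out = 30)
  fd <- vapply(d_grid, function(dd) expected_frequency(0.001, 1000, dd),
               numeric(1))
  expect_true(all(diff(fd) < 0))
  # for taxa above the detection limit, larger Nm tightens occupancy up
  nm_grid <- 10^seq(1, 4, length.out = 30)
  fn <- vapply(nm_grid, function(nm) expected_frequency(2e-4, nm, 1e-4),
               numeric(1))
  expect_true(all(diff(fn) > 0))
})

test_that("Wilson band equals the direct score-interval evaluation", {
  grid <- expand.grid(phat = c(0, 0.01, 0.1, 0.25, 0.5, 0.77, 0.95, 1),
                      n = c(2, 5, 10, 30))
  for (i in seq_len(nrow(grid))) {
    got <- wilson_band(grid$phat[i], grid$n[i])
    want <- wilson_direct(grid$phat[i], grid$n[i])
    expect_equal(c(got$lower, got$upper), want, tolerance = 1e-12)
  }
  b <- wilson_band(0.5, 10)
  expect_equal(round(c(b$lower, b$upper), 4), c(0.2366, 0.7634))
  b0 <- wilson_band(0, 10)
  expect_equal(b0$lower, 0)
  expect_equal(round(b0$upper, 4), 0.2775)
  b1 <- wilson_band(1, 10)  # mirror of the p-hat = 0 case
  expect_equal(b1$upper, 1)
  expect_equal(b1$lower, 1 - b0$upper, tolerance = 1e-12)
  expect_error(wilson_band(0.5, 1), "n >= 2")
})

test_that("noise-free input recovers Nm exactly with R^2 = 1", {
  set.seed(404)
  raw <- rlnorm(400, 0, 2)
  p <- raw / sum(raw)
  d <- 1e-5
  inp <- structure(list(sgb_ids = sprintf("s%d", 1:400), p = p,
                        F = expected_frequency(p, 5000, d),
                        n_samples = 10, N = 1 / d, d = d),
                   class = "ncm_input")
  fit <- fit_ncm(inp)
  expect_lt(abs(fit$Nm - 5000) / 5000, 0.001)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$converged)
  expect_true(all(fit$band_lower <= fit$F_hat + 1e-12) &&
                all(fit$F_hat <= fit$band_upper + 1e-12))
})

test_that("R^2 is undefined for constant frequencies and never exceeds 1", {
  inp <- structure(list(sgb_ids = sprintf("s%d", 1:20),
                        p = rep(1 / 20, 20), F = rep(0.5, 20),
                        n_samples = 10, N = 1000, d = 1e-3),
                   class = "ncm_input")
  expect_warning(fit <- fit_ncm(inp), "identical")
  expect_true(is.nan(fit$r_squared))

  sim <- simulate_neutral_slice(300, 6, 2000, depth_mean = 2e4, seed = 12)
  fit2 <- fit_ncm(prepare_ncm_input(sim$counts))
  expect_lte(fit2$r_squared, 1)
})

test_that("fit refuses slices below the SGB floor", {
  m <- cm(matrix(5, 4, 3))
  inp <- prepare_ncm_input(m)
  expect_error(fit_ncm(inp), "floor")
})

test_that("partition labels follow the strict band inequalities", {
  inp <- structure(list(sgb_ids = c("a", "b", "c"),
                        p = c(0.2, 0.3, 0.5), F = c(0.9, 0.8, 0.1),
                        n_samples = 10, N = 1000, d = 1e-3),
                   class = "ncm_input")
  fit <- structure(list(F_hat = c(0.5, 0.5, 0.5),
                        band_lower = c(0.2, 0.2, 0.2),
                        band_upper = c(0.8, 0.8, 0.8),
                        converged = TRUE), class = "ncm_fit")
  part <- classify_partitions(inp, fit)
  expect_equal(as.character(part$label), c("above", "neutral", "below"))
  expect_equal(sum(attr(part, "proportions")), 1)
})

test_that("dropped SGBs never reach the partition table", {
  sim <- simulate_neutral_slice(500, 8, 1000, depth_mean = 5000, seed = 33)
  res <- ncm_analyze_slice(sim$counts)
  expect_length(intersect(res$partition$sgb_id, res$input$dropped), 0)
  expect_equal(nrow(res$partition), length(res$input$F))
})
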
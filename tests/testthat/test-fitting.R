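# hand-built distribution with exactly exponential bin densities
exact_exp_dist <- function(pi = 20, bin_width = 5, n_bins = 20,
                           counts = 100L) {
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(edges = edges, mids = mids,
                 counts = rep(counts, n_bins),
                 density = exp(-mids / pi) / pi, n = n_bins * counts,
                 bin_width = bin_width),
            class = "area_distribution")
}

test_that("binning counts, normalizes and keeps empty bins", {
  d <- build_distribution(c(10, 10, 30), bin_width = 20)
  expect_equal(d$counts, c(2L, 1L))
  expect_equal(d$density, c(2, 1) / (3 * 20))
  expect_equal(sum(d$density * d$bin_width), 1)

  d1 <- build_distribution(42, bin_width = 5)
  expect_equal(sum(d1$density * d1$bin_width), 1)
  expect_equal(sum(d1$counts > 0), 1)
  # empty bins below the single occupied one are retained
  expect_gt(length(d1$counts), 5)

  expect_error(build_distribution(numeric()), "no defect areas")
  expect_error(build_distribution(10, bin_width = 0), "positive")
})

test_that("large samples reproduce the analytic bin masses", {
  set.seed(42)
  a <- rexp(1e5, 1 / 20)
  d <- build_distribution(a, 5)
  sel <- which(d$edges[-1] <= 100)
  p_true <- exp(-d$edges[sel] / 20) - exp(-d$edges[sel + 1] / 20)
  p_hat <- d$counts[sel] / d$n
  sigma <- sqrt(p_true * (1 - p_true) / d$n)
  expect_true(all(abs(p_hat - p_true) < 3 * sigma + 1e-12))
})

test_that("exact exponential densities are fitted to machine precision", {
  d <- exact_exp_dist(pi = 20)
  f <- fit_pi(d, c(0, 100))
  expect_equal(f$pi, 20, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_lt(f$pi_stderr, 1e-6)
  expect_true(f$diagnostics$pass)
})

test_that("a perturbed bin lowers R^2 but barely moves pi", {
  d <- exact_exp_dist(pi = 20)
  d$density[8] <- d$density[8] * exp(1)
  f <- fit_pi(d, c(0, 100))
  expect_lt(f$r_squared, 1)
  expect_lt(abs(f$pi - 20) / 20, 0.1)
})

test_that("fit errors are informative", {
  d <- exact_exp_dist(pi = 20, n_bins = 20)
  d$counts[5:20] <- 0L  # only 4 usable bins below 20 A^2... then restrict
  expect_error(fit_pi(d, c(0, 9)), "fewer than 3")
  # growing distribution
  d2 <- exact_exp_dist(pi = 20)
  d2$density <- rev(d2$density)
  expect_error(fit_pi(d2, c(0, 100)), "not decaying")
})

test_that("pi is scale-equivariant and normalization-invariant", {
  set.seed(7)
  a <- rexp(5000, 1 / 20)
  f1 <- fit_pi(build_distribution(a, 5), c(15, 80))
  f2 <- fit_pi(build_distribution(3 * a, 15), c(45, 240))
  expect_equal(f2$pi / f1$pi, 3, tolerance = 1e-6)

  d <- build_distribution(a, 5)
  d$density <- d$density * 7.3   # un-normalized input
  f3 <- fit_pi(d, c(15, 80))
  expect_equal(f3$pi, f1$pi, tolerance = 1e-9)
})

test_that("window selection respects the floor and recovers pi", {
  set.seed(11)
  a <- rexp(20000, 1 / 20)
  f <- select_window(build_distribution(a, 5))
  expect_gte(f$window[1], 15)
  expect_lt(abs(f$pi - 20) / 20, 0.05)
  expect_false(f$diagnostics_failed)

  # hard-sphere-like contamination below 15 A^2 leaves pi unbiased
  cont <- c(a, runif(30000, 0, 12))
  fc <- select_window(build_distribution(cont, 5))
  expect_gte(fc$window[1], 15)
  expect_lt(abs(fc$pi - 20) / 20, 0.05)

  # distributions that cannot support a window error out
  expect_error(select_window(build_distribution(c(2, 3, 4), 5)),
               "beyond the lower-bound floor")
  expect_error(select_window(build_distribution(c(2, 18, 22), 5)),
               "candidate window")
})

test_that("diagnostics flag the pathologies they are named for", {
  # well-behaved residuals: exact normal scores, the large ones placed at
  # low-leverage (central) positions so no single point dominates the fit
  x <- 1:20
  scores <- qnorm(ppoints(20)) * 0.05
  res <- numeric(20)
  res[order(-abs(x - 10.5))] <- scores[order(abs(scores))]
  lev <- stats::hatvalues(lm(seq_along(x) ~ x))
  d0 <- run_diagnostics(res, x, lev)
  expect_true(d0$pass)

  # all-zero residuals trivially pass
  expect_true(run_diagnostics(rep(0, 10), 1:10,
                              rep(0.2, 10))$pass)

  # a single huge residual fails the Cook's-distance criterion
  res_out <- res
  res_out[20] <- 10 * sd(res)
  d1 <- run_diagnostics(res_out, x, lev)
  expect_false(d1$checks$cooks)

  # variance growing with the fitted value fails scale-location
  set.seed(2)
  fitted <- seq(1, 30)
  res_h <- rnorm(30, 0, 0.01) * fitted^2
  d2 <- run_diagnostics(res_h, fitted, rep(2 / 30, 30))
  expect_false(d2$checks$homoscedasticity)
})

test_that("grouped area tables yield one fit per group", {
  set.seed(3)
  df <- data.frame(
    leaflet = rep(0:1, each = 4000),
    kind = "overall",
    area = c(rexp(4000, 1 / 18), rexp(4000, 1 / 30)))
  fits <- fit_defect_areas(df, bin_width = 5)
  expect_length(fits, 2)
  expect_lt(abs(fits[[1]]$pi - 18) / 18, 0.1)
  expect_lt(abs(fits[[2]]$pi - 30) / 30, 0.1)

  # undersized groups are skipped with a warning
  df2 <- rbind(df, data.frame(leaflet = 2, kind = "overall",
                              area = rexp(5, 1 / 20)))
  expect_warning(fits2 <- fit_defect_areas(df2, bin_width = 5), "skipped")
  expect_length(fits2, 2)
})

test_that("fit reports serialize with diagnostics and config", {
  set.seed(4)
  f <- fit_pi(build_distribution(rexp(5000, 1 / 20), 5), c(15, 80))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fit_report(f, tmp, config = dm_defaults())
  rep <- jsonlite::read_json(tmp)
  expect_equal(rep$package, "defectmesh")
  expect_true(is.numeric(rep$fits$all$pi))
  expect_equal(rep$config$a0, 50)
})
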
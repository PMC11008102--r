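test_that("randomly mixed lipids have contact fraction near one", {
  phis <- vapply(1:5, function(s) {
    spec <- fixture_spec(n_lipids = 1600, seed = s,
                         mix = list(types = c("LIPA", "LIPB"),
                                    fraction = 0.5,
                                    arrangement = "random"))
    fx <- generate_fixture(spec)
    contact_fraction(fx$frames[[1]], fx$ff, "LIPA", "LIPB")$phi
  }, 0)
  expect_true(all(abs(phis - 1) < 0.05))
})

test_that("demixed half-planes give a near-zero contact fraction", {
  spec <- fixture_spec(n_lipids = 3000, seed = 9,
                       mix = list(types = c("LIPA", "LIPB"),
                                  fraction = 0.5,
                                  arrangement = "demixed"))
  fx <- generate_fixture(spec)
  res <- contact_fraction(fx$frames[[1]], fx$ff, "LIPA", "LIPB")
  expect_lt(res$phi, 0.1)
})

test_that("a one-component system has contact fraction exactly one", {
  spec <- fixture_spec(n_lipids = 400, seed = 2)
  fx <- generate_fixture(spec)
  res <- contact_fraction(fx$frames[[1]], fx$ff, "LIPA", "LIPA")
  expect_equal(res$phi, 1, tolerance = 1e-12)
  expect_error(contact_fraction(fx$frames[[1]], fx$ff, "LIPA", "NOPE"),
               "no lipids")
})

test_that("superposition prediction honours the degenerate limits", {
  expect_equal(predict_pi_mixture(c(20, 20), c(0.3, 0.7)), 20)
  expect_equal(predict_pi_mixture(c(17.5, 26.7), c(1, 0)), 17.5)
  expect_equal(predict_pi_mixture(c(17.5, 26.7), c(0, 1)), 26.7)
  # symmetry under swapping components
  expect_equal(predict_pi_mixture(c(17.5, 26.7), c(0.3, 0.7)),
               predict_pi_mixture(c(26.7, 17.5), c(0.7, 0.3)))
  expect_error(predict_pi_mixture(c(-1, 20), c(0.5, 0.5)), "positive")
  expect_error(predict_pi_mixture(c(10, 20), c(0.4, 0.4)), "sum to 1")
  expect_error(predict_pi_mixture(c(10, 20), c(1.2, -0.2)), "0, 1")
})

test_that("prediction is monotone in the fraction between the pure limits", {
  f2 <- seq(0.01, 0.99, by = 0.01)
  p <- vapply(f2, function(f) predict_pi_mixture(c(12, 35), c(1 - f, f)),
              0)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 12 & p < 35))
})

test_that("prediction tracks the single-exponential fit oracle", {
  # oracle: least-squares single-exponential fit to the fraction-weighted
  # two-exponential mixture density over the fit validity window
  oracle <- function(p1, p2, f2, lo = 15, hi = 100) {
    mids <- seq(lo + 2.5, hi - 2.5, by = 5)
    dens <- (1 - f2) * exp(-mids / p1) + f2 * exp(-mids / p2)
    -1 / coef(lm(log(dens) ~ mids))[[2]]
  }
  for (p1 in c(5, 12, 20, 35, 50)) {
    for (p2 in c(5, 12, 20, 35, 50)) {
      for (f in seq(0.1, 0.9, by = 0.2)) {
        pred <- predict_pi_mixture(c(p1, p2), c(1 - f, f))
        expect_lt(abs(pred - oracle(p1, p2, f)) / oracle(p1, p2, f), 0.1)
      }
    }
  }
})

test_that("three components compose pairwise with a flag", {
  expect_warning(
    p <- predict_pi_mixture(c(10, 20, 30), c(0.2, 0.3, 0.5)),
    "experimental")
  expect_true(p > 10 && p < 30)
})
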
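test_that("truncated power-law quantile function matches its closed form", {
  expect_equal(inv_powerlaw_duration(0, 0.03, 50), 0.03)
  expect_equal(inv_powerlaw_duration(1, 0.03, 50), 50)
  # hand evaluation of the exponent -3/2 inverse CDF at the median
  expect_equal(inv_powerlaw_duration(0.5, 0.03, 50), 0.11434,
               tolerance = 1e-4)
  expect_error(inv_powerlaw_duration(0.5, 1, 0.5), "t_min")
})

test_that("piecewise concentration quantile matches hand-inverted branches", {
  expect_equal(inv_concentration(0), 0)
  expect_equal(inv_concentration(0.4), 0.24)          # linear branch
  expect_equal(inv_concentration(0.9), 3.0, tolerance = 1e-12)
  expect_error(inv_concentration(1), "u")
})

test_that("Gaussian copula produces uniform, correctly correlated pairs", {
  set.seed(11)
  u <- sample_correlated_uniform_pairs(1, 1000)
  expect_equal(u[, 1], u[, 2])
  u0 <- sample_correlated_uniform_pairs(0, 1e5)
  expect_lt(abs(cor(u0[, 1], u0[, 2])), 0.02)
  ks <- suppressWarnings(ks.test(u0[, 1], "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_correlated_uniform_pairs(1.2, 10), "rho")
})

test_that("tail-exponent MLE recovers the generating exponent", {
  set.seed(12)
  d <- inv_powerlaw_duration(runif(1e5), 0.03, 50)
  expect_equal(fit_powerlaw_exponent(d, 0.03, 50), -1.5, tolerance = 0.05)
  d2 <- inv_powerlaw_duration(runif(5e4), 0.03, 50, exponent = -2)
  expect_equal(fit_powerlaw_exponent(d2, 0.03, 50), -2, tolerance = 0.06)
})

test_that("sampled concentrations reproduce the analytic CDF", {
  set.seed(13)
  x <- sort(inv_concentration(runif(1e5)))
  cdf <- ifelse(x <= 0.3, 5 / 3 * x, 1 - 10^(-(0.22 + 0.26 * x)))
  emp <- (seq_along(x) - 0.5) / length(x)
  expect_lt(max(abs(emp - cdf)), 0.01)
})

test_that("plume pairs are rectangular-whiff series with the right limits", {
  set.seed(14)
  spec <- plume_spec(rho_target = 1, t_total = 20, whiff_max = 3, dt = 0.5)
  w <- generate_plume_pair(spec)
  expect_identical(w$conc_a, w$conc_b)      # perfect copula, shared draws
  expect_true(all(w$conc_a >= 0))
  expect_gt(mean(w$conc_a > 0), 0)          # some whiffs
  expect_gt(mean(w$conc_a == 0), 0)         # some blanks
  set.seed(15)
  w0 <- generate_plume_pair(plume_spec(rho_target = 0, t_total = 200,
                                       whiff_max = 3, dt = 1))
  st <- measure_plume_stats(w0)
  expect_lt(abs(st$rho_realized), 0.1)      # uncorrelated construction
  expect_true(all(st$intermittency > 0 & st$intermittency < 1))
})

test_that("realized whiff statistics are invariant across target correlation", {
  reps <- function(rho) {
    sapply(1:3, function(s) {
      set.seed(300 + s)
      w <- generate_plume_pair(plume_spec(rho_target = rho, t_total = 100,
                                          whiff_max = 3, dt = 1))
      st <- measure_plume_stats(w)
      c(st$intermittency[1], st$mean_conc[1])
    })
  }
  lo <- rowMeans(reps(0))
  hi <- rowMeans(reps(1))
  expect_equal(lo[1], hi[1], tolerance = 0.35)   # intermittency
  expect_equal(lo[2], hi[2], tolerance = 0.6)    # mean concentration
})

test_that("degenerate plume inputs are rejected or signalled", {
  expect_error(plume_spec(rho_target = 2), "rho")
  expect_error(plume_spec(whiff_min = 0), "whiff")
  expect_error(plume_spec(exponent = -0.5), "exponent")
  w <- stimulus_waveform(0:10, rep(0, 11), rep(0, 11))
  expect_error(measure_plume_stats(w), "correlation undefined")
})
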
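fake_record <- function(times, t_total = 1000, n = 1, pop = "PN_a") {
  spike_record(data.frame(population = rep(pop, length(times)),
                          neuron = rep(1L, length(times)), time = times),
               t_total = t_total, dt = 0.1,
               n_per_pop = stats::setNames(n, pop))
}

test_that("spike density function uses a unit-area alpha kernel", {
  rec <- fake_record(numeric(0))
  tr <- sdf(rec, "PN_a")
  expect_true(all(tr$rate == 0))
  rec1 <- fake_record(500)
  tr1 <- sdf(rec1, "PN_a", tau = 20, dt_grid = 1)
  dt <- tr1$t[2] - tr1$t[1]
  expect_equal(sum(tr1$rate) * dt / 1000, 1, tolerance = 0.01)
  # kernel maximum falls at the spike time itself
  expect_equal(tr1$t[which.max(tr1$rate)], 500, tolerance = 2)
  expect_error(sdf(rec1, "PN_a", tau = -1), "tau")
})

test_that("SDF of merged spike sets equals the sum of SDFs", {
  r1 <- fake_record(c(100, 300, 450))
  r2 <- fake_record(c(200, 350))
  merged <- fake_record(c(100, 200, 300, 350, 450))
  s <- sdf(merged, "PN_a")$rate
  expect_equal(s, sdf(r1, "PN_a")$rate + sdf(r2, "PN_a")$rate,
               tolerance = 1e-10)
})

test_that("window statistics reduce correctly on constructed traces", {
  t <- 0:1000
  flat <- make_rate_trace(t, matrix(10, 1, length(t)))
  expect_equal(max_activity(flat, 0, 200), 10)
  expect_equal(avg_activity(flat, 0, 200), 10)
  zero <- make_rate_trace(t, matrix(0, 1, length(t)))
  expect_equal(max_activity(zero, 0, 200), 0)
  tri <- make_rate_trace(t, matrix(pmax(0, 100 - abs(t - 100)), 1))
  expect_equal(max_activity(tri, 0, 200), 100)
  expect_equal(avg_activity(tri, 0, 200), mean(pmax(0, 100 - abs(t[1:201] - 100))))
  expect_error(max_activity(flat, 900, 200), "window")
})

test_that("supra-threshold activity integrates only above-threshold epochs", {
  t <- 0:999
  flat200 <- make_rate_trace(t, matrix(200, 1, length(t)))
  expect_equal(peak_activity(flat200, 100), 200 * 1000 / 1000)
  low <- make_rate_trace(t, matrix(40, 1, length(t)))
  expect_equal(peak_activity(low, 100), 0)
  expect_equal(peak_activity(flat200, 0), 200)
  mixed <- make_rate_trace(t, matrix(c(rep(200, 500), rep(60, 500)), 1))
  expect_true(peak_activity(mixed, 50) >= peak_activity(mixed, 100))
  expect_true(peak_activity(mixed, 100) >= peak_activity(mixed, 150))
})

test_that("encoding error matches its closed form and symmetry", {
  expect_equal(encoding_error(3, 3), 0)
  expect_equal(encoding_error(1, 3), 0.25)
  expect_equal(encoding_error(1e6, 3), 1, tolerance = 1e-4)
  expect_equal(encoding_error(2, 5), encoding_error(5, 2))
  expect_error(encoding_error(0, 3), "positive")
})

test_that("ratio correlation handles degenerate inputs", {
  expect_equal(ratio_correlation(1:5, 1:5), 1)
  expect_error(ratio_correlation(1:5, rep(2, 5)), "variance")
  expect_lt(ratio_correlation(1:5, 5:1), 0)
  expect_error(ratio_correlation(1:2, 1:2), "3 points")
  expect_equal(ratio_correlation(1:5, c(1, 4, 9, 16, 25),
                                 method = "spearman"), 1)
})

test_that("correlation-encoding distances read off the curve endpoints", {
  df <- expand.grid(variant = c("control", "NSI", "LN"), rho = c(0, 1))
  df$peak <- c(10, 8, 6, 10, 4, 5)
  d <- correlation_encoding_distances(df)
  nsi <- d[d$variant == "NSI", ]
  expect_equal(nsi$d_interference, 2)
  expect_equal(nsi$d_encoding, 4)
  ln <- d[d$variant == "LN", ]
  expect_equal(ln$d_interference, 4)
  expect_equal(ln$d_encoding, 1)
  # a variant identical to control has zero interference distance
  df2 <- rbind(df, data.frame(variant = "mix", rho = c(0, 1),
                              peak = c(10, 10)))
  d2 <- correlation_encoding_distances(df2)
  expect_equal(d2$d_interference[d2$variant == "mix"], 0)
  expect_equal(d2$d_encoding[d2$variant == "mix"], 0)
  expect_error(correlation_encoding_distances(df[df$rho == 0, ]), "near 1")
})

test_that("sigmoid fit recovers parameters from exact curves", {
  nu_orn <- seq(5, 250, length.out = 20)
  nu_pn <- 150 * nu_orn^1.5 / (40^1.5 + nu_orn^1.5)
  fit <- fit_pn_sigmoid(nu_orn, nu_pn)
  expect_equal(fit$nu_max, 150, tolerance = 0.01)
  expect_equal(fit$sigma, 40, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.999)
  # half-max point: input sigma yields nu_max / 2
  half <- fit$nu_max * fit$sigma^1.5 / (fit$sigma^1.5 + fit$sigma^1.5)
  expect_equal(half, fit$nu_max / 2)
  z <- fit_pn_sigmoid(nu_orn, rep(0, 20))
  expect_equal(z$nu_max, 0)
})

test_that("dose-response thresholds honor the first-crossing rule", {
  conc <- 10^seq(-5, -1, length.out = 20)
  resp <- 100 / (1 + (3e-3 / conc)^1.2)
  th <- dose_response_thresholds(conc, resp, baseline = 0)
  expect_lt(th$C_l, th$C_h)
  expect_gt(th$dynamic_range, 0)
  expect_true(th$monotonic)
  # peak-and-plateau curve: thresholds still defined, flagged non-monotonic
  pk <- c(resp[1:12], resp[12] * c(0.8, 0.7, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6))
  th2 <- dose_response_thresholds(conc, pk, baseline = 0)
  expect_false(th2$monotonic)
  expect_lt(th2$C_l, th2$C_h)
  expect_error(dose_response_thresholds(conc, rep(0.01, 20) * 0 + 1e-9,
                                        baseline = 1),
               "bracketed")
})

test_that("latency and plateau detectors work on synthetic traces", {
  t <- 0:2000
  rate <- ifelse(t < 500, 5, 5 + 95 * exp(-(t - 550)^2 / 200) +
                   20 * pmin(1, (t - 500) / 150))
  tr <- make_rate_trace(t, matrix(rate, 1))
  expect_equal(onset_to_peak_latency(tr, 500), 50, tolerance = 5)
  pt <- plateau_time(tr, 500, search_end = 2000)
  expect_gt(pt, 100)
  expect_lt(pt, 400)
})
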
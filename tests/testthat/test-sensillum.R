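test_that("transduction converges to its closed-form steady state", {
  tr <- default_params()$transduction
  # pure unbinding decay when concentration is zero and the offset is off
  r <- 0.8
  for (i in 1:100) r <- step_transduction(r, 0, tr, 0.1, use_c0 = FALSE)
  expect_equal(r, 0.8 * exp(-tr$beta_r * 10), tolerance = 0.01)
  # constant concentration drives r to alpha c^n / (alpha c^n + beta)
  c <- 1e-3
  r <- 0
  for (i in 1:20000) r <- step_transduction(r, c, tr, 0.1, use_c0 = FALSE)
  expect_equal(r, transduction_steady_state(c, tr, use_c0 = FALSE),
               tolerance = 1e-6)
  # the half-activation concentration solves alpha c^n = beta
  c_half <- (tr$beta_r / tr$alpha_r)^(1 / tr$n)
  expect_equal(c_half, 1.99e-3, tolerance = 0.01)
  expect_equal(transduction_steady_state(c_half, tr, use_c0 = FALSE), 0.5)
  expect_error(step_transduction(0.5, -1, tr, 0.1), "non-negative")
})

test_that("ephaptic reversal shift interpolates between V_rev and V_rest", {
  expect_equal(nsi_reversal(0, -33, 0, 0.7), 0)       # coupling off
  expect_equal(nsi_reversal(0, -33, 1, 1), -33)       # full shunt
  expect_equal(nsi_reversal(0, -33, 0.6, 0.5), -9.9)  # direct evaluation
})

test_that("single ORN stepper respects leak equilibrium and spike jumps", {
  orn <- default_params()$orn
  st <- list(V = orn$V_rest, y = 0, refr = 0)
  for (i in 1:100) st <- step_orn(st, 0, 0, orn, 0, 0.1)$state
  expect_equal(st$V, orn$V_rest, tolerance = 1e-4)
  # drive above threshold: on the spike y jumps by exactly alpha_y
  st <- list(V = orn$theta + 1, y = 0.2, refr = 0)
  out <- step_orn(st, 0.5, 0, orn, 0, 0.1)
  expect_true(out$spiked)
  expect_equal(out$state$y, (0.2 - 0.1 * orn$beta_y * 0.2) + orn$alpha_y)
  expect_equal(out$state$V, orn$V_rest)
  expect_error(step_orn(list(V = NaN, y = 0, refr = 0), 0.5, 0, orn),
               "non-finite")
})

test_that("noise-free firing matches the analytic LIF interspike interval", {
  orn <- default_params()$orn
  orn$g_y <- 0   # no adaptation
  dt <- 0.01
  st <- list(V = orn$V_rest, y = 0, refr = 0)
  spikes <- c()
  for (i in 1:40000) {
    out <- step_orn(st, 1, 0, orn, 0, dt)
    st <- out$state
    if (out$spiked) spikes <- c(spikes, i * dt)
  }
  isi <- mean(diff(spikes))
  expect_equal(isi, lif_isi(orn$g_r, orn$V_rev, orn), tolerance = 0.02)
})

test_that("compiled sensilla reproduce the pure-R reference exactly", {
  p <- noiseless_params(n_orn = 1)
  w <- make_triangles(2e-3, 1e-3, duration = 50, delay = 20, onset = 100,
                      t_total = 400, dt = 0.1)
  rec <- run_sensilla(w, p, make_variant("NSI", 0.6), seed = 1)
  ref <- reference_sensillum(w, p, 0.6)
  expect_equal(rec$time[rec$population == "ORN_a"], ref[[1]])
  expect_equal(rec$time[rec$population == "ORN_b"], ref[[2]])
  expect_gt(length(ref[[1]]), 3)   # the check is not vacuous
})

test_that("zero coupling reproduces the control variant bit-exactly", {
  p <- small_params(4)
  w <- make_triangles(1e-3, 1e-3, duration = 50, onset = 200, t_total = 600)
  a <- run_sensilla(w, p, make_variant("NSI", omega_nsi = 0), seed = 7)
  b <- run_sensilla(w, p, make_variant("control"), seed = 7)
  expect_identical(a$time, b$time)
  expect_identical(a$population, b$population)
})

test_that("spike records respect refractoriness and state bounds", {
  p <- default_params()
  w <- make_step(5e-3, 5e-3, onset = 200, duration = 400, t_total = 700)
  rec <- run_sensilla(w, p, seed = 3)
  tau_ref <- p$orn$tau_ref
  by_neuron <- split(rec$time, paste(rec$population, rec$neuron))
  gaps <- unlist(lapply(by_neuron, function(ts) diff(sort(ts))))
  expect_true(all(gaps >= tau_ref - 1e-9))
})

test_that("ephaptic coupling suppresses the partner of a driven ORN", {
  p <- default_params()
  w <- make_step(2e-3, 0, onset = 300, duration = 400, t_total = 800)
  rate_b <- function(variant, seed) {
    rec <- run_sensilla(w, p, variant, seed = seed)
    sum(rec$population == "ORN_b" & rec$time > 300 & rec$time < 700)
  }
  nsi <- mean(sapply(1:4, function(s) rate_b(make_variant("NSI"), s)))
  ctrl <- mean(sapply(1:4, function(s) rate_b(make_variant("control"), s)))
  expect_lt(nsi, ctrl)   # ORN_b driven only by spontaneous input, inhibited
})

test_that("control steady response increases monotonically with concentration", {
  p <- default_params()
  rates <- sapply(c(5e-4, 2e-3, 8e-3), function(conc) {
    w <- make_step(conc, 0, onset = 300, duration = 500, t_total = 900)
    mean(sapply(1:3, function(s) {
      rec <- run_sensilla(w, p, seed = s)
      sum(rec$population == "ORN_a" & rec$time > 400 & rec$time < 800)
    }))
  })
  expect_true(all(diff(rates) > 0))
})
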
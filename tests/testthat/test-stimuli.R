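test_that("step waveform has the prescribed rectangular profile", {
  w <- make_step(1e-3, 0, onset = 100, duration = 500, t_total = 1000,
                 dt = 0.1)
  at <- function(ch, t) ch[which.min(abs(w$t - t))]
  expect_equal(at(w$conc_a, 300), 1e-3)
  expect_equal(at(w$conc_a, 50), 0)
  expect_equal(at(w$conc_a, 700), 0)
  expect_true(all(w$conc_b == 0))
  expect_error(make_step(-1e-3, 0), "non-negative")
  expect_error(make_step(1e-3, 0, onset = 900, duration = 500,
                         t_total = 1000), "fit")
})

test_that("ramp is linear and parabola quadratic in time since onset", {
  s <- 2e-6
  w <- make_ramp(s, 0, onset = 200, duration = 2000, t_total = 2500)
  at <- function(t) w$conc_a[which.min(abs(w$t - t))]
  expect_equal(at(200 + 700), s * 700, tolerance = 1e-10)
  expect_equal(at(100), 0)
  a <- 1e-9
  wp <- make_parabola(a, 0, onset = 200, duration = 2000, t_total = 2500)
  atp <- function(t) wp$conc_a[which.min(abs(wp$t - t))]
  expect_equal(atp(200 + 1000), a * 1000^2, tolerance = 1e-10)
  w0 <- make_ramp(s, 0, onset = 200, duration = 0, t_total = 500)
  expect_true(all(w0$conc_a == 0))
  expect_error(make_ramp(-1), "non-negative")
})

test_that("triangular pulses rise and fall linearly around the apex", {
  p <- 2e-3
  w <- make_triangles(p, p, duration = 50, delay = 0, onset = 500,
                      t_total = 1100, dt = 0.1)
  at <- function(ch, t) ch[which.min(abs(w$t - t))]
  expect_equal(at(w$conc_a, 525), p)                 # apex at onset + d/2
  expect_equal(at(w$conc_a, 512.5), p / 2)           # halfway up the rise
  expect_equal(w$conc_a, w$conc_b)                   # delay 0, equal peaks
  # integral equals peak * duration / 2
  expect_equal(sum(w$conc_a) * w$dt, p * 50 / 2, tolerance = 1e-3)
  wd <- make_triangles(p, p, duration = 50, delay = 200, onset = 500,
                       t_total = 1200, dt = 0.1)
  expect_equal(at(wd$conc_b, 725), p)                # channel b delayed
  expect_error(make_triangles(p, p, duration = 50, delay = 500,
                              t_total = 900), "too short")
})

test_that("waveforms refine consistently under a finer grid", {
  w1 <- make_triangles(1e-3, 2e-3, duration = 50, onset = 100,
                       t_total = 300, dt = 0.2)
  w2 <- make_triangles(1e-3, 2e-3, duration = 50, onset = 100,
                       t_total = 300, dt = 0.1)
  shared <- match(w1$t, w2$t)
  expect_equal(w1$conc_a, w2$conc_a[shared], tolerance = 1e-12)
})

test_that("waveform CSV round-trips", {
  w <- make_triangles(1e-3, 2e-3, duration = 50, onset = 100, t_total = 300,
                      dt = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, path)
  back <- read_waveform_csv(path)
  expect_equal(back$conc_a, w$conc_a)
  expect_equal(back$conc_b, w$conc_b)
  expect_equal(back$dt, w$dt)
})
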
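test_that("synaptic activation jumps saturate and decay as prescribed", {
  expect_equal(step_synapse(0, 1, 0.5, 26.8, 0), 0.5)
  expect_equal(step_synapse(1, 1, 0.5, 26.8, 0), 1)
  act <- 0.8
  for (i in 1:5000) act <- step_synapse(act, 0, 0.5, 26.8, 0.1)
  expect_lt(act, 1e-6)
  # two spikes in one step compound through the saturation
  expect_equal(step_synapse(0, 2, 0.5, 26.8, 0), 0.75)
})

test_that("connectivity follows the glomerular wiring rules", {
  lay <- default_params()$layout
  cn <- build_connectivity(lay)
  expect_equal(dim(cn$w), c(10, 40))
  expect_equal(sum(cn$w[1:5, 1:20]), 100)       # all-to-all within glom a
  expect_equal(sum(cn$w[1:5, 21:40]), 0)        # no cross-glomerular input
  expect_equal(sum(cn$v[1:3, 6:10]), 0)         # LN input within glom only
  expect_equal(sum(cn$u[1:5, 1:3]), 0)          # no self-glomerulus inhibition
  expect_equal(sum(cn$u[1:5, 4:6]), 15)         # full cross-inhibition block
})

test_that("silent LN pathway reproduces control PN spikes bit-exactly", {
  p <- small_params(4)
  w <- make_triangles(1.5e-3, 1.5e-3, duration = 50, onset = 200,
                      t_total = 600)
  orn <- run_sensilla(w, p, make_variant("control"), seed = 5)
  a <- run_network(orn, p, make_variant("LN", alpha_ln = 0), seed = 6)
  b <- run_network(orn, p, make_variant("control"), seed = 6)
  pa <- a[a$population %in% c("PN_a", "PN_b"), ]
  pb <- b[b$population %in% c("PN_a", "PN_b"), ]
  expect_identical(pa$time, pb$time)
})

test_that("without input or noise the antennal lobe stays at rest", {
  p <- noiseless_params(2)
  w <- make_step(0, 0, onset = 100, duration = 100, t_total = 500)
  orn_empty <- spike_record(
    data.frame(population = character(), neuron = integer(),
               time = numeric()),
    t_total = 500, dt = 0.1,
    n_per_pop = c(ORN_a = 2, ORN_b = 2))
  al <- run_network(orn_empty, p, seed = 1)
  expect_equal(nrow(al), 0)
})

test_that("LN inhibition suppresses projection neurons of the other glomerulus", {
  p <- default_params()
  w <- make_triangles(1e-3, 1e-3, duration = 50, delay = 100, onset = 400,
                      t_total = 1000)
  count_b <- function(variant) {
    mean(sapply(1:4, function(s) {
      set.seed(s)
      orn <- run_sensilla(w, p, make_variant("control"))
      set.seed(s + 100)
      al <- run_network(orn, p, variant)
      sum(al$population == "PN_b")
    }))
  }
  expect_lt(count_b(make_variant("LN")), count_b(make_variant("control")))
})

test_that("local neurons track the projection neurons of their glomerulus", {
  p <- default_params()
  w <- make_step(2e-3, 0, onset = 300, duration = 400, t_total = 900)
  set.seed(2)
  orn <- run_sensilla(w, p)
  al <- run_network(orn, p)
  pn <- sdf(al, "PN_a")
  ln <- sdf(al, "LN_a")
  expect_gt(cor(pn$rate, ln$rate), 0)
})

test_that("end-to-end runs are reproducible under a fixed seed", {
  p <- small_params(3)
  w <- make_triangles(1.5e-3, 1e-3, duration = 50, onset = 200,
                      t_total = 600)
  a <- run_model(w, p, make_variant("mix"), seed = 11)
  b <- run_model(w, p, make_variant("mix"), seed = 11)
  expect_identical(a$time, b$time)
  expect_identical(a$population, b$population)
  expect_identical(a$neuron, b$neuron)
})

test_that("PN and LN spike trains respect the refractory period", {
  p <- default_params()
  w <- make_step(5e-3, 5e-3, onset = 200, duration = 300, t_total = 600)
  set.seed(4)
  orn <- run_sensilla(w, p)
  al <- run_network(orn, p)
  gaps <- unlist(lapply(split(al$time, paste(al$population, al$neuron)),
                        function(ts) diff(sort(ts))))
  expect_true(all(gaps >= p$al$pn$tau_ref - 1e-9))
})
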
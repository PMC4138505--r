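test_that("passive soma relaxes to E_L with the analytic RC time constant", {
  cfg <- passive_config(geometry = list(
    smooth = list(n = 1, length = 0.1, diam = 0.01),
    spiny = list(n = 1, length = 0.1, diam = 0.01)))
  cfg$densities$dend[] <- 0                 # soma leak only
  cfg$integration$dt <- 0.0025
  cfg$integration$settle <- 0
  cfg$integration$record_stride <- 40       # 0.1 ms sampling
  tr <- simulate_protocol(quiet_protocol(40), cfg, 1)
  # v(t) = E + (v0 - E) exp(-t/tau), tau = cm/g_L = 0.8/0.1 = 8 ms
  v_ana <- -70 + (-65 + 70) * exp(-tr$t / 8)
  expect_lt(max(abs(tr$v[, "soma"] - v_ana)), 0.001 * 5)   # 0.1% of the span
})

test_that("implicit cable solve equals a dense solve of the same system", {
  cfg <- passive_config(geometry = list(
    smooth = list(n = 1, length = 20, diam = 2),
    spiny = list(n = 1, length = 10, diam = 1)))
  topo <- build_default_topology(cfg)
  comp <- topo$compartments
  dt <- cfg$integration$dt
  st <- init_state(cfg)
  out <- advance(st, cfg, n_steps = 1)
  v_engine <- out$state$v

  n <- 3; v0 <- rep(-65, n)
  gl <- c(0.1, 0.38, 0.38) / 1000                      # S/cm2
  el <- c(-70, -80, -80)
  cap <- comp$cm * 1e-3 / dt
  M <- diag(cap + gl)
  rhs <- cap * v0 + gl * el
  rhs[1] <- rhs[1] - pump_current(10)                  # somatic pump constant
  for (k in seq_len(nrow(topo$edges))) {
    a <- topo$edges$a[k] + 1; b <- topo$edges$b[k] + 1
    r <- topo$edges$r_mohm[k]
    cab <- 1e-6 / (r * comp$area[a])                   # into a from b
    cba <- 1e-6 / (r * comp$area[b])
    M[a, a] <- M[a, a] + cab; M[a, b] <- M[a, b] - cab
    M[b, b] <- M[b, b] + cba; M[b, a] <- M[b, a] - cba
  }
  v_dense <- solve(M, rhs)
  expect_equal(v_engine, v_dense, tolerance = 1e-10)
})

test_that("removing a channel by zero density equals omitting its current", {
  # with all densities zero the passive trace defines the baseline; adding a
  # zero-density channel elsewhere must not perturb it
  cfg <- passive_config()
  cfg$integration$settle <- 100
  tr1 <- simulate_protocol(quiet_protocol(100), cfg, 1)
  cfg2 <- cfg
  cfg2$densities$soma[["na_r"]] <- 0   # explicit zero (already zero): identical
  tr2 <- simulate_protocol(quiet_protocol(100), cfg2, 1)
  expect_identical(tr1$v, tr2$v)
})

test_that("identical config and seed give bit-identical traces", {
  pr <- protocol_spec("det", duration = 1500,
                      cf = list(on = TRUE, freq = 1),
                      pf = list(on = TRUE, rate = 100, seed = NULL),
                      overrides = list())
  cfg <- default_config()
  cfg$integration$settle <- 500
  tr1 <- simulate_protocol(pr, cfg, seed = 5)
  tr2 <- simulate_protocol(pr, cfg, seed = 5)
  expect_identical(tr1$v, tr2$v)
  expect_identical(tr1$spikes, tr2$spikes)
  expect_identical(tr1$smooth, tr2$smooth)
  # a different seed changes the PF realisation and the trace
  tr3 <- simulate_protocol(pr, cfg, seed = 6)
  expect_false(identical(tr1$v, tr3$v))
})

test_that("a zero-length protocol returns an empty window with settle-state metadata", {
  cfg <- default_config()
  cfg$integration$settle <- 100
  tr <- simulate_protocol(quiet_protocol(0), cfg, 1)
  expect_length(tr$t, 0)
  expect_length(tr$spikes, 0)
  expect_false(is.null(tr$state))
  expect_true(all(is.finite(tr$state$v)))
})

test_that("state validity holds after every step of a full-model run", {
  cfg <- default_config()
  cfg$integration$settle <- 100
  pars <- purksim:::build_engine_pars(cfg, NULL, 1)
  st <- purksim:::cpp_init_state(pars)
  # check_stride = 1: engine asserts gates, occupancy and floors each step
  out <- purksim:::cpp_run(pars, st, n_steps = 8000, settle_steps = 4000,
                           record_stride = 40, check_stride = 1)
  expect_true(all(is.finite(out$v)))
  expect_equal(sum(out$state$markov), 1, tolerance = 1e-9)
  expect_true(all(out$state$markov >= -1e-12))
  expect_true(all(out$state$dend_gates >= -1e-12 & out$state$dend_gates <= 1 + 1e-12))
  expect_gte(out$state$na_i, 10)
  expect_true(all(out$state$ca > 0))
})

test_that("engine smooth-compartment switch state matches the pure-R switch rules", {
  tr <- cf_trace(0.72, duration = 4000)
  w <- tr$smooth[, "w"]; r <- tr$smooth[, "r"]; g <- tr$smooth[, "gsk_live"]
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(r >= 0 & r <= 1))
  expect_identical(unname(g), ifelse(r > 0.1, 0.72, 1e-7))
  # CF at 1 Hz keeps r above 0.1 after the first event (s ln 10 > 1 s)
  after <- tr$t > 1100
  expect_true(all(r[after] > 0.1))
  # smooth calcium stays positive and below the 10 mM sanity bound
  expect_true(all(tr$smooth[, "ca"] > 0 & tr$smooth[, "ca"] < 10))
})
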
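test_that("somatic shell: floor, exponential decay, and influx balance", {
  st <- soma_ca_state(ca = 1e-4)
  st2 <- step_soma_ca(st, 0, 0.025)
  expect_equal(st2$ca, 1e-4)                       # stays at the floor
  # above the floor with no current: decay toward zero at rate beta
  st <- soma_ca_state(ca = 5e-3)
  ca <- st$ca
  for (i in 1:40) st <- step_soma_ca(st, 0, 0.025)  # 1 ms
  # discrete Euler decay factor (1 - beta dt)^n, ~exp(-beta t)
  expect_equal(st$ca / ca, (1 - 0.025)^40, tolerance = 1e-12)
  expect_equal(st$ca / ca, exp(-1), tolerance = 2e-2)
  # sustained inward current: steady state where influx = beta * ca
  i_ca <- -0.5
  st <- soma_ca_state(ca = 1e-4)
  for (i in 1:4000) st <- step_soma_ca(st, i_ca, 0.025)
  sf <- 1e4 / (2 * 96485.332 * 0.1)
  expect_equal(st$ca, sf * 0.5 / 1, tolerance = 1e-3)   # algebraic balance
})

test_that("spiny shell: influx clamp, root-find steady state, depth scaling", {
  st <- spiny_ca_state(ca = 2e-3)
  # outward Ca current contributes exactly nothing
  a <- step_spiny_ca(st, +5, 0.025)$ca
  b <- step_spiny_ca(st, 0, 0.025)$ca
  expect_identical(a, b)
  # chan-free steady state solves (y - ca)/tau_r = kt ca/(ca + kd)
  st <- spiny_ca_state(ca = 1e-3)
  for (i in 1:80000) st <- step_spiny_ca(st, 0, 0.025)
  f <- function(ca) (4e-5 - ca) / 2 - 4e-5 * ca / (ca + 4e-5)
  root <- uniroot(f, c(1e-9, 4e-5), tol = 1e-14)$root
  expect_equal(st$ca, root, tolerance = 1e-6)
  # doubling depth halves the influx term
  d1 <- step_spiny_ca(spiny_ca_state(depth = 0.1), -1, 0.025)$ca
  d2 <- step_spiny_ca(spiny_ca_state(depth = 0.2), -1, 0.025)$ca
  base <- step_spiny_ca(spiny_ca_state(), 0, 0.025)$ca
  expect_equal((d2 - base) / (d1 - base), 0.5, tolerance = 1e-9)
})

test_that("smooth shell reduces to the spiny dynamics when y is pinned at z", {
  sm <- smooth_ca_state(ca = 3e-3, kt = 1e-4, kd = 1e-4, y = 2.4e-4)
  sp <- spiny_ca_state(ca = 3e-3, kt = 1e-4, kd = 1e-4, y = 2.4e-4)
  # no influx: dy/dt = 0 when y = z, so the two trajectories coincide
  for (i in 1:400) {
    sm <- step_smooth_ca(sm, 0, 6, 0.025)
    sp <- step_spiny_ca(sp, 0, 0.025)
    expect_equal(sm$y, 2.4e-4)
  }
  expect_equal(sm$ca, sp$ca, tolerance = 1e-12)
})

test_that("set-point accumulation scales inversely with g (10x under the CF pair)", {
  mk <- function() smooth_ca_state(y = 2.4e-4)
  influx <- -0.5
  fast <- mk(); fast$w <- 1; fast <- purksim:::.apply_switches(fast)  # g = 1e4
  slow <- mk()                                                       # g = 1e5
  expect_equal(fast$g, 1e4); expect_equal(fast$tau_m_y, 1000)
  expect_equal(slow$g, 1e5); expect_equal(slow$tau_m_y, 100)
  dy_fast <- step_smooth_ca(fast, influx, 6, 0.025)$y - 2.4e-4
  dy_slow <- step_smooth_ca(slow, influx, 6, 0.025)$y - 2.4e-4
  expect_equal(dy_fast / dy_slow, 10, tolerance = 1e-9)  # decay term is 0 at y = z
})

test_that("set point rises under sustained influx and decays to z without it", {
  st <- smooth_ca_state()
  for (i in 1:2000) st <- step_smooth_ca(st, -1, 6, 0.025)   # 50 ms of influx
  expect_gt(st$y, 2.4e-4)
  y_high <- st$y
  for (i in 1:40000) st <- step_smooth_ca(st, 0, 6, 0.025)   # 1 s quiet
  expect_lt(st$y, y_high)
  expect_equal(st$y, 2.4e-4, tolerance = 1e-4)   # ~10 tau_m of decay
})

test_that("w switch: threshold trigger, f*ln(10) lifespan, retrigger prolongation", {
  st <- smooth_ca_state()
  # subthreshold influx never flips the (g, tau_m) pair
  st2 <- update_w(st, -0.05, 0.025)
  expect_equal(st2$w, 0); expect_equal(st2$g, 1e5); expect_equal(st2$tau_m_y, 100)
  # outward current of any size never triggers
  expect_equal(update_w(st, +5, 0.025)$w, 0)
  # crossing 0.06 mA/cm2 inward sets w = 1 and the slow pair
  st <- update_w(st, -0.07, 0.025)
  expect_equal(st$w, 1)
  expect_equal(st$g, 1e4); expect_equal(st$tau_m_y, 1000)
  # lifespan to w = 0.1 equals f ln 10 = 230.26 ms
  t <- 0; dt <- 0.5
  while (st$w > 0.1) { st <- update_w(st, 0, dt); t <- t + dt }
  expect_equal(t, 100 * log(10), tolerance = dt / (100 * log(10)) * 2)
  # a retrigger mid-decay restarts the full lifespan
  st <- update_w(st, -0.07, dt)
  expect_equal(st$w, 1)
})

test_that("r switch: CF current trigger, s*ln(10) lifespan, live SK mapping", {
  st <- smooth_ca_state()
  expect_equal(st$gsk_live, 1e-7)                  # no CF input ever
  st <- update_r(st, -65, 0.025)                   # |65 nA| > 3 nA
  expect_equal(st$r, 1)
  expect_equal(st$gsk_live, 0.72)
  st$gsk_on <- 0.62                                # protocol override
  st <- update_r(st, 0, 0.025)
  expect_equal(st$gsk_live, 0.62)
  # lifespan to r = 0.1 is s ln 10 = 2302.6 ms, so 1 Hz CF input keeps SK on
  t <- 0; dt <- 1
  st$r <- 1
  while (st$r > 0.1) { st <- update_r(st, 0, dt); t <- t + dt }
  expect_equal(t, 1000 * log(10), tolerance = 2 * dt / (1000 * log(10)))
  expect_gt(t, 1000)        # survives a 1 s inter-CF interval
  expect_lt(t, 5000)        # but not a 5 s (0.2 Hz) interval
})

test_that("CF at 1 Hz keeps SK continuously enabled; at 0.2 Hz it lapses", {
  run_rate <- function(period_ms) {
    st <- smooth_ca_state()
    dt <- 1; r_min <- Inf
    # track the dip between the first and second CF events
    for (t in seq(0, 2 * period_ms, by = dt)) {
      i_cf <- if (t %% period_ms < dt && t > 0) -65 else 0
      st <- update_r(st, i_cf, dt)
      if (t > period_ms && t <= 2 * period_ms) r_min <- min(r_min, st$r)
    }
    r_min
  }
  expect_gt(run_rate(1000), 0.1)
  expect_lt(run_rate(5000), 0.1)
})

test_that("switch outputs are pure functions of w and r", {
  st <- smooth_ca_state()
  for (w in c(0, 0.05, 0.0999, 0.1001, 0.5, 1)) {
    for (r in c(0, 0.0999, 0.1001, 1)) {
      st$w <- w; st$r <- r
      st <- purksim:::.apply_switches(st)
      expect_identical(st$g, if (w > 0.1) 1e4 else 1e5)
      expect_identical(st$tau_m_y, if (w > 0.1) 1000 else 100)
      expect_identical(st$gsk_live, if (r > 0.1) st$gsk_on else st$gsk_off)
    }
  }
})
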
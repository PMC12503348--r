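test_that("adaptive dt follows the damped rule and its clamps", {
  p <- default_parameters()
  d <- tiny_domain(12)
  u <- p$units
  # zero potential gradient -> dt_max (1300 min)
  expect_equal(adaptive_dt(array(0, d$n), p, d) * u$tau, 1300)
  # enormous gradient -> clamp at dt_min (26 min)
  ax <- grid_axes(d)
  steep <- outer(1e6 * ax[[1]], rep(1, d$n[2]))
  expect_equal(adaptive_dt(steep, p, d) * u$tau, 26)
  # alpha |E'|^2 = 1 -> dt_max / 2 = 650 min: build a linear mu whose
  # squared L2 gradient norm is sqrt(1/alpha)
  target <- (1 / p$alpha_dt)^(1 / 4)   # ||grad mu|| with |E'|^2 = 1
  vol <- prod(d$n) * d$h^2
  slope <- target / sqrt(vol)
  mu <- outer(slope * ax[[1]], rep(1, d$n[2]))
  expect_equal(adaptive_dt(mu, p, d) * u$tau, 650, tolerance = 1e-6)
})

test_that("step accounting: one month at dt_min is 1662 base steps", {
  expect_identical(n_base_steps(30 * 1440), 1662L)
  expect_identical(n_base_steps(26), 1L)
})

test_that("activation-time bisection agrees with a dt_min-resolution scan", {
  # synthetic world: a tiny quiescent state whose AF production ramps up as
  # the tumor (growing fast) crosses the production threshold at t*
  p <- default_parameters(dt_max = 30)
  d <- tiny_domain(16)
  tum <- tumor_ellipsoid(d$extent / 2, 0.02, 0.02,
                         tgr = 1.2)  # fast growth so eligibility arrives
  cf <- array(-1, d$n)
  cf[8, ] <- 1
  st <- init_state(cf, tum, p, d)
  phi0 <- tumor_indicator(tum, 0, d)
  st$af <- solve_af_steady(phi0, cf, p, d, st$ops)
  dt_eff <- bisect_activation_time(st, dt_candidate = 30, p)
  # oracle: brute-force scan of the same trial construction at dt_min steps
  trial_oracle <- function(dt) {
    phi <- tumor_indicator(tum, dt, d)
    cap <- step_capillaries(st$capillaries, st$af, dt, p, d, st$ops)
    aff <- solve_af_steady(phi, cap$c, p, d, st$ops)
    any(cap$c >= 1 - p$c_tol & aff$af >= p$T_c & aff$G >= p$G_m)
  }
  scan <- sapply(seq(p$dt_min, 30, by = p$dt_min), trial_oracle)
  if (any(scan)) {
    t_star <- seq(p$dt_min, 30, by = p$dt_min)[which(scan)[1]]
    expect_lte(abs(dt_eff - t_star), p$dt_min)
  } else {
    expect_equal(dt_eff, 30)
  }
  # eligibility from the very start of the span -> dt_min
  st2 <- st
  big <- tumor_ellipsoid(d$extent / 2, 0.2, 0.2, tgr = 1.2)
  st2$tumor <- big
  st2$af <- solve_af_steady(tumor_indicator(big, 0, d), cf, p, d, st$ops)
  trial2 <- function(dt) {
    phi <- tumor_indicator(big, dt, d)
    cap <- step_capillaries(st2$capillaries, st2$af, dt, p, d, st$ops)
    aff <- solve_af_steady(phi, cap$c, p, d, st$ops)
    any(cap$c >= 1 - p$c_tol & aff$af >= p$T_c & aff$G >= p$G_m)
  }
  if (trial2(p$dt_min)) {
    expect_equal(bisect_activation_time(st2, 30, p), p$dt_min)
  }
  # no activation anywhere in the span -> the candidate comes back
  p0 <- default_parameters(dt_max = 30, V_pT = 1e-6)
  st3 <- init_state(cf, tum, p0, d)
  st3$af <- solve_af_steady(phi0, cf, p0, d, st3$ops)
  expect_equal(bisect_activation_time(st3, 30, p0), 30)
})

test_that("driver keeps dt within bounds and dt_min while tips are active", {
  sc <- make_scenario("2d_sprouting", seed = 1)
  st <- scenario_initial_state(sc)
  for (k in 1:6) st <- rhangio::step(st)
  h <- st$history
  expect_true(all(h$dt >= st$p$dt_min - 1e-12))
  expect_true(all(h$dt <= st$p$dt_max + 1e-12))
  active_steps <- h$n_active_tips > 0
  expect_true(all(h$dt[active_steps] == st$p$dt_min))
  expect_true(all(diff(h$t_tau) > 0))
  expect_equal(nrow(h), st$step_index)
})

test_that("minimal-size bisection matches an exhaustive scan", {
  # synthetic monotone predicate with threshold 0.37
  pred <- function(fr) fr >= 0.37
  r <- estimate_minimal_size(activates = pred)
  expect_true(r$capable)
  expect_lt(r$bracket, 0.05)
  expect_lte(abs(r$min_volume_fraction - 0.37), 0.05)
  expect_equal(r$min_diameter_fraction, r$min_volume_fraction^(1 / 3))
  # oracle: exhaustive scan at the stopping resolution
  grid <- seq(0.025, 1, by = 0.025)
  scan_min <- grid[which(sapply(grid, pred))[1]]
  expect_lte(abs(r$min_volume_fraction - scan_min), 0.05)
  # never activates -> incapable, no bisection
  r0 <- estimate_minimal_size(activates = function(fr) FALSE)
  expect_false(r0$capable)
  expect_identical(r0$iterations, 1L)
  # always activates -> converges to the lowest probed fraction
  r1 <- estimate_minimal_size(activates = function(fr) TRUE)
  expect_true(r1$capable)
  expect_lt(r1$min_volume_fraction, 0.05)
  expect_lt(r1$bracket, 0.05)
})

test_that("scenario-driven minimal size probes the AF/activation pipeline", {
  sc <- make_scenario("2d_sprouting", seed = 1)
  st <- scenario_initial_state(sc)
  r <- estimate_minimal_size(c0 = st$capillaries$c, tumor = st$tumor,
                             p = st$p, domain = st$domain)
  expect_true(r$capable)
  expect_gt(r$min_volume_fraction, 0)
  expect_lte(r$min_volume_fraction, 1)
  # with negligible production the same lesion is incapable
  p_low <- st$p
  p_low$V_pT <- 1e-6
  r0 <- estimate_minimal_size(c0 = st$capillaries$c, tumor = st$tumor,
                              p = p_low, domain = st$domain)
  expect_false(r0$capable)
})

test_that("quiescent world: no tumor means no AF and no tips, ever", {
  p <- default_parameters()
  d <- tiny_domain(16)
  tum <- tumor_ellipsoid(c(-10, -10), 0.01, 0.01, tgr = 1)  # off-domain
  st <- init_state(blob_field(d), tum, p, d)
  for (k in 1:3) st <- rhangio::step(st)
  expect_true(all(st$history$n_active_tips == 0))
  expect_true(all(st$history$af_max < 1e-10))
  # at numerical equilibrium (uniform tissue) the adaptive rule opens up
  # to dt_max in a single step
  st2 <- init_state(array(-1, d$n), tum, p, d)
  st2 <- rhangio::step(st2)
  expect_equal(st2$history$dt[1], p$dt_max)
})
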
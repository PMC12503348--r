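# helper: state pieces with a controlled AF field (linear ramp in x) on a
# small 2D grid, vessel band at c = 1
tip_fixture <- function(slope = 4, af0 = 0, n = 21, h = 0.01,
                        vessel_rows = NULL) {
  d <- sim_domain(rep((n - 1) * h, 2), h = h, dim = 2)
  ax <- grid_axes(d)
  af <- outer(af0 + slope * ax[[1]], rep(1, n))
  grad <- gradient_field(af, d)
  aff <- structure(list(af = af, grad = grad, G = gradient_norm(grad)),
                   class = "rh_af")
  cf <- array(-1, d$n)
  if (!is.null(vessel_rows)) cf[vessel_rows, ] <- 1
  list(d = d, aff = aff, cf = cf)
}

test_that("activation requires all three thresholds and Notch spacing", {
  p <- default_parameters()
  # af ramp: af = 4x, G = 4 > G_m; T_c = 0.5 crossed at x = 0.125
  fx <- tip_fixture(slope = 4, vessel_rows = 14:16)  # x in [0.13, 0.15]
  tips <- activate_tips(fx$cf, fx$aff, empty_tips(2), p, fx$d)
  expect_gt(nrow(tips), 0)
  # all tips on vessel nodes with af >= T_c
  expect_true(all(tips$x1 >= 0.125))
  # Notch: pairwise distances >= delta4
  pos <- as.matrix(tips[, c("x1", "x2")])
  dd <- as.matrix(dist(pos))
  expect_true(all(dd[upper.tri(dd)] >= p$delta4 - 1e-12))
  # below T_c: no activation (vessel where af < 0.5)
  fx2 <- tip_fixture(slope = 4, vessel_rows = 2:3)   # x ~ 0.01-0.02
  expect_equal(nrow(activate_tips(fx2$cf, fx2$aff, empty_tips(2), p, fx2$d)),
               0)
  # below G_m: no activation even with high af
  fx3 <- tip_fixture(slope = 1, af0 = 1, vessel_rows = 14:16)
  expect_equal(nrow(activate_tips(fx3$cf, fx3$aff, empty_tips(2), p, fx3$d)),
               0)
  # c < 1 - c_tol: no activation
  fx4 <- tip_fixture(slope = 4)
  fx4$cf[14:16, ] <- 0.99
  expect_equal(nrow(activate_tips(fx4$cf, fx4$aff, empty_tips(2), p, fx4$d)),
               0)
})

test_that("two eligible nodes closer than delta4 yield exactly one tip", {
  p <- default_parameters()
  fx <- tip_fixture(slope = 4)
  # two isolated vessel nodes 0.03 sau apart (< delta4 = 0.05)
  fx$cf[15, 10] <- 1
  fx$cf[18, 10] <- 1
  tips <- activate_tips(fx$cf, fx$aff, empty_tips(2), p, fx$d)
  expect_equal(nrow(tips), 1)
  # greedy lexicographic order keeps the lower linear index
  expect_equal(tips$x1, 0.14)
})

test_that("existing active tips block activation within delta4", {
  p <- default_parameters()
  fx <- tip_fixture(slope = 4)
  fx$cf[15, 10] <- 1
  prior <- empty_tips(2)
  prior[1, ] <- list(0.145, 0.09, 0, 0, TRUE, 0)
  tips <- activate_tips(fx$cf, fx$aff, prior, p, fx$d)
  expect_equal(nrow(tips), 1)   # nothing added
  prior$active <- FALSE         # inactive tips do not block
  tips2 <- activate_tips(fx$cf, fx$aff, prior, p, fx$d)
  expect_equal(nrow(tips2), 2)
})

test_that("deactivation fires when either threshold is lost", {
  p <- default_parameters()
  tips <- empty_tips(2)
  tips[1:3, ] <- list(c(0.05, 0.10, 0.15), rep(0.1, 3), rep(0, 3),
                      rep(0, 3), rep(TRUE, 3), rep(0, 3))
  # ramp af = 4x: tip1 af=0.2 < T_c; G = 4 everywhere >= G_m
  fx <- tip_fixture(slope = 4)
  out <- deactivate_tips(tips, fx$aff, p, fx$d)
  expect_equal(out$active, c(FALSE, FALSE, TRUE))  # af 0.2, 0.4 < 0.5 <= 0.6
  # flat high af: G = 0 < G_m kills all
  fx2 <- tip_fixture(slope = 0, af0 = 1)
  out2 <- deactivate_tips(tips, fx2$aff, p, fx2$d)
  expect_true(all(!out2$active))
})

test_that("velocity law: linear regime, cap, and branch continuity", {
  p <- default_parameters()
  v <- tip_velocity(c(2, 0), p)
  expect_equal(v, c(p$chi * 2, 0))
  expect_lt(abs(v[1] - 0.004062), 1e-6)
  # cap branch: G = 2 G_M -> speed chi * G_M
  v2 <- tip_velocity(c(0, 2 * p$G_M), p)
  expect_equal(sqrt(sum(v2^2)), p$chi * p$G_M, tolerance = 1e-12)
  expect_lt(abs(sqrt(sum(v2^2)) - 0.0113736), 2e-6)
  # at exactly G_M both branches agree
  v3 <- tip_velocity(c(0, p$G_M), p)
  expect_equal(sqrt(sum(v3^2)), p$chi * p$G_M, tolerance = 1e-12)
  # below G_m is a contract violation
  expect_error(tip_velocity(c(0.1, 0), p), "deactivated")
})

test_that("imprint overwrites a tip-cell disk with the coupling value", {
  p <- default_parameters()
  fx <- tip_fixture(slope = 0, af0 = 0.3, n = 21)
  st <- capillary_state(fx$cf)   # all tissue (-1)
  tips <- empty_tips(2)
  tips[1, ] <- list(0.1, 0.1, 0.004062, 0, TRUE, 0)
  out <- imprint_tips(st, tips, fx$aff, p, fx$d)
  # c_c = S_p(0.3) * pi * R_c^2 / |v| ~ 0.0508
  cc_expect <- p$alpha_pSC * 0.3 * pi * p$R_c^2 / 0.004062
  expect_lt(abs(cc_expect - 0.0508), 5e-4)
  center_val <- out$c[11, 11]
  expect_equal(center_val, cc_expect, tolerance = 1e-12)
  # nodes within R_c changed, beyond R_c untouched
  expect_equal(out$c[11, 12], cc_expect)   # 0.01 < R_c = 0.0125
  expect_equal(out$c[11, 13], -1)          # 0.02 > R_c
  # no active tips -> unchanged
  tips$active <- FALSE
  expect_equal(imprint_tips(st, tips, fx$aff, p, fx$d)$c, st$c)
  # af <= 0 at the tip -> c_c = 0 imprinted
  fxn <- tip_fixture(slope = 0, af0 = -1, n = 21)
  tips$active <- TRUE
  outn <- imprint_tips(st, tips, fxn$aff, p, fx$d)
  expect_equal(outn$c[11, 11], 0)
})

test_that("movement integrates velocity and clamps at the boundary", {
  d <- sim_domain(c(0.2, 0.2), h = 0.01)
  tips <- empty_tips(2)
  tips[1, ] <- list(0.1, 0.1, 0.004062, 0, TRUE, 0)
  out <- move_tips(tips, dt = 1, d)
  expect_equal(out$x1, 0.104062)
  # dt = 0 leaves positions unchanged
  expect_equal(move_tips(tips, 0, d)$x1, 0.1)
  # outward motion at the boundary clamps
  tips[1, c("x1", "v1")] <- list(0.199, 0.02)
  expect_equal(move_tips(tips, 1, d)$x1, 0.2)
})

test_that("agent sweep invariants hold on a live scenario step", {
  p0 <- default_parameters()
  sc <- make_scenario("2d_sprouting", seed = 3)
  st <- scenario_initial_state(sc)
  for (k in 1:3) st <- rhangio::step(st)
  p <- st$p
  act <- st$tips[st$tips$active, ]
  if (nrow(act) >= 2) {
    pos <- as.matrix(act[, c("x1", "x2")])
    dd <- as.matrix(dist(pos))
    # tips may drift together after birth; Notch governs placement
    expect_true(all(dd[upper.tri(dd)] > 0))
  }
  # speed cap for every tip with an assigned velocity
  spd <- sqrt(act$v1^2 + act$v2^2)
  expect_true(all(spd <= p$chi * p$G_M + 1e-12))
  # determinism: identical scenario + seed gives identical histories
  st2 <- scenario_initial_state(make_scenario("2d_sprouting", seed = 3))
  for (k in 1:3) st2 <- rhangio::step(st2)
  expect_identical(st$history, st2$history)
  expect_identical(st$tips, st2$tips)
})
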
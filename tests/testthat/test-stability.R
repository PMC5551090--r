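test_that("the internal equilibrium is uniform and invariant", {
  eq <- internal_equilibrium()
  expect_equal(eq$h, rep(0.25, 4))
  expect_equal(eq$p, rep(0.25, 4))
  set.seed(21)
  for (k in 1:10) {
    out <- step_generation(eq, random_params())$state
    expect_equal(out$h, eq$h, tolerance = 1e-12)
    expect_equal(out$p, eq$p, tolerance = 1e-12)
  }
})

test_that("the spotted-parasite equilibrium exists only when spots are invisible", {
  blind <- acceptance_policy(0.8, 0.1, 0.8, 0.1)   # A0 = As, Ac = Acs
  res <- semi_internal_equilibrium(blind)
  expect_true(res$exists)
  expect_equal(res$state$p, c(0, 0, 0.5, 0.5))
  expect_equal(res$state$h, rep(0.25, 4))

  # with spottiness mutation off, it really is a fixed point
  pars <- model_params(blind, P = 0.05, mc = 2e-3, ms = 0)
  out <- step_generation(res$state, pars)$state
  expect_equal(out$h, res$state$h, tolerance = 1e-12)
  expect_equal(out$p, res$state$p, tolerance = 1e-12)

  # a spot-discriminating host forbids it
  expect_false(semi_internal_equilibrium(fig_policy())$exists)
})

test_that("jacobian demands a fixed point and honors limiting cases", {
  pars <- fig2_params(1e-4)
  expect_error(map_jacobian(pars, fig2_init()), "not a fixed point")

  # negligible parasitism, no mutation: neutral multipliers.  The host
  # block is the identity; the parasite block still couples to host
  # frequencies (rejection acts at any P) but every eigenvalue is 1.
  neutral <- model_params(fig_policy(), P = 1e-12, mc = 0, ms = 0)
  J <- map_jacobian(neutral, internal_equilibrium())
  expect_equal(J$reduced[1:3, ], cbind(diag(3), matrix(0, 3, 3)),
               tolerance = 1e-6)
  expect_lt(max(Mod(eigen(J$reduced, only.values = TRUE)$values - 1)),
            1e-6)

  # maximal mutation collapses every deviation in one generation
  mixing <- model_params(fig_policy(), P = 0.05, mc = 0.5, ms = 0.5)
  Jm <- map_jacobian(mixing, internal_equilibrium())
  expect_lt(max(abs(eigen(Jm$reduced, only.values = TRUE)$values)), 1e-6)
})

test_that("reduced and raw spectra agree on the non-trivial multipliers", {
  J <- map_jacobian(fig2_params(1e-4), internal_equilibrium())
  ev_red <- eigen(J$reduced, only.values = TRUE)$values
  ev_raw <- eigen(J$raw, only.values = TRUE)$values
  for (z in ev_red) {
    expect_lt(min(Mod(ev_raw - z)), 1e-8)
  }
})

test_that("mutation above/below the critical rate flips local stability", {
  expect_false(stability_report(fig2_params(1e-4))$stable)   # below m*
  expect_true(stability_report(fig2_params(4e-3))$stable)    # above m*
  rep_b <- stability_report(fig2_params(1e-4))
  expect_false(is.na(rep_b$predicted_period))
  expect_gt(rep_b$spectral_radius, 1)
})

test_that("bisection brackets the stability crossing", {
  pars <- fig2_params(1e-4)
  res <- mutation_threshold(pars, "both_equal")
  expect_s3_class(res, "threshold_result")
  expect_lt(res$tolerance, 1e-8)
  expect_identical(res$direction, "radius_decreasing")
  # the crossing really straddles 1
  lo <- stability_report(fig2_params(res$m_star * 0.99))$spectral_radius
  hi <- stability_report(fig2_params(res$m_star * 1.01))$spectral_radius
  expect_gt(lo, 1)
  expect_lt(hi, 1)
})

test_that("threshold search responds to the parasitism rate", {
  base05 <- fig2_params(1e-4)
  base10 <- model_params(fig_policy(), P = 0.1, mc = 1e-4, ms = 1e-4)
  m05 <- mutation_threshold(base05)$m_star
  m10 <- mutation_threshold(base10)$m_star
  expect_false(isTRUE(all.equal(m05, m10)))
  # direction measured, not assumed: doubling P strengthens selection,
  # so more mutation is needed to stabilize
  expect_gt(m10, m05)
})

test_that("a selectively neutral trait yields no stability crossing", {
  blind <- acceptance_policy(0.8, 0.1, 0.8, 0.1)
  pars <- model_params(blind, P = 0.05, mc = 1e-4, ms = 1e-4)
  expect_error(mutation_threshold(pars, "spottiness_only"), "no straddle")
})

test_that("log-log fitter recovers an exact power law", {
  P <- c(0.0125, 0.025, 0.05, 0.1, 0.2)
  expect_equal(power_law_exponent(P, 3.7 * P^(-0.5)), -0.5,
               tolerance = 1e-12)
})

test_that("oscillation period scales as the inverse square root of P", {
  res <- period_scaling(fig2_params(1e-4),
                        c(0.0125, 0.025, 0.05, 0.1, 0.2))
  expect_gt(res$exponent, -0.6)
  expect_lt(res$exponent, -0.4)
  # restated as a ratio: quadrupling P roughly halves the period
  expect_equal(res$periods[3] / res$periods[1], 0.5, tolerance = 0.05)
})

test_that("scaling errors out when a rate leaves the equilibrium stable", {
  expect_error(period_scaling(fig2_params(0.4),
                              c(0.0125, 0.025, 0.05, 0.1)),
               "stable")
})

test_that("near the threshold, trajectory and eigenvalue periods agree", {
  m <- 1.5e-3   # unstable side, close to m* ~ 1.94e-3
  pars <- fig2_params(m)
  pred <- stability_report(pars)$predicted_period
  tr <- simulate_dynamics(pars, fig2_init(), 5000)
  est <- estimate_period(tr)
  expect_lt(abs(est - pred) / est, 0.25)
})

test_that("mutation above m* converges, far below it does not", {
  mstar <- mutation_threshold(fig2_params(1e-4))$m_star
  up <- simulate_dynamics(fig2_params(2 * mstar), fig2_init(), 5000)
  expect_identical(classify_regime(up)$regime, "converged")
  down <- simulate_dynamics(fig2_params(mstar / 10), fig2_init(), 5000)
  expect_true(classify_regime(down)$regime %in%
                c("oscillating", "heteroclinic_like"))
})
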
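test_that("acceptance matrix realizes the mismatch rules and is symmetric", {
  A <- acceptance_matrix(fig_policy())
  # host row 1 against parasite types 1..4: match, color, spots, both
  expect_equal(unname(A[1, ]), c(0.8, 0.1, 0.1, 0.01))
  # blue-immaculate host vs blue-spotted parasite: spots only differ
  expect_identical(unname(A[2, 4]), 0.1)
  expect_identical(unname(A), unname(t(A)))
  expect_identical(unname(diag(A)), rep(0.8, 4))

  everything <- acceptance_policy(1, 1, 1, 1)   # indiscriminate acceptor
  expect_equal(unname(acceptance_matrix(everything)), matrix(1, 4, 4))
})

test_that("invalid acceptance policies and parameters are rejected", {
  expect_error(acceptance_policy(0.5, 0.6, 0.1, 0.01), "A0")
  expect_error(acceptance_policy(0.8, 0.1, 0.1, 0.2), "A0")  # Acs > Ac, As
  expect_error(acceptance_policy(0.8, 0.1, 0.1, -0.1), "probability")
  pol <- fig_policy()
  expect_error(model_params(pol, P = 0, mc = 0, ms = 0), "0 < P < 1")
  expect_error(model_params(pol, P = 1, mc = 0, ms = 0), "0 < P < 1")
  expect_error(model_params(pol, P = 0.05, mc = 0.6, ms = 0), "0, 0.5")
  expect_error(population_state(c(0.2, 0.2, 0.2, 0.3), rep(0.25, 4)),
               "sums to")
  expect_error(population_state(c(-0.1, 0.4, 0.4, 0.3), rep(0.25, 4)),
               "outside")
  # near-unit mass is renormalized exactly
  st <- population_state(rep(0.25, 4) + 2e-11, rep(0.25, 4))
  expect_identical(sum(st$h), 1)
})

test_that("mutation matrix is the independent two-trait product", {
  expect_equal(mutation_matrix(0, 0), diag(4))
  expect_equal(mutation_matrix(0.5, 0.5), matrix(0.25, 4, 4))

  m <- 1e-4
  M <- mutation_matrix(m, m)
  expect_equal(M[1, 1], (1 - m)^2)
  expect_equal(M[1, 2], m * (1 - m))
  expect_equal(M[1, 4], m^2)   # simultaneous double mutation

  # doubly stochastic and symmetric across a parameter sweep
  set.seed(11)
  for (k in 1:25) {
    Mk <- mutation_matrix(runif(1, 0, 0.5), runif(1, 0, 0.5))
    expect_equal(colSums(Mk), rep(1, 4), tolerance = 1e-14)
    expect_equal(rowSums(Mk), rep(1, 4), tolerance = 1e-14)
    expect_identical(Mk, t(Mk))
  }
})

test_that("fitness vectors follow the brood-loss / acceptance accounting", {
  pol <- fig_policy()
  A <- acceptance_matrix(pol)

  # vanishing parasitism removes selection on the host
  weak <- model_params(pol, P = 1e-15, mc = 0, ms = 0)
  expect_equal(host_fitness(rep(0.25, 4), weak, A), rep(1, 4),
               tolerance = 1e-14)

  # four-term hand arithmetic: p = (0,0,0.6,0.4), P = 0.05
  pars <- model_params(pol, P = 0.05, mc = 0, ms = 0)
  wH <- host_fitness(c(0, 0, 0.6, 0.4), pars, A)
  expect_equal(wH[1], 1 - 0.05 * (0.6 * 0.1 + 0.4 * 0.01))  # 0.9968

  # uniform parasite pool hits every host type equally
  expect_true(all(abs(diff(host_fitness(rep(0.25, 4), pars, A))) < 1e-15))

  # single-type host reads off one acceptance row
  expect_equal(parasite_fitness(c(1, 0, 0, 0), A), c(0.8, 0.1, 0.1, 0.01))
  expect_equal(parasite_fitness(rep(0.25, 4),
                                acceptance_matrix(acceptance_policy(1, 1, 1, 1))),
               rep(1, 4))
  expect_true(all(abs(diff(parasite_fitness(rep(0.25, 4), A))) < 1e-15))

  # total rejection is a signalled degenerate case
  Az <- acceptance_matrix(acceptance_policy(0, 0, 0, 0))
  expect_error(parasite_fitness(rep(0.25, 4), Az), "degenerate")
})

test_that("the uniform state is a fixed point for any valid parameters", {
  set.seed(42)
  uniform <- population_state(rep(0.25, 4), rep(0.25, 4))
  for (k in 1:30) {
    out <- step_generation(uniform, random_params())$state
    expect_equal(out$h, rep(0.25, 4), tolerance = 1e-12)
    expect_equal(out$p, rep(0.25, 4), tolerance = 1e-12)
  }
})

test_that("a monomorphic matched pair is absorbing without mutation", {
  pars <- model_params(fig_policy(), P = 0.3, mc = 0, ms = 0)
  st <- population_state(c(0, 1, 0, 0), c(0, 1, 0, 0))
  out <- step_generation(st, pars)$state
  expect_identical(out$h, c(0, 1, 0, 0))
  expect_identical(out$p, c(0, 1, 0, 0))
})

test_that("step output is normalized, non-negative, with consistent means", {
  set.seed(99)
  for (k in 1:25) {
    pars <- random_params()
    st <- random_state()
    out <- step_generation(st, pars)
    expect_equal(sum(out$state$h), 1, tolerance = 1e-12)
    expect_equal(sum(out$state$p), 1, tolerance = 1e-12)
    expect_true(all(out$state$h >= 0) && all(out$state$p >= 0))
    expect_identical(out$state$generation, st$generation + 1L)
    d <- out$diagnostics
    expect_equal(d$w_bar_H, sum(d$w_H * st$h), tolerance = 1e-14)
    expect_equal(d$w_bar_P, sum(d$w_P * st$p), tolerance = 1e-14)
  }
})

test_that("step matches the brute-force scalar-loop oracle", {
  set.seed(123)
  for (k in 1:100) {
    pars <- random_params()
    st <- random_state()
    got <- step_generation(st, pars)$state
    want <- oracle_step(st$h, st$p, pars$policy, pars$P, pars$mc, pars$ms)
    expect_equal(got$h, want$h, tolerance = 1e-14)
    expect_equal(got$p, want$p, tolerance = 1e-14)
  }
})

test_that("relabeling either trait commutes with the update", {
  set.seed(5)
  for (k in 1:25) {
    pars <- random_params()
    st <- random_state()
    stepped <- step_generation(st, pars)$state
    for (perm in list(swap_color(), swap_spottiness())) {
      swapped <- step_generation(
        population_state(st$h[perm], st$p[perm]), pars)$state
      expect_equal(swapped$h, stepped$h[perm], tolerance = 1e-15)
      expect_equal(swapped$p, stepped$p[perm], tolerance = 1e-15)
    }
  }
})
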
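test_that("per-capita recruitment matches hand-evaluated cases", {
  sp <- species_life_history(0, numeric(0), 0.5, 2)
  comm <- cdm_community(list(sp), matrix(1), q = 1)
  expect_equal(percap_growth(comm, 1), 1)  # 2 / (1 + 1)

  # zero density: growth at the density-independent ceiling
  cm <- random_community(21, m = 3)
  expect_equal(percap_growth(cm, rep(0, 3)), community_lambda(cm))

  # immature survival discount, delta = 2 with sigma = 0.5 each
  sp2 <- species_life_history(2, c(0.5, 0.5), 0.5, 2)
  comm2 <- cdm_community(list(sp2), matrix(1), q = 1)
  expect_equal(percap_growth_F(comm2, 1), percap_growth(comm2, 1) * 0.25)

  # no delay: F and G coincide
  expect_equal(percap_growth_F(comm, 1), percap_growth(comm, 1))

  # mosquito fixture at its equilibrium: G = z lambda / lambda_tilde = z
  ac <- anopheles_community()
  expect_equal(percap_growth(ac$community, ac$x_bar), rep(0.125, 3),
               tolerance = 1e-12)

  comm_noq <- cdm_community(list(sp), matrix(1))
  expect_error(percap_growth(comm_noq, 1), "q required")
  expect_error(percap_growth(comm, -1), "non-negative")
})

test_that("expanded step reproduces hand-evaluated branches", {
  # extinction is absorbing
  cm <- random_community(22, m = 3, delta_max = 3)
  n <- cm$m + sum(community_delta(cm))
  expect_equal(step_expanded(cm, rep(0, n)), rep(0, n))

  # delta = 0 merged branch: y' = sigma y + G y; 3 is the fixed point
  sp <- species_life_history(0, numeric(0), 0.5, 2)
  comm <- cdm_community(list(sp), matrix(1), q = 1)
  expect_equal(step_expanded(comm, 3), 3)
  expect_equal(step_expanded(comm, 1), 0.5 * 1 + 1 * 1)

  # delta = 1: recruit branch and adult branch evaluated separately
  sp1 <- species_life_history(1, 1, 0.6, 2)
  comm1 <- cdm_community(list(sp1), matrix(1), q = 1)
  G1 <- percap_growth(comm1, 1)
  expect_equal(step_expanded(comm1, c(1, 1)), c(G1 * 1, 1 * 1 + 0.6 * 1))
})

test_that("delayed and expanded forms generate identical adult trajectories", {
  for (seed in 1:10) {
    fc <- make_feasible_community(seed, delta_max = 5)
    cm <- fc$community
    h0 <- random_history(cm, seed + 500L)
    tr_d <- simulate(cm, nsim = 200, init = adult_history(cm, h0),
                     form = "delayed")
    y0 <- expanded_state_from_history(cm, adult_history(cm, h0))
    tr_e <- simulate(cm, nsim = 200, init = y0, form = "expanded")
    expect_lt(max(abs(tr_d$adults - tr_e$adults)), 1e-10)
    expect_true(all(tr_d$adults >= 0))
    expect_true(all(tr_e$adults >= 0))
  }
})

test_that("the interior equilibrium is a fixed point of both forms", {
  fc <- make_feasible_community(31, m = 3, delta_max = 4)
  cm <- fc$community
  eq <- interior_equilibrium(cm)
  expect_true(eq$feasible)
  y_star <- expanded_equilibrium_state(cm, eq$x_star)
  tr <- simulate(cm, nsim = 100, init = y_star, form = "expanded")
  expect_lt(max(abs(sweep(tr$adults, 2, eq$x_star))), 1e-10)
  h <- step_delayed(cm, adult_history(cm, eq$x_star))
  expect_lt(max(abs(current_adults(h) - eq$x_star)), 1e-12)
})

test_that("with no delays the two step maps coincide on adults", {
  set.seed(41)
  sp <- replicate(3, species_life_history(0, numeric(0), runif(1, 0.3, 0.7),
                                          runif(1, 1.5, 4)), simplify = FALSE)
  A <- matrix(runif(9, 0, 0.3), 3); diag(A) <- 1
  cm <- cdm_community(sp, A, q = runif(3, 0.5, 2))
  x <- runif(3, 0.5, 2)
  h <- step_delayed(cm, adult_history(cm, x))
  expect_equal(current_adults(h), step_expanded(cm, x))
})

test_that("stronger competition strictly lowers per-capita recruitment", {
  fc <- make_feasible_community(42, m = 3)
  cm <- fc$community
  x <- c(1, 2, 0.5)
  g0 <- percap_growth(cm, x)
  cm2 <- cm
  cm2$A[1, 3] <- cm2$A[1, 3] + 0.7
  g1 <- percap_growth(cm2, x)
  expect_lt(g1[1], g0[1])
  expect_equal(g1[-1], g0[-1])
})

test_that("simulate handles degenerate cases and bad input", {
  fc <- make_feasible_community(43, m = 2)
  tr <- simulate(fc$community, nsim = 0, init = c(1, 1))
  expect_equal(nrow(tr$adults), 1L)
  expect_error(simulate(fc$community, nsim = 5, init = c(1, 1), form = "bogus"))

  # single species with lambda_tilde < z decays toward extinction
  sp <- species_life_history(2, c(0.5, 0.5), 0.6, 1)  # lambda_tilde = 0.25 < z = 0.4
  cm <- cdm_community(list(sp), matrix(1), q = 1)
  tr <- simulate(cm, nsim = 300, init = 2)
  expect_lt(tr$adults[301, 1], 1e-6)
})

test_that("the non-delayed reduction shares the delayed system's equilibria", {
  fc <- make_feasible_community(44, m = 3, delta_max = 4)
  cm <- fc$community
  eq <- interior_equilibrium(cm)
  f <- reduce_to_nondelayed(cm)
  expect_equal(f(eq$x_star), eq$x_star, tolerance = 1e-12)

  # two-species no-delay case: iterating the reduction reaches the same
  # fixed point as direct iteration of the dynamics
  set.seed(45)
  sp <- replicate(2, species_life_history(0, numeric(0), 0.5, 3), simplify = FALSE)
  cm2 <- cdm_community(sp, matrix(c(1, 0.2, 0.3, 1), 2), q = 1)
  x <- c(1, 1)
  g <- reduce_to_nondelayed(cm2)
  for (k in 1:500) x <- g(x)
  tr <- simulate(cm2, nsim = 500, init = c(1, 1))
  expect_equal(x, unname(tr$adults[501, ]), tolerance = 1e-8)
  expect_equal(x, interior_equilibrium(cm2)$x_star, tolerance = 1e-8)

  # boundary of feasibility is flagged
  spb <- species_life_history(0, numeric(0), 0.5, 0.5)  # lambda_tilde == z
  cmb <- cdm_community(list(spb), matrix(1), q = 1)
  expect_warning(reduce_to_nondelayed(cmb), "trivial")
})

test_that("proportional perturbation scales whole species blocks", {
  ac <- anopheles_community()
  y_eq <- expanded_equilibrium_state(ac$community, ac$x_bar)
  y0 <- perturb_equilibrium(ac$community, ac$x_bar, c(0, 0, 0))
  expect_equal(y0, y_eq)
  y1 <- perturb_equilibrium(ac$community, ac$x_bar, c(0.5, 0, 0))
  blocks <- state_blocks(ac$community)
  expect_equal(y1[blocks[[1]]], 0.5 * y_eq[blocks[[1]]])
  expect_equal(y1[blocks[[2]]], y_eq[blocks[[2]]])
  expect_error(perturb_equilibrium(ac$community, ac$x_bar, c(1, 0, 0)), "\\[0, 1\\)")
})
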
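test_that("promoter occupancy matches independent hand evaluation", {
  p <- model_parameters()
  # derived constants from the Boltzmann weights and site numbers
  expect_equal(p$c1, 12 / 10000 * 5e6)
  expect_equal(p$c1, 6000)
  expect_equal(p$c2, (12 / 10000) / (1 / 10000))
  expect_equal(p$c2, 12)
  # direct arithmetic on the rate law, no autorepression load
  q <- promoter_rate(p, Theta = 4, Lambda = 2.875, P = 5050, A_minus = 0)
  expect_equal(q, 75 * 4 / (1 + 6000 * 2.875 / 5050))
  expect_equal(q, 67.937, tolerance = 1e-4)
  # no-autorepression limit: c2 = 0 ignores A_minus entirely
  p0 <- model_parameters(c2 = 0)
  expect_equal(promoter_rate(p0, 4, 2.875, 5050, 1e5),
               promoter_rate(p0, 4, 2.875, 5050, 0))
  # linear in gene dosage
  expect_equal(promoter_rate(p, 8, 2.875, 5050, 300),
               2 * promoter_rate(p, 4, 2.875, 5050, 300))
  # monotone decreasing in repressor and in genome load
  expect_true(promoter_rate(p, 4, 2.875, 5050, 500) <
                promoter_rate(p, 4, 2.875, 5050, 100))
  expect_true(promoter_rate(p, 4, 4, 5050, 0) <
                promoter_rate(p, 4, 2.875, 5050, 0))
  expect_error(promoter_rate(p, 4, 2.875, 0, 0), "P")
})

test_that("RNAP grows exponentially (or linearly) and doubles per cycle", {
  expect_equal(rnap_profile(5050, 21, 0), 5050)
  expect_equal(rnap_profile(5050, 21, 21), 10100)
  expect_equal(rnap_profile(5050, 21, 10.5), 5050 * sqrt(2))
  expect_equal(rnap_profile(5050, 21, 10.5, growth = "linear"),
               5050 * 1.5)
  expect_error(rnap_profile(5050, 21, 22))
})

test_that("balance equations and the initiation-potential identity agree", {
  p <- model_parameters()
  s <- build_schedule(cell_cycle_periods(21), k_lambda = p$k_lambda)
  # no forks: no RIDA, no replication
  d <- dnaa_rhs(cell_state(45, 800, 100, 2), build_schedule(
    cell_cycle_periods(60), k_lambda = p$k_lambda), p)
  expect_equal(unname(d["A_plus"]), 0)
  expect_equal(unname(d["Lambda"]), 0)
  # pure sink with silenced promoter: dA-/dt = -k_R * F
  psink <- model_parameters(k_A = 0)
  d2 <- dnaa_rhs(cell_state(10, 500, 0, 3.5), s, psink)
  expect_equal(unname(d2["A_minus"]), -10 * 6)
  # chain rule: d(A-/Lambda)/dt equals the published single equation for
  # r at randomly drawn states
  set.seed(42)
  for (k in 1:20) {
    t <- runif(1, 0, 21)
    A <- runif(1, 0, 2000)
    Lam <- runif(1, 2, 6)
    st <- cell_state(t, A, 50, Lam)
    d <- dnaa_rhs(st, s, p)
    lhs <- d[["A_minus"]] / Lam - A * d[["Lambda"]] / Lam^2
    prof <- profiles_at(s, t)
    P <- rnap_profile(p$P0, 21, t)
    r <- A / Lam
    rhs <- (prof$Theta / Lam) * p$k_A /
      (1 + p$c1 * Lam / P + p$c2 * (Lam / P) * r) -
      (p$k_R + r * p$k_lambda) * prof$F / Lam
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  expect_error(dnaa_rhs(cell_state(1, -5, 0, 2), s, p), "invalid state")
})

test_that("one-cycle integration reproduces closed forms in flat regions", {
  # tau = 60, c2 = 0: during the D period (40, 60) there are no forks,
  # Lambda and Theta are constant and Q depends only on the RNAP curve,
  # so A- grows by an explicit quadrature
  p <- model_parameters(c2 = 0)
  s <- build_schedule(cell_cycle_periods(60), k_lambda = p$k_lambda)
  tr <- integrate_cycle(cell_state(0, 300, 0, s$Lambda0), s, p,
                        step = test_step(60))
  i40 <- which.min(abs(tr$t - 40))
  expect_equal(tr$t[i40], 40)
  Lam <- tr$Lambda[i40]
  expect_equal(Lam, 2 * s$Lambda0)
  gain <- tr$A_minus[nrow(tr)] - tr$A_minus[i40]
  Qfun <- function(t) 75 * 2 / (1 + 6000 * Lam / (5050 * 2^(t / 60)))
  expected <- stats::integrate(Qfun, 40, 60, rel.tol = 1e-12)$value
  expect_equal(gain, expected, tolerance = 1e-6)
  # A+ and Lambda are exact quadratures of the fork profile
  expect_equal(tr$A_plus[nrow(tr)], 10 * 40, tolerance = 1e-9)
})

test_that("the integrator shows fourth-order step convergence", {
  p <- model_parameters()
  s <- build_schedule(cell_cycle_periods(21), k_lambda = p$k_lambda)
  init <- cell_state(0, 500, 0, s$Lambda0)
  ref <- integrate_cycle(init, s, p, step = 21 / 16384)
  endref <- ref$A_minus[nrow(ref)]
  errs <- vapply(c(8, 16, 32, 64, 128), function(n) {
    tr <- integrate_cycle(init, s, p, step = 21 / n)
    abs(tr$A_minus[nrow(tr)] - endref)
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 3.8 & orders < 4.2))
  # step halving at the production step leaves the solution unchanged
  # far below the verification tolerances
  a <- solve_cyclic_steady_state(s, p, step = test_step(21))
  b <- solve_cyclic_steady_state(s, p, step = test_step(21) / 2)
  expect_equal(attr(a, "r_X"), attr(b, "r_X"), tolerance = 1e-8)
})

test_that("the cyclic steady state closes the average-cell cycle", {
  p <- model_parameters()
  s <- build_schedule(cell_cycle_periods(21), k_lambda = p$k_lambda)
  tr <- solve_cyclic_steady_state(s, p, step = test_step(21))
  n <- nrow(tr)
  # genome doubles exactly; DnaA pools halve to the birth state
  expect_equal(tr$Lambda[n], 2 * tr$Lambda[1])
  expect_equal(tr$Lambda[1], 2.875)
  expect_equal(tr$A_minus[n] / 2, tr$A_minus[1], tolerance = 1e-9)
  expect_equal(tr$r[n], tr$r[1], tolerance = 1e-9)
  # DnaA-ADP birth value has the closed form k_R * integral(F)
  expect_equal(tr$A_plus[1], 10 * 115, tolerance = 1e-9)
  # A+ non-decreasing, Lambda non-decreasing within the cycle
  expect_true(all(diff(tr$A_plus) >= -1e-12))
  expect_true(all(diff(tr$Lambda) >= -1e-12))
  # independence from the starting guess
  tr2 <- solve_cyclic_steady_state(s, p, step = test_step(21),
                                   A0_init = 5000)
  expect_equal(tr2$A_minus, tr$A_minus, tolerance = 1e-6)
  # empty dynamics: nothing made, nothing converted
  p0 <- model_parameters(k_A = 0, k_R = 0)
  tr0 <- solve_cyclic_steady_state(s, p0, step = test_step(21))
  expect_true(all(tr0$A_minus == 0))
  expect_true(all(tr0$r == 0))
  # a silenced promoter with active RIDA drives DnaA-ATP negative:
  # reported as a regime the equations do not support
  expect_error(solve_cyclic_steady_state(s, model_parameters(k_A = 0),
                                         step = test_step(21)),
               "model-regime")
})

test_that("the initiation potential peaks at (or just past) initiation", {
  p <- model_parameters()
  for (tau in c(21, 27, 33, 40, 48, 55, 60)) {
    s <- build_schedule(cell_cycle_periods(tau), k_lambda = p$k_lambda)
    tr <- solve_cyclic_steady_state(s, p, step = test_step(tau))
    iX <- attr(tr, "i_X")
    # r accumulates from birth to initiation and the cycle maximum sits
    # at initiation up to the flat-top width of the peak
    expect_gte(tr$r[iX], tr$r[1])
    expect_gte(tr$r[iX], 0.995 * max(tr$r))
    # peak location, measured around the cycle (birth and division are
    # the same cycle phase)
    gap <- abs(tr$t[which.max(tr$r)] - s$X)
    expect_lte(min(gap, tau - gap), 0.15 * tau)
  }
})

test_that("trajectory export round-trips through CSV and JSON", {
  p <- model_parameters()
  s <- build_schedule(cell_cycle_periods(21), k_lambda = p$k_lambda)
  tr <- solve_cyclic_steady_state(s, p, step = 21 / 500)
  csv <- tempfile(fileext = ".csv")
  write_trajectory(tr, csv, "csv")
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$A_minus[1], tr$A_minus[1], tolerance = 1e-10)
  js <- tempfile(fileext = ".json")
  write_trajectory(tr, js, "json")
  meta <- jsonlite::read_json(js)
  expect_equal(meta$metadata$r_X, attr(tr, "r_X"))
  expect_equal(meta$metadata$params$k_A, 75)
})
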
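test_that("reversibility elasticities reproduce worked values and limits", {
  m1 <- matrix(1); m0 <- matrix(0)
  # 1 kJ/mol force at RT = 2.479: substrate ~ 3, product ~ -2
  th <- 1 / 2.479
  expect_equal(round(elasticity_rev(th, m1, m0)[1]), 3)
  expect_equal(round(elasticity_rev(th, m0, m1)[1]), -2)
  # 10 kJ/mol: 1.02 and -0.02
  th10 <- 10 / 2.479
  expect_equal(round(elasticity_rev(th10, m1, m0)[1], 2), 1.02)
  expect_equal(round(elasticity_rev(th10, m0, m1)[1], 2), -0.02)
  # completely forward driven: m_S for substrates, 0 for products
  expect_equal(elasticity_rev(60, matrix(2), m0)[1], 2, tolerance = 1e-12)
  expect_equal(elasticity_rev(60, m0, m1)[1], 0, tolerance = 1e-12)
  expect_error(elasticity_rev(0, m1, m0), "diverges at equilibrium")
  expect_warning(elasticity_rev(1e-8, m1, m0), "guard")
})

test_that("substrate elasticities fall and product elasticities rise with theta", {
  th <- seq(0.1, 10, length.out = 40)
  sub <- vapply(th, function(t) elasticity_rev(t, matrix(1), matrix(0))[1],
                numeric(1))
  pro <- vapply(th, function(t) elasticity_rev(t, matrix(0), matrix(1))[1],
                numeric(1))
  expect_true(all(diff(sub) < 0))
  expect_true(all(diff(pro) > 0))
  expect_true(all(sub > 0) && all(pro < 0))
})

test_that("mass-action elasticity equals the one-way-flux form", {
  set.seed(3)
  for (rep in 1:20) {
    th <- runif(1, 0.2, 6)
    mS <- matrix(sample(0:2, 3, replace = TRUE), 1)
    mP <- matrix(sample(0:2, 3, replace = TRUE), 1)
    v <- runif(1, 0.1, 2)
    a <- elasticity_ma(th, mS, mP)
    b <- elasticity_ma(th, mS, mP, v = v)
    expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # a mirrored reaction (flux and stoichiometry flipped) gives the same values
  fx <- make_fixture("linear_chain", n = 2)
  net2 <- fx$network
  net2$stoich[, 1] <- -net2$stoich[, 1]
  st2 <- stm_state(net2, fx$state$c, c(-1, 1) * fx$state$v,
                   c(-1, 1) * fx$state$ln_keq, check = FALSE)
  E1 <- elasticities(fx$network, fx$state, law = "ma")
  E2 <- elasticities(net2, st2, law = "ma")
  expect_equal(E1$E_scaled, E2$E_scaled, tolerance = 1e-12)
})

test_that("sm elasticities reduce to the irreversible structural-kinetic form", {
  # theta -> inf, beta_M -> 0: substrate elasticity -> m_S
  mS <- matrix(c(1, 0), 1); mP <- matrix(c(0, 1), 1)
  bM_small <- matrix(c(1e-12, 1e-12), 1)
  E <- elasticity_sm(50, beta_M = bM_small, m_S = mS, m_P = mP)
  skm <- mS * (1 - bM_small)
  expect_lt(max(abs(E[1, 1] - skm[1, 1])), 1e-9)
  expect_lt(abs(E[1, 2]), 1e-9)
  # inhibitor with beta = 1/2: contribution -1/2
  Ei <- elasticity_sm(2, beta_M = matrix(NA, 1, 2), m_S = matrix(0, 1, 2),
                      m_P = matrix(0, 1, 2), beta_I = matrix(c(NA, 0.5), 1),
                      m_I = matrix(c(0, 1), 1))
  expect_equal(Ei[1, 2], -0.5)
  # beta_M = 0 limit: back to the reversibility term alone
  E0 <- elasticity_sm(1.3, beta_M = matrix(c(1e-15, 1e-15), 1), m_S = mS, m_P = mP)
  expect_equal(E0, elasticity_rev(1.3, mS, mP), tolerance = 1e-12)
})

test_that("cm elasticities agree with numerical differentiation on random fixtures", {
  set.seed(42)
  worst <- 0
  for (rep in 1:20) {
    fx <- make_fixture("random", n_met = 3, n_rxn = 4, seed = 100 + rep)
    sat <- sample_saturation(fx$network)
    mod <- reconstruct_kinetics(fx$network, fx$state, sat, "cm")
    E <- suppressWarnings(elasticities(fx$network, fx$state, sat, "cm"))
    h <- 1e-6
    lnc0 <- log(fx$state$c)
    for (i in seq_along(lnc0)) {
      up <- lnc0; up[i] <- up[i] + h
      dn <- lnc0; dn[i] <- dn[i] - h
      num <- (log(abs(model_rates(mod, exp(up)))) -
                log(abs(model_rates(mod, exp(dn))))) / (2 * h)
      dev <- max(abs(num - E$E_scaled[, i]) /
                   pmax(abs(E$E_scaled[, i]), 1))
      worst <- max(worst, dev)
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("cm substrate elasticity approaches E_rev - m_S at full saturation", {
  mS <- matrix(1); mP <- matrix(0)
  b <- matrix(1 - 1e-7)
  E <- elasticity_cm(3, c = 1, beta_M = b, m_S = mS, m_P = mP)
  expect_equal(E[1, 1], elasticity_rev(3, mS, mP)[1, 1] - 1, tolerance = 1e-3)
  # beta -> 0 recovers the reversibility term
  E0 <- elasticity_cm(3, c = 1, beta_M = matrix(1e-12), m_S = mS, m_P = mP)
  expect_equal(E0[1, 1], elasticity_rev(3, mS, mP)[1, 1], tolerance = 1e-9)
})

test_that("factorised-law elasticities match the eta_rev derivative", {
  # oracle: v(c) = e kcat (1 - exp(-theta(c))) with eta_sat constant
  lnkeq <- 3
  theta_of <- function(cS, cP) lnkeq + log(cS) - log(cP)  # S -> P
  v_of <- function(cS, cP) 1 - exp(-theta_of(cS, cP))
  h <- 1e-7
  for (cp in c(0.5, 1, 2)) {
    th <- theta_of(1, cp)
    num_S <- (log(v_of(exp(h), cp)) - log(v_of(exp(-h), cp))) / (2 * h)
    num_P <- (log(v_of(1, cp * exp(h))) - log(v_of(1, cp * exp(-h)))) / (2 * h)
    E <- elasticity_factorized(th, matrix(c(-1, 1), 1))
    expect_equal(E[1, 1], num_S, tolerance = 1e-6)
    expect_equal(E[1, 2], num_P, tolerance = 1e-6)
  }
})

test_that("sign rule holds across feasible random fixtures", {
  set.seed(77)
  for (rep in 1:10) {
    fx <- make_fixture("random", n_met = 4, n_rxn = 5, seed = 200 + rep)
    sat <- sample_saturation(fx$network)
    E <- suppressWarnings(elasticities(fx$network, fx$state, sat, "cm"))
    s <- sign(fx$state$v)
    for (l in seq_along(s)) {
      n <- fx$network$stoich[, l] * s[l]   # oriented: substrates < 0
      expect_true(all(E$E_scaled[l, n < 0] > 0))
      expect_true(all(E$E_scaled[l, n > 0] < 0))
    }
  }
})

test_that("scaled and unscaled elasticities round-trip", {
  fx <- make_fixture("bypass")
  E <- elasticities(fx$network, fx$state, fx$saturation, "cm")
  back <- convert_elasticities(E$E_unscaled, fx$state$v, fx$state$c, "scaled")
  expect_equal(back, E$E_scaled, tolerance = 1e-12)
})

test_that("second-order elasticities are symmetric and step-size robust", {
  fx <- make_fixture("bypass", beta = 0.4)
  mod <- reconstruct_kinetics(fx$network, fx$state, fx$saturation, "cm")
  E2a <- second_order_elasticities(mod, h = 1e-4)
  E2b <- second_order_elasticities(mod, h = 1e-5)
  m <- E2a$E2_scaled
  expect_lt(max(abs(m - aperm(m, c(1, 3, 2)))), 1e-8)
  expect_lt(max(abs(E2a$E2_scaled - E2b$E2_scaled)), 1e-5)

  # strongly driven mass-action law is log-linear: zero log-Hessian
  fchain <- make_fixture("linear_chain", n = 2, theta = 50)
  modma <- reconstruct_kinetics(fchain$network, fchain$state,
                                fchain$saturation, "ma")
  E2ma <- second_order_elasticities(modma)
  expect_lt(max(abs(E2ma$E2_scaled)), 1e-6)
})
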
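test_that("saturation values and dissociation constants are mutual inverses", {
  expect_equal(saturation_from_constants(1, 1), 0.5)
  expect_equal(constants_from_saturation(1, 0.5), 1)
  expect_equal(saturation_from_constants(3, 1), 0.75)
  expect_error(constants_from_saturation(1, 1), "strictly inside")
  set.seed(5)
  c <- runif(50, 0.01, 10); k <- runif(50, 0.01, 10)
  expect_equal(constants_from_saturation(c, saturation_from_constants(c, k)), k,
               tolerance = 1e-12)
})

test_that("uniform saturation values imply standard-logistic log c/kM ratios", {
  set.seed(8)
  beta <- runif(1e5)
  lnratio <- log(beta / (1 - beta))   # ln(c/kM) at fixed c via k = c(1-b)/b
  ks <- suppressWarnings(ks.test(lnratio, "plogis"))
  expect_gt(ks$p.value, 0.01)
})

test_that("all rate laws vanish at chemical equilibrium", {
  set.seed(12)
  for (law in c("cm", "sm", "ma")) {
    for (rep in 1:5) {
      fx <- make_fixture("bypass", theta = runif(1, 1.5, 4))
      sat <- sample_saturation(fx$network)
      mod <- reconstruct_kinetics(fx$network, fx$state, sat, law)
      # move every reaction to equilibrium: c realising theta = 0
      # chain of potentials: with ln c = pinv solution of N' ln c = ln_keq
      lnc_eq <- as.numeric(pracma::pinv(t(fx$network$stoich)) %*% fx$state$ln_keq)
      th_eq <- compute_forces(fx$network, exp(lnc_eq), fx$state$ln_keq)
      expect_lt(max(abs(th_eq)), 1e-9)
      v_eq <- model_rates(mod, exp(lnc_eq))
      expect_lt(max(abs(v_eq)), 1e-10)
    }
  }
})

test_that("cm law reduces to mass action at low saturation and no backward rate", {
  N <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "R1"))
  net <- stm_network(N, external = c("A", "B"))
  st <- suppressWarnings(stm_state(net, c(A = 1, B = 1), v = 1, ln_keq = 30,
                                   check = FALSE))
  sat <- stm_saturation(net, beta_M = 0.5)
  mod <- reconstruct_kinetics(net, st, sat, "cm")
  c_low <- c(A = 1e-5, B = 1e-9)
  expected_ma <- mod$e[1] * mod$k_cat_plus[1] * (c_low["A"] / mod$k_M[1, "A"])
  expect_equal(unname(model_rates(mod, c_low)[1]), unname(expected_ma),
               tolerance = 1e-3)
})

test_that("cm rate factorises into e kcat eta_rev eta_sat", {
  fx <- make_fixture("bypass", beta = 0.37)
  mod <- reconstruct_kinetics(fx$network, fx$state, fx$saturation, "cm")
  mol <- stmkin:::molecularity_matrices(fx$network)
  for (l in seq_along(fx$network$reactions)) {
    idx <- which((mol$m_S + mol$m_P)[l, ] > 0)
    ratio <- fx$state$c[idx] / mod$k_M[l, idx]
    psi_p <- prod((1 + ratio)^mol$m_S[l, idx])
    psi_m <- prod((1 + ratio)^mol$m_P[l, idx])
    eta_sat <- prod(ratio^mol$m_S[l, idx]) / (psi_p + psi_m - 1)
    eta_rev <- 1 - exp(-fx$state$theta[l])
    v_fact <- mod$e[l] * mod$k_cat_plus[l] * eta_rev * eta_sat
    expect_equal(unname(v_fact), unname(fx$state$v[l]), tolerance = 1e-9)
  }
})

test_that("reconstruction satisfies Haldane and reproduces the reference state", {
  set.seed(33)
  for (rep in 1:10) {
    fx <- make_fixture(sample(c("bypass", "moiety_cycle", "linear_chain"), 1),
                       n = 3)
    sat <- sample_saturation(fx$network)
    for (basis in c("kV", "kcat_plus")) {
      mod <- reconstruct_kinetics(fx$network, fx$state, sat, "cm",
                                  basis = basis, k_cat_plus = 10)
      expect_lt(max(abs(haldane_residual(mod))), 1e-9)
      expect_equal(mod$k_V^2, mod$k_cat_plus * mod$k_cat_minus,
                   tolerance = 1e-9, ignore_attr = TRUE)
      v <- model_rates(mod, fx$state$c)
      expect_equal(v, fx$state$v, tolerance = 1e-9)
    }
  }
})

test_that("rates are proportional to enzyme level", {
  fx <- make_fixture("bypass")
  mod <- reconstruct_kinetics(fx$network, fx$state, fx$saturation, "cm")
  mod2 <- mod; mod2$e <- 2 * mod$e
  expect_equal(model_rates(mod2, fx$state$c), 2 * model_rates(mod, fx$state$c),
               tolerance = 1e-12)
})

test_that("closed-form cm elasticities match finite differences of the rate law", {
  fx <- make_fixture("bypass", beta = 0.3)
  mod <- reconstruct_kinetics(fx$network, fx$state, fx$saturation, "cm")
  E <- elasticities(fx$network, fx$state, fx$saturation, "cm")
  h <- 1e-6
  lnc0 <- log(fx$state$c)
  for (i in seq_along(lnc0)) {
    up <- lnc0; up[i] <- up[i] + h
    dn <- lnc0; dn[i] <- dn[i] - h
    num <- (log(abs(model_rates(mod, exp(up)))) -
              log(abs(model_rates(mod, exp(dn))))) / (2 * h)
    expect_equal(unname(num), unname(E$E_scaled[, i]), tolerance = 1e-6)
  }
})
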
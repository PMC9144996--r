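test_that("1x1 Jacobian gives relaxation time 1/E and shifts with dilution", {
  # single internal metabolite, constant inflow, outflow with elasticity E
  N <- matrix(c(1, -1), 1, 2, dimnames = list("S", c("Rin", "Rout")))
  net <- stm_network(N)
  red <- reduce_network(net)
  Eun <- matrix(c(0, 2.5), 2, 1, dimnames = list(c("Rin", "Rout"), "S"))
  A <- jacobian(red, Eun)
  expect_equal(A$A[1, 1], -2.5)
  expect_equal(-1 / A$A[1, 1], 1 / 2.5)  # relaxation time 1/E
  A_lam <- jacobian(red, Eun, growth_rate = 0.3)
  expect_equal(A_lam$eigenvalues, A$eigenvalues - 0.3, tolerance = 1e-12)
})

test_that("a strongly driven upstream reaction takes all flux control", {
  fx <- make_fixture("linear_chain", n = 2)
  st <- fx$state
  st$theta <- c(R1 = 60, R2 = 2)   # upstream product elasticity ~ 0
  E <- elasticities(fx$network, st, law = "ma")
  ctl <- control_matrices(reduce_network(fx$network), E$E_unscaled,
                          net = fx$network)
  Cs <- diag(1 / st$v) %*% ctl$C_V %*% diag(st$v)
  expect_equal(Cs[1, 1], 1, tolerance = 1e-12)
  expect_equal(Cs[1, 2], 0, tolerance = 1e-12)
  # summation theorem: scaled flux control sums to 1 along the chain
  expect_equal(rowSums(Cs), c(1, 1), tolerance = 1e-10)
})

test_that("summation and connectivity theorems hold on random stable fixtures", {
  for (seed in 1:10) {
    fx <- random_stable_fixture(seed)
    red <- fx$control$reduced
    Ec <- fx$control$elasticities$E_unscaled[, !fx$network$external, drop = FALSE]
    C_V <- fx$control$C_V; C_S <- fx$control$C_S
    expect_lt(max(abs(C_V %*% red$K - red$K)), 1e-8)
    expect_lt(max(abs(C_S %*% red$K)), 1e-8)
    expect_lt(max(abs(C_V %*% Ec %*% red$L)), 1e-8)
    expect_lt(max(abs(C_S %*% Ec %*% red$L + red$L)), 1e-8)
  }
})

test_that("closed-form control matches steady-state perturbation of the model", {
  fx <- make_fixture("linear_chain", n = 3, theta = 2.5)
  sat <- stm_saturation(fx$network, beta_M = 0.4)
  mod <- reconstruct_kinetics(fx$network, fx$state, sat, "cm")
  ctl <- control_analysis(fx$network, fx$state, sat, "cm")
  fd <- fd_scaled_control(mod)
  expect_equal(fd$C_V, ctl$C_V_scaled, tolerance = 1e-3)
  expect_equal(fd$C_S, ctl$C_S_scaled, tolerance = 1e-3)
})

test_that("enzyme responses equal control coefficients on log scale", {
  fx <- make_fixture("bypass")
  ctl <- control_analysis(fx$network, fx$state)
  E_e <- diag(fx$state$v / 1)      # unscaled enzyme elasticity dv/de at e = v/u
  resp <- response_matrices(ctl, E_e)
  # scaled response = (1/v) R diag(e); with E_e = diag(v/e) this is C_V scaled
  mod <- reconstruct_kinetics(fx$network, fx$state, fx$saturation, "cm")
  E_e <- diag(fx$state$v / mod$e)
  resp <- response_matrices(ctl, E_e)
  Rhat <- diag(1 / fx$state$v) %*% resp$R_v %*% diag(mod$e)
  expect_equal(Rhat, unname(ctl$C_V_scaled), tolerance = 1e-10, ignore_attr = TRUE)
  # external substrate response of a chain flux is positive
  fc <- make_fixture("linear_chain", n = 2)
  ctl2 <- control_analysis(fc$network, fc$state)
  E_ext <- ctl2$elasticities$E_unscaled[, fc$network$external, drop = FALSE]
  r2 <- response_matrices(ctl2, E_ext)
  expect_gt(r2$R_v["R1", "X0"], 0)
  expect_gt(r2$R_v["R2", "X0"], 0)
})

test_that("synergy signs distinguish serial from parallel enzymes", {
  fx <- make_fixture("bypass")
  mod <- reconstruct_kinetics(fx$network, fx$state, fx$saturation, "cm")
  syn <- synergy_coefficients(mod, "R_out",
                              rbind(c("R_s12", "R_s23"),
                                    c("R_direct", "R_s12")))
  expect_equal(syn$classification, c("buffering", "aggravating"))
  # step-size robustness: 1e-3 vs 5e-4 agree to 1%
  syn2 <- synergy_coefficients(mod, "R_out", rbind(c("R_s12", "R_s23")),
                               delta = 5e-4)
  expect_equal(syn2$synergy[1], syn$synergy[1], tolerance = 1e-2)
})

test_that("synergy effect eta measures deviation from independence", {
  expect_equal(synergy_eta(0.8, 0.5, 0.4), 0)
  expect_gt(synergy_eta(0.9, 0.9, 0.9), 0)   # buffering
  expect_lt(synergy_eta(0.9, 0.9, 0.5), 0)   # aggravating
  expect_equal(synergy_eta(0.3, 0.4, 0.9, form = "additive"), 0.2)
  expect_error(synergy_eta(-1, 0.5, 0.4), "nonpositive")
})

test_that("spectral response reduces to statics at omega 0 and is Lorentzian in 1D", {
  fx <- make_fixture("linear_chain", n = 2, theta = 3)
  red <- reduce_network(fx$network)
  E <- elasticities(fx$network, fx$state, fx$saturation, "cm")
  Ep <- diag(2)
  ctl <- control_matrices(red, E$E_unscaled, net = fx$network)
  om <- c(0, 10^seq(-2, 3, length.out = 30))
  R <- spectral_response(red, E$E_unscaled, Ep, om, net = fx$network)
  R0 <- ctl$C_S %*% Ep
  expect_equal(Re(R$R_c[, , 1]), unname(R0), tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(Im(R$R_c[, , 1]))), 1e-12)
  # scalar resolvent: |R(w)|^2 = |R(0)|^2 / (1 + (w/E)^2)
  a <- -ctl$A[1, 1]
  for (k in c(10, 20, 30)) {
    ratio <- as.numeric(abs(R$R_c[1, 1, k])^2 / abs(R$R_c[1, 1, 1])^2)
    expect_equal(ratio, 1 / (1 + (om[k] / a)^2), tolerance = 1e-10)
  }
  # high frequencies are damped
  expect_lt(max(abs(R$R_c[, , length(om)])), 1e-2 * max(abs(R$R_c[, , 1])))
})

test_that("linearised time courses decay and conserve moieties", {
  # scalar: A = -k gives exp(-k t)
  N <- matrix(c(1, -1), 1, 2, dimnames = list("S", c("Rin", "Rout")))
  net <- stm_network(N)
  red <- reduce_network(net)
  A <- matrix(-0.7, 1, 1)
  tc <- linear_timecourse(A, red, 1, seq(0, 5, 0.25))
  expect_equal(as.numeric(tc), exp(-0.7 * seq(0, 5, 0.25)), tolerance = 1e-6)
  expect_equal(linear_timecourse(A, red, 0, 0:3), cbind(S = rep(0, 4)),
               ignore_attr = TRUE)
  # moiety fixture: G . delta_c constant over time
  fm <- make_fixture("moiety_cycle")
  redm <- reduce_network(fm$network)
  Em <- elasticities(fm$network, fm$state, fm$saturation, "cm")
  Am <- jacobian(redm, Em$E_unscaled, net = fm$network)
  d0 <- c(0.2, -0.2)
  tcm <- linear_timecourse(Am$A, redm, d0, seq(0, 10, 1))
  tot <- tcm %*% t(redm$G)
  expect_lt(max(abs(tot - tot[1])), 1e-10)
})

test_that("the turbo design shows paradoxical negative self-control at strong forces", {
  fx <- make_fixture("turbo", theta = 4)
  ctl <- control_analysis(fx$network, fx$state, law = "cm")
  expect_true(ctl$stable)
  # the ATP-draining enzyme decreases its own steady-state flux
  expect_lt(ctl$C_V_scaled["R_atpase", "R_atpase"], 0)
  # closer to equilibrium the effect disappears
  weak <- make_fixture("turbo", theta = 1)
  ctl_weak <- control_analysis(weak$network, weak$state, law = "cm")
  expect_gt(ctl_weak$C_V_scaled["R_atpase", "R_atpase"], 0)
  # confirmed on the reconstructed nonlinear model
  mod <- reconstruct_kinetics(fx$network, fx$state, stm_saturation(fx$network),
                              "cm")
  fd <- fd_scaled_control(mod)
  expect_lt(fd$C_V["R_atpase", "R_atpase"], 0)
})

test_that("singular steady states are reported", {
  fx <- make_fixture("linear_chain", n = 2)
  red <- reduce_network(fx$network)
  E0 <- matrix(0, 2, 1)   # all elasticities zero: deficient
  expect_error(control_matrices(red, E0), "deficient steady state")
})
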
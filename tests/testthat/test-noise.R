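test_that("static covariance propagates through the response matrix", {
  R <- matrix(0.5)
  expect_equal(static_covariance(R, matrix(0))[1, 1], 0)
  expect_equal(sqrt(static_covariance(R, matrix(log(2)^2))[1, 1]), 0.5 * log(2))
  expect_error(static_covariance(matrix(1, 1, 2), matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
  # omega -> 0 spectral slice equals static propagation
  fx <- make_fixture("linear_chain", n = 2, theta = 3)
  red <- reduce_network(fx$network)
  E <- elasticities(fx$network, fx$state, fx$saturation, "cm")
  ctl <- control_matrices(red, E$E_unscaled, net = fx$network)
  Ep <- diag(2)
  Sigma_p <- diag(c(0.3, 0.7))
  sp <- propagate_spectrum(red, E$E_unscaled, Ep, Sigma_p, omega = c(0, 1),
                           net = fx$network)
  Sigma_c_static <- static_covariance(ctl$C_S %*% Ep, Sigma_p)
  expect_equal(Re(sp$S_c[, , 1]), unname(Sigma_c_static), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("chemical noise power reflects one-way fluxes", {
  NA_mM_um3 <- 6.02214076e5
  fx <- make_fixture("linear_chain", n = 2, theta = 40)
  src <- chemical_noise_source(fx$state, volume_um3 = 2)
  # strongly driven: v+ ~ v, v- ~ 0 -> minimal noise v/(Omega N_A)
  expect_equal(unname(src$s), rep(1 / (2 * NA_mM_um3), 2), tolerance = 1e-6)
  # halving theta at fixed net flux strictly increases the noise
  st_half <- scale_forces(fx$network, fx$state, 0.5)
  expect_true(all(chemical_noise_source(st_half, 2)$s > src$s))
  th <- seq(5, 0.2, length.out = 10)
  pw <- vapply(th, function(t) {
    ow <- one_way_fluxes(1, t)
    ow$v_plus + ow$v_minus
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
  # at equilibrium with net flux the one-way rates are undefined
  st_bad <- fx$state; st_bad$theta <- c(0, 40)
  expect_error(chemical_noise_source(st_bad), "equilibrium")
})

test_that("counting 1e4 events per second gives 1 percent relative noise", {
  rate <- 1e4  # Poisson events per second, counted over 1 s
  expect_equal(sqrt(rate) / rate, 0.01)
})

test_that("a single metabolite with white noise has a Lorentzian spectrum", {
  fx <- make_fixture("linear_chain", n = 2, theta = 5)
  red <- reduce_network(fx$network)
  E <- elasticities(fx$network, fx$state, fx$saturation, "cm")
  A <- jacobian(red, E$E_unscaled, net = fx$network)$A
  a <- -A[1, 1]
  # unit white noise entering through the supply reaction only
  Ep <- matrix(c(1, 0), 2, 1)
  om <- default_omega_grid(40, c(1e-3, 1e3))
  sp <- propagate_spectrum(red, E$E_unscaled, Ep, matrix(1), om, net = fx$network)
  got <- Re(sp$S_c[1, 1, ])
  expect_equal(got, 1 / (a^2 + om^2), tolerance = 1e-10)
  # high-frequency diagonal decays like 1/omega^2
  tail_ratio <- got[40] / got[30]
  expect_equal(tail_ratio, (om[30]^2 + a^2) / (om[40]^2 + a^2), tolerance = 1e-9)
})

test_that("high-frequency fluctuations are damped with distance from the source", {
  fx <- make_fixture("linear_chain", n = 5, theta = 4)
  red <- reduce_network(fx$network)
  E <- elasticities(fx$network, fx$state, fx$saturation, "cm")
  # noise source: the first (supply) reaction only
  Ep <- matrix(0, 5, 1); Ep[1, 1] <- 1
  sp <- propagate_spectrum(red, E$E_unscaled, Ep, matrix(1), omega = c(1),
                           net = fx$network)
  diag1 <- Re(diag(sp$S_c[, , 1]))
  expect_true(all(diff(diag1) < 0))   # monotone decay along the chain
})

test_that("spectral matrices are Hermitian positive semidefinite", {
  fx <- make_fixture("bypass")
  red <- reduce_network(fx$network)
  E <- elasticities(fx$network, fx$state, fx$saturation, "cm")
  src <- chemical_noise_source(fx$state)
  Ep <- diag(5)
  om <- default_omega_grid(20, c(1e-3, 1e2))
  sp <- propagate_spectrum(red, E$E_unscaled, Ep, src$S, om, net = fx$network)
  for (k in seq_along(om)) {
    S <- sp$S_c[, , k]
    expect_lt(max(abs(S - Conj(t(S)))), 1e-12)
    ev <- eigen(S, only.values = TRUE)$values
    expect_gt(min(Re(ev)), -1e-10)
    expect_true(all(Re(diag(S)) >= 0))
  }
})

test_that("windowed variances match the Ornstein-Uhlenbeck closed form", {
  s <- 2; E <- 1.3
  om <- default_omega_grid(4000, c(1e-6, 1e5))
  S <- s / (E^2 + om^2)
  dt <- c(1e-4, 0.01, 0.1, 1, 10, 100)
  w <- windowed_std(S, om, dt)
  closed <- sqrt(s * (E * dt - 1 + exp(-E * dt)) / (E^3 * dt^2))
  expect_equal(as.numeric(w), closed, tolerance = 0.01)
  # dt -> 0 recovers the total variance s/(2E)
  expect_equal(as.numeric(w[1, 1])^2, s / (2 * E), tolerance = 0.01)
  # non-increasing in the window width
  expect_true(all(diff(as.numeric(w)) <= 0))
})
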
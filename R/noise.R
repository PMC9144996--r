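# Static covariance and frequency-resolved fluctuation propagation, with
# chemical Langevin noise sources from one-way fluxes.

# molecules per (um^3 mM): Avogadro * 1e-3 mol/L * 1e-15 L/um^3
MOLECULES_PER_UM3_MM <- 6.02214076e23 * 1e-3 * 1e-15

#' Static covariance propagation
#'
#' First-order propagation `Sigma_target = R Sigma_p R'` of parameter
#' covariance through a response matrix. With scaled (log) response matrices
#' and log-scale parameter covariance, the result is the covariance of log
#' state variables.
#'
#' @param R response matrix (target x parameter)
#' @param Sigma_p symmetric positive semidefinite parameter covariance.
#' @return covariance matrix of the targets.
#' @export
static_covariance <- function(R, Sigma_p) {
  Sigma_p <- as.matrix(Sigma_p)
  if (nrow(Sigma_p) != ncol(R)) stop("dimension mismatch")
  ev <- eigen((Sigma_p + t(Sigma_p)) / 2, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) stop("Sigma_p is not positive semidefinite")
  out <- R %*% Sigma_p %*% t(R)
  dimnames(out) <- list(rownames(R), rownames(R))
  out
}

#' Chemical Langevin noise source from one-way fluxes
#'
#' Single reaction events occur stochastically in both directions, so the
#' white-noise spectral density of each rate is proportional to the *sum* of
#' one-way fluxes, not the net flux:
#' `s_l = (v+_l + v-_l) / (Omega N_A)` in concentration-rate units
#' (mM^2/s for fluxes in mM/s and a cell volume Omega in um^3). Reactions
#' close to equilibrium carry large one-way fluxes at fixed net flux
#' (`v+ + v- = |v| coth(|theta|/2)`) and therefore produce strong noise.
#'
#' @param state an `stm_state` (feasible; forces nonzero where fluxes are).
#' @param volume_um3 cell volume Omega (um^3), default 2.
#' @return list with diagonal spectral density matrix `S` (white,
#'   frequency-constant) and the per-reaction densities `s`.
#' @export
chemical_noise_source <- function(state, volume_um3 = 2) {
  if (any(state$v != 0 & state$theta == 0)) {
    stop("infinite one-way flux at equilibrium (theta = 0 with v != 0)")
  }
  ow <- one_way_fluxes(state$v, state$theta)
  s <- (ow$v_plus + ow$v_minus) / (volume_um3 * MOLECULES_PER_UM3_MM)
  names(s) <- names(state$v)
  list(S = diag(s, length(s)), s = s, white = TRUE)
}

#' Propagate parameter noise spectra through the linearised network
#'
#' `S_c(omega) = R_c(omega) S_p(omega) R_c(omega)^H` and analogously for
#' fluxes, using the spectral response matrices. Diagonals are real and
#' non-negative; high-frequency diagonals decay like 1/omega^2.
#'
#' @param reduced an `stm_reduced`
#' @param E_unscaled unscaled elasticity matrix (reaction x internal
#'   metabolites, or full with `net`).
#' @param E_p unscaled parameter elasticity matrix (reaction x parameter).
#' @param S_p parameter spectral density: a constant matrix (white noise) or
#'   a function of omega returning one.
#' @param omega frequency grid (1/s); default 200 log-spaced points on
#'   [1e-5, 1e3].
#' @param growth_rate dilution rate lambda.
#' @param net optional network for column subsetting.
#' @return object of class `stm_spectra` with complex arrays `S_c`
#'   (metabolite x metabolite x omega), `S_v`, and `omega`.
#' @export
propagate_spectrum <- function(reduced, E_unscaled, E_p, S_p,
                               omega = default_omega_grid(),
                               growth_rate = 0, net = NULL) {
  R <- spectral_response(reduced, E_unscaled, E_p, omega, growth_rate, net)
  Sp_fun <- if (is.function(S_p)) S_p else function(w) S_p
  n_i <- dim(R$R_c)[1]; n_r <- dim(R$R_v)[1]
  S_c <- array(complex(real = 0), c(n_i, n_i, length(omega)),
               dimnames = list(dimnames(R$R_c)[[1]], dimnames(R$R_c)[[1]], NULL))
  S_v <- array(complex(real = 0), c(n_r, n_r, length(omega)),
               dimnames = list(dimnames(R$R_v)[[1]], dimnames(R$R_v)[[1]], NULL))
  for (k in seq_along(omega)) {
    Sp <- as.matrix(Sp_fun(omega[k]))
    Rc <- R$R_c[, , k, drop = FALSE]; dim(Rc) <- dim(R$R_c)[1:2]
    Rv <- R$R_v[, , k, drop = FALSE]; dim(Rv) <- dim(R$R_v)[1:2]
    S_c[, , k] <- Rc %*% Sp %*% Conj(t(Rc))
    S_v[, , k] <- Rv %*% Sp %*% Conj(t(Rv))
  }
  structure(list(S_c = S_c, S_v = S_v, omega = omega), class = "stm_spectra")
}

#' @export
print.stm_spectra <- function(x, ...) {
  cat("<stm_spectra> ", dim(x$S_c)[1], " metabolites, ", dim(x$S_v)[1],
      " reactions, ", length(x$omega), " frequencies\n", sep = "")
  invisible(x)
}

#' Default log-spaced frequency grid
#' @param n points, `range` in 1/s
#' @export
default_omega_grid <- function(n = 200, range = c(1e-5, 1e3)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' Time-window-averaged standard deviations
#'
#' Variance of a fluctuating variable after boxcar averaging over a window
#' `Delta t`: `var(dt) = (1/pi) Int_0^Inf S(omega) sinc^2(omega dt / 2)
#' d omega` (two-sided spectral density convention), integrated numerically
#' on the frequency grid. Monotonically non-increasing in the window width.
#'
#' @param S_diag numeric vector: one-sided samples of the (real) spectral
#'   density of one variable on `omega`, or a matrix (omega x variable).
#' @param omega frequency grid (1/s), increasing.
#' @param dt window widths (s).
#' @return matrix (length(dt) x variables) of standard deviations.
#' @export
windowed_std <- function(S_diag, omega, dt) {
  S_diag <- cbind(S_diag)
  stopifnot(nrow(S_diag) == length(omega))
  sinc <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)
  out <- matrix(0, length(dt), ncol(S_diag))
  for (k in seq_along(dt)) {
    w <- sinc(omega * dt[k] / 2)^2
    integrand <- S_diag * w
    # trapezoid on the (log-spaced) grid
    dw <- diff(omega)
    v <- colSums((integrand[-1, , drop = FALSE] +
                    integrand[-nrow(integrand), , drop = FALSE]) / 2 * dw)
    out[k, ] <- sqrt(pmax(v / pi, 0))
  }
  dimnames(out) <- list(NULL, colnames(S_diag))
  out
}
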
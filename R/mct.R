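# Metabolic Control Theory on linearised models: Jacobian, control and
# response matrices, synergy coefficients, time courses, spectral response.

# internal columns of a full elasticity matrix
elast_internal <- function(net, E_unscaled) {
  E_unscaled[, !net$external, drop = FALSE]
}

# inverse via one pass of row/column equilibration; unscaled elasticities can
# span many orders of magnitude when concentrations do
solve_equilibrated <- function(M) {
  r <- apply(abs(M), 1, max)
  r[r == 0] <- 1
  Ms <- M / r
  cs <- apply(abs(Ms), 2, max)
  cs[cs == 0] <- 1
  Ms <- sweep(Ms, 2, cs, "/")
  if (rcond(Ms) < 1e-14) stop("singular matrix")
  inv <- sweep(solve(Ms), 1, cs, "/")
  sweep(inv, 2, r, "/")
}

#' Jacobian of the linearised metabolic dynamics
#'
#' `A = N_ind E_c L - lambda I` in the independent metabolite coordinates,
#' where `E_c` holds unscaled elasticities with respect to internal
#' metabolites and `lambda` is the growth (dilution) rate.
#'
#' @param reduced an `stm_reduced`
#' @param E_unscaled unscaled elasticity matrix (reaction x all metabolites)
#'   or reaction x internal metabolites.
#' @param growth_rate dilution rate lambda (1/s).
#' @param net optional network (needed to subset internal columns when the
#'   full matrix is passed).
#' @return list with `A` and its eigenvalues.
#' @export
jacobian <- function(reduced, E_unscaled, growth_rate = 0, net = NULL) {
  E_c <- if (!is.null(net) && ncol(E_unscaled) == length(net$metabolites)) {
    elast_internal(net, E_unscaled)
  } else E_unscaled
  if (ncol(E_c) != nrow(reduced$N_int)) stop("elasticity dimensions do not match network")
  A <- reduced$N_ind %*% E_c %*% reduced$L - growth_rate * diag(nrow(reduced$N_ind))
  list(A = A, eigenvalues = eigen(A, only.values = TRUE)$values)
}

#' Unscaled control matrices
#'
#' `C_V = I - E_c L M^-1 N_ind` and `C_S = -L M^-1 N_ind` with
#' `M = N_ind E_c L - lambda I`. At `lambda = 0` they satisfy the summation
#' and connectivity theorems `C_V K = K`, `C_S K = 0`, `C_V E_c L = 0`,
#' `C_S E_c L = -L`.
#'
#' @inheritParams jacobian
#' @return list with `C_V` (reaction x reaction), `C_S` (internal metabolite
#'   x reaction), `A` and its eigenvalues.
#' @export
control_matrices <- function(reduced, E_unscaled, growth_rate = 0, net = NULL) {
  E_c <- if (!is.null(net) && ncol(E_unscaled) == length(net$metabolites)) {
    elast_internal(net, E_unscaled)
  } else E_unscaled
  n_r <- nrow(E_c)
  M <- reduced$N_ind %*% E_c %*% reduced$L - growth_rate * diag(nrow(reduced$N_ind))
  Minv <- tryCatch(solve_equilibrated(M), error = function(e) {
    stop("deficient steady state (check conserved moieties / zero elasticities)")
  })
  EL <- E_c %*% reduced$L
  C_V <- diag(n_r) - EL %*% Minv %*% reduced$N_ind
  C_S <- -reduced$L %*% Minv %*% reduced$N_ind
  dimnames(C_V) <- list(colnames(reduced$N_int), colnames(reduced$N_int))
  dimnames(C_S) <- list(rownames(reduced$N_int), colnames(reduced$N_int))
  list(C_V = C_V, C_S = C_S, A = M,
       eigenvalues = eigen(M, only.values = TRUE)$values)
}

#' Response matrices to parameter perturbations
#'
#' Multiplies control matrices with parameter elasticities:
#' `R_c = C_S E_p`, `R_v = C_V E_p`. For enzyme perturbations the unscaled
#' parameter elasticity is `diag(v/e)`; scaled enzyme-flux responses then
#' equal scaled flux control coefficients.
#'
#' @param control result of [control_matrices()]
#' @param E_p unscaled parameter elasticity matrix (reaction x parameter).
#' @return list with `R_v`, `R_c`.
#' @export
response_matrices <- function(control, E_p) {
  list(R_v = control$C_V %*% E_p, R_c = control$C_S %*% E_p)
}

#' Full control analysis of a state
#'
#' Convenience wrapper: elasticities, reduction, Jacobian, control and
#' response matrices, scaled variants, and relaxation times in one object.
#'
#' @param net an `stm_network`
#' @param state an `stm_state`
#' @param sat an `stm_saturation` (default: half saturation)
#' @param law rate-law kind
#' @return object of class `stm_control_set`.
#' @export
control_analysis <- function(net, state, sat = NULL, law = "cm") {
  if (is.null(sat)) sat <- stm_saturation(net)
  red <- reduce_network(net)
  E <- elasticities(net, state, sat, law)
  ctl <- control_matrices(red, E$E_unscaled, state$growth_rate, net)
  v <- state$v
  c_int <- state$c[!net$external]
  Dv <- diag(v, length(v)); Dvi <- diag(ifelse(v == 0, 0, 1 / v), length(v))
  C_V_scaled <- Dvi %*% ctl$C_V %*% Dv
  C_S_scaled <- diag(1 / c_int, length(c_int)) %*% ctl$C_S %*% Dv
  dimnames(C_V_scaled) <- dimnames(ctl$C_V)
  dimnames(C_S_scaled) <- dimnames(ctl$C_S)
  structure(
    list(network = net, state = state, saturation = sat, law = law,
         reduced = red, elasticities = E,
         A = ctl$A, eigenvalues = ctl$eigenvalues,
         C_V = ctl$C_V, C_S = ctl$C_S,
         C_V_scaled = C_V_scaled, C_S_scaled = C_S_scaled,
         relaxation_times = -1 / diag(ctl$A),
         stable = all(Re(ctl$eigenvalues) < 0)),
    class = "stm_control_set"
  )
}

#' @export
print.stm_control_set <- function(x, ...) {
  cat("<stm_control_set> ", nrow(x$C_V), " reactions; max Re(eig) = ",
      format(max(Re(x$eigenvalues)), digits = 4),
      if (x$stable) " (stable)" else " (UNSTABLE)", "\n", sep = "")
  invisible(x)
}

#' Steady state of a reconstructed nonlinear model
#'
#' Damped Newton iteration on the independent metabolite concentrations,
#' starting from the reference state; dependent concentrations follow the
#' link matrix (conserved moieties stay fixed).
#'
#' @param model an `stm_kinetic_model`
#' @param e enzyme levels (default: the model's own).
#' @param c_ext external concentrations (default: reference).
#' @param reduced optional precomputed `stm_reduced`.
#' @param tol relative residual tolerance, `maxit` iteration cap.
#' @return list with `c` (full concentration vector), `v`, `converged`,
#'   `iterations`.
#' @export
steady_state <- function(model, e = NULL, c_ext = NULL, reduced = NULL,
                         tol = 1e-10, maxit = 200) {
  net <- model$network
  state <- model$state
  if (is.null(reduced)) reduced <- reduce_network(net)
  if (is.null(e)) e <- model$e
  lam <- state$growth_rate
  int <- !net$external
  c_full <- state$c
  if (!is.null(c_ext)) c_full[net$external] <- c_ext
  ind <- reduced$independent_rows
  c_int_ref <- state$c[int]
  x <- c_int_ref[ind]                       # independent concentrations

  assemble <- function(x) {
    ci <- c_int_ref + as.numeric(reduced$L %*% (x - c_int_ref[ind]))
    cc <- c_full; cc[int] <- ci; cc
  }
  resid <- function(x) {
    cc <- assemble(x)
    if (any(cc <= 0)) return(rep(Inf, length(x)))
    v <- model_rates_e(model, cc, e)
    as.numeric(reduced$N_ind %*% v) - lam * cc[int][ind]
  }
  scale <- max(abs(c_int_ref))
  g <- resid(x)
  it <- 0L
  while (max(abs(g)) > tol * max(scale, 1) && it < maxit) {
    it <- it + 1L
    # numeric Jacobian of the residual
    J <- matrix(0, length(x), length(x))
    hx <- pmax(abs(x), 1e-6) * 1e-7
    for (k in seq_along(x)) {
      xp <- x; xp[k] <- xp[k] + hx[k]
      xm <- x; xm[k] <- xm[k] - hx[k]
      J[, k] <- (resid(xp) - resid(xm)) / (2 * hx[k])
    }
    dx <- tryCatch(-solve(J, g), error = function(err) NULL)
    if (is.null(dx)) break
    step <- 1
    repeat {
      xn <- x + step * dx
      gn <- resid(xn)
      if (all(is.finite(gn)) && max(abs(gn)) < max(abs(g))) break
      step <- step / 2
      if (step < 1e-8) break
    }
    if (step < 1e-8) break
    x <- x + step * dx
    g <- resid(x)
  }
  cc <- assemble(x)
  list(c = cc, v = model_rates_e(model, cc, e),
       converged = max(abs(g)) <= tol * max(scale, 1), iterations = it)
}

model_rates_e <- function(model, c, e) {
  m <- model; m$e <- e
  model_rates(m, c)
}

#' Scaled second-order response (synergy) coefficients
#'
#' Central second differences of the log steady-state target with respect to
#' log enzyme levels of a reconstructed nonlinear model. Negative synergisms
#' are aggravating, positive synergisms buffering.
#'
#' @param model an `stm_kinetic_model`
#' @param target a reaction id (steady-state flux target) or metabolite id
#'   (concentration target).
#' @param pairs 2-column matrix or list of enzyme (reaction id) pairs;
#'   identical entries give self-synergies.
#' @param delta relative log-enzyme step (default 1e-3).
#' @param reduced optional precomputed reduction.
#' @return tibble with columns `enzyme_a`, `enzyme_b`, `synergy`,
#'   `classification`.
#' @export
synergy_coefficients <- function(model, target, pairs, delta = 1e-3,
                                 reduced = NULL) {
  net <- model$network
  if (is.null(reduced)) reduced <- reduce_network(net)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.character(pairs), ncol = 2)

  target_value <- function(ss) {
    if (target %in% net$reactions) ss$v[target]
    else if (target %in% net$metabolites) ss$c[target]
    else stop("unknown target: ", target)
  }
  Fln <- function(dln) {
    e <- model$e * exp(dln)
    ss <- steady_state(model, e = e, reduced = reduced)
    if (!ss$converged) stop("steady-state solver did not converge after perturbation")
    log(abs(target_value(ss)))
  }
  zero <- stats::setNames(numeric(length(net$reactions)), net$reactions)
  F0 <- Fln(zero)
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    if (a == b) {
      dp <- zero; dp[a] <- delta
      dm <- zero; dm[a] <- -delta
      r2 <- (Fln(dp) - 2 * F0 + Fln(dm)) / delta^2
    } else {
      d <- function(sa, sb) { dd <- zero; dd[a] <- sa * delta; dd[b] <- sb * delta; dd }
      r2 <- (Fln(d(1, 1)) - Fln(d(1, -1)) - Fln(d(-1, 1)) + Fln(d(-1, -1))) /
        (4 * delta^2)
    }
    r2 <- unname(r2)
    tibble::tibble(enzyme_a = a, enzyme_b = b, synergy = r2,
                   classification = ifelse(r2 < 0, "aggravating", "buffering"))
  })
  dplyr::bind_rows(out)
}

#' Synergy effect from single and double perturbation outcomes
#'
#' Multiplicative form `eta = ln(w_ab / (w_a w_b))`; additive form
#' `eta = w_ab - (w_a + w_b)`.
#'
#' @param w_a,w_b,w_ab relative target changes for the single and double
#'   perturbations.
#' @param form "multiplicative" or "additive".
#' @export
synergy_eta <- function(w_a, w_b, w_ab, form = c("multiplicative", "additive")) {
  form <- match.arg(form)
  if (form == "multiplicative") {
    if (any(c(w_a, w_b, w_ab) <= 0)) stop("nonpositive w in multiplicative mode")
    log(w_ab / (w_a * w_b))
  } else {
    w_ab - (w_a + w_b)
  }
}

#' Spectral response matrices
#'
#' Frequency-dependent transfer functions from parameter fluctuations to
#' metabolite concentrations and fluxes:
#' `R_c(omega) = L (i omega I - A)^-1 N_ind E_p` and
#' `R_v(omega) = E_c R_c(omega) + E_p`. At `omega = 0` the static response
#' matrices are recovered.
#'
#' @param reduced an `stm_reduced`
#' @param E_unscaled unscaled elasticity matrix (reaction x internal
#'   metabolites, or full with `net` given).
#' @param E_p unscaled parameter elasticity matrix (reaction x parameter).
#' @param omega frequency grid (1/s).
#' @param growth_rate dilution rate lambda.
#' @param net optional network for column subsetting.
#' @return list with complex arrays `R_c` (internal metabolite x parameter x
#'   omega) and `R_v` (reaction x parameter x omega), plus `omega`.
#' @export
spectral_response <- function(reduced, E_unscaled, E_p, omega,
                              growth_rate = 0, net = NULL) {
  E_c <- if (!is.null(net) && ncol(E_unscaled) == length(net$metabolites)) {
    elast_internal(net, E_unscaled)
  } else E_unscaled
  A <- reduced$N_ind %*% E_c %*% reduced$L - growth_rate * diag(nrow(reduced$N_ind))
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0 & abs(Im(ev)) < 1e-12 & abs(Re(ev)) < 1e-12)) {
    stop("Jacobian has eigenvalue on the imaginary axis; unstable reference")
  }
  n_i <- nrow(reduced$N_int); n_p <- ncol(E_p); n_r <- nrow(E_c)
  R_c <- array(complex(real = 0), c(n_i, n_p, length(omega)))
  R_v <- array(complex(real = 0), c(n_r, n_p, length(omega)))
  NEp <- reduced$N_ind %*% E_p
  I <- diag(nrow(A))
  for (k in seq_along(omega)) {
    res <- solve(1i * omega[k] * I - A, NEp)
    Rck <- reduced$L %*% res
    R_c[, , k] <- Rck
    R_v[, , k] <- E_c %*% Rck + E_p
  }
  dimnames(R_c) <- list(rownames(reduced$N_int), colnames(E_p), NULL)
  dimnames(R_v) <- list(colnames(reduced$N_int), colnames(E_p), NULL)
  list(R_c = R_c, R_v = R_v, omega = omega)
}

#' Linearised time course after a concentration perturbation
#'
#' Integrates `d/dt delta_c_ind = A delta_c_ind` and maps back to the full
#' internal concentration vector via the link matrix, so conserved moieties
#' stay constant over time.
#'
#' @param A Jacobian (independent coordinates)
#' @param reduced an `stm_reduced`
#' @param delta_c0 initial internal concentration perturbation (full internal
#'   vector, consistent with conservation, or independent vector).
#' @param times time grid (s)
#' @return matrix (time x internal metabolite) of perturbations `delta_c(t)`.
#' @export
linear_timecourse <- function(A, reduced, delta_c0, times) {
  n_ind <- nrow(A)
  if (length(delta_c0) == n_ind) {
    x0 <- delta_c0
    full0 <- as.numeric(reduced$L %*% x0)
  } else {
    x0 <- delta_c0[reduced$independent_rows]
    full0 <- delta_c0
  }
  sol <- deSolve::ode(y = as.numeric(x0), times = times,
                      func = function(t, y, p) list(as.numeric(A %*% y)),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  Xind <- sol[, -1, drop = FALSE]
  # delta_c(t) = delta_c(0) + L (x(t) - x(0)): moiety components persist
  X <- matrix(rep(full0, each = nrow(Xind)), nrow(Xind)) +
    sweep(Xind, 2, as.numeric(x0)) %*% t(reduced$L)
  colnames(X) <- rownames(reduced$N_int)
  rownames(X) <- NULL
  X
}
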
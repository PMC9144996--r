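# First- and second-order reaction elasticities from thermodynamic forces and
# saturation values. All low-level formulas are evaluated in the flux
# direction (theta > 0 for active reactions); scaled elasticities
# d ln|v| / d ln c are orientation-invariant, so the high-level wrapper only
# needs to orient molecularities before calling them.

THETA_MIN <- 1e-6

#' Reversibility term of the scaled elasticity
#'
#' The thermodynamic part shared by all consistent reversible rate laws:
#' `(zeta mS - mP) / (zeta - 1)` with flux ratio `zeta = e^theta`. Substrate
#' entries are positive and exceed `mS` near equilibrium; product entries are
#' negative. Diverges as `theta -> 0`.
#'
#' @param theta thermodynamic forces per reaction (RT units), oriented along
#'   the flux (positive for active reactions).
#' @param m_S,m_P substrate / product molecularity matrices
#'   (reaction x metabolite), flux-oriented.
#' @return scaled elasticity matrix on the reactant pattern (0 elsewhere).
#' @export
elasticity_rev <- function(theta, m_S, m_P) {
  m_S <- rbind(m_S); m_P <- rbind(m_P)
  if (any(theta == 0)) stop("elasticity diverges at equilibrium (theta = 0)")
  if (any(abs(theta) < THETA_MIN)) {
    warning("theta below equilibrium guard (", THETA_MIN,
            " RT); elasticities are near-divergent")
  }
  zeta <- exp(theta)
  E <- (zeta * m_S - m_P) / (zeta - 1)
  E[(m_S + m_P) == 0] <- 0
  dimnames(E) <- dimnames(m_S)
  E
}

#' Mass-action / power-law scaled elasticities
#'
#' For mass-action rate laws without regulation the kinetic term vanishes and
#' the elasticity equals the reversibility term. Equivalently computed from
#' one-way fluxes as `Dg(v)^-1 [Dg(v+) MS - Dg(v-) MP]`.
#'
#' @inheritParams elasticity_rev
#' @param v optional net flux vector; when given, the one-way-flux form is
#'   used (identical up to rounding).
#' @export
elasticity_ma <- function(theta, m_S, m_P, v = NULL) {
  if (is.null(v)) return(elasticity_rev(theta, m_S, m_P))
  ow <- one_way_fluxes(v, sign(v) * abs(theta))
  E <- (ow$v_plus * rbind(m_S) - ow$v_minus * rbind(m_P)) / abs(v)
  E[(rbind(m_S) + rbind(m_P)) == 0] <- 0
  E
}

#' Simultaneous-binding modular rate law elasticities
#'
#' `E = E_rev - (mS + mP) beta_M + mA (1 - beta_A) - mI beta_I`. In the
#' completely forward-driven limit (`theta -> Inf`, `beta_M -> 0`) this
#' reduces to the irreversible structural-kinetic form `mS (1 - beta_M)`.
#'
#' @inheritParams elasticity_rev
#' @param beta_M reactant saturation matrix (NA off pattern).
#' @param beta_A,beta_I activator / inhibitor saturation matrices.
#' @param m_A,m_I regulation molecularity matrices.
#' @export
elasticity_sm <- function(theta, beta_M, beta_A = NULL, beta_I = NULL,
                          m_S, m_P, m_A = NULL, m_I = NULL) {
  E <- elasticity_rev(theta, m_S, m_P)
  bM <- ifelse(is.na(beta_M), 0, beta_M)
  E <- E - (m_S + m_P) * bM
  E + regulation_elasticity(beta_A, beta_I, m_A, m_I, dim(E))
}

regulation_elasticity <- function(beta_A, beta_I, m_A, m_I, dims) {
  out <- matrix(0, dims[1], dims[2])
  if (!is.null(m_A) && any(m_A > 0)) {
    bA <- ifelse(is.na(beta_A), 0, beta_A)
    out <- out + m_A * (1 - bA) * (m_A > 0)
  }
  if (!is.null(m_I) && any(m_I > 0)) {
    bI <- ifelse(is.na(beta_I), 0, beta_I)
    out <- out - m_I * bI
  }
  out
}

#' Common modular rate law elasticities
#'
#' `E = E_rev - beta (mS psi+ + mP psi-)/(psi+ + psi- - 1) + mA (1-beta_A)
#' - mI beta_I`, with `psi+- = prod_i (1 + c_i/kM_li)^(m_li+-)`.
#'
#' @inheritParams elasticity_sm
#' @param c concentration vector (metabolite order of the matrix columns).
#' @param k_M dissociation constant matrix (reaction x metabolite, NA off
#'   pattern); if NULL, derived from `beta_M` and `c`.
#' @export
elasticity_cm <- function(theta, c, k_M = NULL, beta_M, beta_A = NULL,
                          beta_I = NULL, m_S, m_P, m_A = NULL, m_I = NULL) {
  E_rev <- elasticity_rev(theta, m_S, m_P)
  n_r <- nrow(E_rev); n_m <- ncol(E_rev)
  cmat <- matrix(rep(c, each = n_r), n_r)
  if (is.null(k_M)) k_M <- constants_from_saturation(cmat, beta_M)
  ratio <- cmat / k_M                       # NA off pattern
  E_den <- matrix(0, n_r, n_m)
  for (l in seq_len(n_r)) {
    idx <- which((m_S[l, ] + m_P[l, ]) > 0)
    psi_plus <- prod((1 + ratio[l, idx])^m_S[l, idx])
    psi_minus <- prod((1 + ratio[l, idx])^m_P[l, idx])
    D <- psi_plus + psi_minus - 1
    E_den[l, idx] <- beta_M[l, idx] *
      (m_S[l, idx] * psi_plus + m_P[l, idx] * psi_minus) / D
  }
  E <- E_rev - E_den + regulation_elasticity(beta_A, beta_I, m_A, m_I, dim(E_rev))
  dimnames(E) <- dimnames(E_rev)
  E
}

#' Thermodynamics-only elasticities of the factorised rate law
#'
#' For rates written as `v = e kcat eta_rev(theta) eta_sat(c)` with
#' `eta_rev = 1 - e^(-theta)`, the thermodynamic contribution to the scaled
#' elasticity is `-n_il / (e^theta - 1)` (flux-oriented stoichiometric
#' coefficients `n_il`, substrates negative). With `dln_eta_sat = 0` the
#' elasticities depend only on forces and stoichiometry.
#'
#' @param theta flux-oriented forces (> 0).
#' @param n_il flux-oriented stoichiometric coefficient matrix
#'   (reaction x metabolite; substrates negative).
#' @param dln_eta_sat matrix of saturation-term log-derivatives (default 0).
#' @export
elasticity_factorized <- function(theta, n_il, dln_eta_sat = 0) {
  if (any(theta == 0)) stop("elasticity diverges at equilibrium (theta = 0)")
  n_il <- rbind(n_il)
  -n_il / expm1(theta) + dln_eta_sat
}

#' First-order elasticities of a model or state
#'
#' Computes the full scaled and unscaled first-order elasticity matrices for a
#' network, state, and saturation set (or reconstructed kinetic model), with
#' all formulas evaluated in the flux direction. Reactions at equilibrium
#' (`v = 0`, `|theta| < THETA_MIN`) get mass-action elasticities based on a
#' configurable equilibrium exchange flux and raise a warning.
#'
#' @param net an `stm_network`
#' @param state an `stm_state`
#' @param sat an `stm_saturation` (ignored for `law = "ma"`).
#' @param law rate-law kind ("cm", "sm", "ma"), recycled per reaction.
#' @param equilibrium_exchange one-way flux assigned to reactions at
#'   equilibrium (mM/s).
#' @return object of class `stm_elasticities` with `E_scaled`, `E_unscaled`
#'   (reaction x metabolite), and components `E_rev`, `E_den`, `E_reg`.
#' @export
elasticities <- function(net, state, sat = NULL, law = "cm",
                         equilibrium_exchange = 0) {
  n_r <- length(net$reactions); n_m <- length(net$metabolites)
  law <- rep(law, length.out = n_r)
  if (is.null(sat) && any(law != "ma")) sat <- stm_saturation(net)
  mol <- molecularity_matrices(net)
  reg <- regulation_matrices(net)
  s <- ifelse(state$v != 0, sign(state$v), ifelse(state$theta != 0, sign(state$theta), 1))
  # orient molecularities along the flux
  swap <- s < 0
  m_S <- mol$m_S; m_P <- mol$m_P
  m_S[swap, ] <- mol$m_P[swap, ]; m_P[swap, ] <- mol$m_S[swap, ]
  th <- abs(state$theta)

  at_eq <- th < THETA_MIN
  th_safe <- ifelse(at_eq, 1, th)  # placeholder, rows overwritten below

  E_rev <- elasticity_rev(th_safe, m_S, m_P)
  E_sc <- matrix(0, n_r, n_m, dimnames = list(net$reactions, net$metabolites))
  E_den <- matrix(0, n_r, n_m, dimnames = dimnames(E_sc))
  E_reg <- regulation_elasticity(if (!is.null(sat)) sat$beta_A else NULL,
                                 if (!is.null(sat)) sat$beta_I else NULL,
                                 reg$m_A, reg$m_I, c(n_r, n_m))
  dimnames(E_reg) <- dimnames(E_sc)
  for (l in seq_len(n_r)) {
    if (law[l] == "ma") {
      E_sc[l, ] <- E_rev[l, ] + E_reg[l, ]
    } else if (law[l] == "sm") {
      bM <- ifelse(is.na(sat$beta_M[l, ]), 0, sat$beta_M[l, ])
      E_den[l, ] <- (m_S[l, ] + m_P[l, ]) * bM
      E_sc[l, ] <- E_rev[l, ] - E_den[l, ] + E_reg[l, ]
    } else {
      Ecm <- elasticity_cm(th_safe[l], state$c, k_M = NULL,
                           beta_M = sat$beta_M[l, , drop = FALSE],
                           m_S = m_S[l, , drop = FALSE], m_P = m_P[l, , drop = FALSE])
      E_den[l, ] <- E_rev[l, ] - Ecm
      E_sc[l, ] <- Ecm + E_reg[l, ]
    }
  }

  # unscaled: E[l,i] = v_l * E_sc[l,i] / c_i
  v_for_scale <- state$v
  if (any(at_eq)) {
    warning("reaction(s) at equilibrium: ",
            paste(net$reactions[at_eq], collapse = ", "),
            "; using mass-action exchange-flux elasticities")
    for (l in which(at_eq)) {
      # near-equilibrium mass action with one-way flux q: dv/dln c_i = -q n_il
      E_sc[l, ] <- -(net$stoich[, l]) * s[l]
      E_rev[l, ] <- E_sc[l, ]
      v_for_scale[l] <- s[l] * equilibrium_exchange
    }
  }
  E_un <- diag(v_for_scale, n_r) %*% E_sc %*% diag(1 / state$c, n_m)
  dimnames(E_un) <- dimnames(E_sc)

  structure(
    list(E_scaled = E_sc, E_unscaled = E_un,
         E_rev = E_rev, E_den = E_den, E_reg = E_reg,
         law = law, v = state$v, c = state$c),
    class = "stm_elasticities"
  )
}

#' @export
print.stm_elasticities <- function(x, ...) {
  cat("<stm_elasticities> ", nrow(x$E_scaled), " reactions x ",
      ncol(x$E_scaled), " metabolites; law: ",
      paste(unique(x$law), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Convert between scaled and unscaled elasticities
#'
#' `E_unscaled[l,i] = v_l E_scaled[l,i] / c_i` on the sparsity pattern.
#' @param E matrix to convert
#' @param v flux vector, `c` concentration vector
#' @param to "unscaled" or "scaled"
#' @export
convert_elasticities <- function(E, v, c, to = c("unscaled", "scaled")) {
  to <- match.arg(to)
  if (to == "unscaled") {
    out <- diag(v, length(v)) %*% E %*% diag(1 / c, length(c))
  } else {
    out <- diag(1 / v, length(v)) %*% E %*% diag(c, length(c))
  }
  dimnames(out) <- dimnames(E)
  out
}

# log-rate function of a model: F(ln c) = ln |v_l(c)|, vector over reactions
model_log_rates <- function(model, lnc) {
  v <- model_rates(model, exp(lnc))
  log(abs(v))
}

# closed-form scaled elasticity matrix of a kinetic model at concentrations c,
# keeping the flux orientation of the reference state
model_scaled_elasticities <- function(model, c) {
  net <- model$network
  n_r <- length(net$reactions); n_m <- length(net$metabolites)
  mol <- molecularity_matrices(net)
  reg <- regulation_matrices(net)
  s <- ifelse(model$state$v != 0, sign(model$state$v),
              ifelse(model$state$theta != 0, sign(model$state$theta), 1))
  swap <- s < 0
  m_S <- mol$m_S; m_P <- mol$m_P
  m_S[swap, ] <- mol$m_P[swap, ]; m_P[swap, ] <- mol$m_S[swap, ]
  theta <- s * compute_forces(net, c, model$ln_keq)
  cmat <- matrix(rep(c, each = n_r), n_r)
  beta_M <- cmat / (cmat + model$k_M)      # NA off pattern
  beta_A <- cmat / (cmat + model$k_A)
  beta_I <- cmat / (cmat + model$k_I)
  E <- matrix(0, n_r, n_m, dimnames = list(net$reactions, net$metabolites))
  for (l in seq_len(n_r)) {
    E[l, ] <- switch(model$law[l],
      ma = elasticity_rev(theta[l], m_S[l, , drop = FALSE],
                          m_P[l, , drop = FALSE]),
      sm = elasticity_sm(theta[l], beta_M[l, , drop = FALSE],
                         m_S = m_S[l, , drop = FALSE],
                         m_P = m_P[l, , drop = FALSE]),
      cm = elasticity_cm(theta[l], c, k_M = model$k_M[l, , drop = FALSE],
                         beta_M = beta_M[l, , drop = FALSE],
                         m_S = m_S[l, , drop = FALSE],
                         m_P = m_P[l, , drop = FALSE])
    )
  }
  E + regulation_elasticity(beta_A, beta_I, reg$m_A, reg$m_I, dim(E))
}

#' Second-order elasticities of a reconstructed model
#'
#' Differentiates the closed-form first-order scaled elasticities of the
#' implemented rate laws by central finite differences with Richardson
#' extrapolation on the log-concentration scale:
#' `E2_scaled[l,i,j] = d E_scaled[l,i] / d ln c_j
#' = d^2 ln|v_l| / d ln c_i d ln c_j`. The result is symmetrised after a
#' symmetry check; the unscaled tensor `d^2 v_l / d c_i d c_j` follows from
#' the scaled one.
#'
#' @param model an `stm_kinetic_model`
#' @param c_ref reference concentrations (default: the model's state).
#' @param h log-scale step (default 1e-4).
#' @return list with arrays `E2_scaled`, `E2_unscaled`
#'   (reaction x metabolite x metabolite).
#' @export
second_order_elasticities <- function(model, c_ref = NULL, h = 1e-4) {
  net <- model$network
  if (is.null(c_ref)) c_ref <- model$state$c
  c_ref <- resolve_named(c_ref, net$metabolites, "c_ref")
  v_ref <- model_rates(model, c_ref)
  if (any(v_ref == 0 & model$e > 0)) stop("reference rate is zero")
  n_r <- length(net$reactions); n_m <- length(net$metabolites)

  dE <- function(j, step) {
    up <- c_ref; up[j] <- up[j] * exp(step)
    dn <- c_ref; dn[j] <- dn[j] * exp(-step)
    (model_scaled_elasticities(model, up) -
       model_scaled_elasticities(model, dn)) / (2 * step)
  }
  hess_at <- function(step) {
    H <- array(0, c(n_r, n_m, n_m))
    for (j in seq_len(n_m)) H[, , j] <- dE(j, step)
    H
  }
  H1 <- hess_at(h); H2 <- hess_at(h / 2)
  E2 <- (4 * H2 - H1) / 3     # Richardson extrapolation, O(h^4)
  asym <- max(abs(E2 - aperm(E2, c(1, 3, 2))))
  if (asym > 1e-8) warning("second-order elasticities asymmetric by ", asym)
  E2 <- (E2 + aperm(E2, c(1, 3, 2))) / 2
  dimnames(E2) <- list(net$reactions, net$metabolites, net$metabolites)

  grad <- model_scaled_elasticities(model, c_ref)
  E2u <- array(0, c(n_r, n_m, n_m), dimnames = dimnames(E2))
  for (l in seq_len(n_r)) {
    Fi <- grad[l, ]
    M <- E2[l, , ] + outer(Fi, Fi) - diag(Fi, n_m)
    E2u[l, , ] <- v_ref[l] * M / outer(c_ref, c_ref)
  }
  list(E2_scaled = E2, E2_unscaled = E2u)
}
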
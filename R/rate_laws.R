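#' Saturation values and dissociation constants
#'
#' A saturation value is `beta = c/(c + k)`, the average fraction of enzyme
#' bound to a metabolite at concentration `c` with dissociation constant `k`.
#' The two helpers are elementwise mutual inverses.
#'
#' @param c concentration(s) (mM, > 0)
#' @param k dissociation constant(s) (mM, > 0)
#' @return saturation value(s) in ]0,1[.
#' @export
saturation_from_constants <- function(c, k) {
  stopifnot(all(c > 0, na.rm = TRUE), all(k > 0, na.rm = TRUE))
  c / (c + k)
}

#' @rdname saturation_from_constants
#' @param beta saturation value(s), strictly inside ]0,1[.
#' @export
constants_from_saturation <- function(c, beta) {
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    stop("saturation values must lie strictly inside ]0,1[")
  }
  c * (1 - beta) / beta
}

#' Saturation value set for a network
#'
#' Holds reaction-by-metabolite matrices of saturation values on the reactant,
#' activator and inhibitor sparsity patterns of a network (entries off the
#' pattern are NA).
#'
#' @param net an `stm_network`
#' @param beta_M reactant saturation values: a single number recycled over the
#'   pattern, or a reaction x metabolite matrix.
#' @param beta_A,beta_I analogous for activators / inhibitors.
#' @return object of class `stm_saturation`.
#' @export
stm_saturation <- function(net, beta_M = 0.5, beta_A = 0.5, beta_I = 0.5) {
  mol <- molecularity_matrices(net)
  reg <- regulation_matrices(net)
  mk <- function(beta, pattern, what) {
    tmpl <- matrix(NA_real_, nrow(pattern), ncol(pattern), dimnames = dimnames(pattern))
    if (is.matrix(beta)) {
      tmpl[pattern > 0] <- beta[pattern > 0]
    } else {
      tmpl[pattern > 0] <- beta
    }
    vals <- tmpl[pattern > 0]
    if (any(is.na(vals)) || any(vals <= 0 | vals >= 1)) {
      stop(what, " saturation values must lie strictly inside ]0,1[ on the network pattern")
    }
    tmpl
  }
  structure(
    list(beta_M = mk(beta_M, mol$m_S + mol$m_P, "reactant"),
         beta_A = mk(beta_A, reg$m_A, "activator"),
         beta_I = mk(beta_I, reg$m_I, "inhibitor")),
    class = "stm_saturation"
  )
}

#' Sample a saturation set
#'
#' Saturation values are sampled independently per pattern entry, either
#' uniformly on `[lo, hi]` or from a `Beta(a, b)` distribution, and clipped to
#' `[0.001, 0.999]` to avoid full saturation.
#'
#' @param net an `stm_network`
#' @param dist "uniform" or "beta"
#' @param lo,hi uniform range (defaults 0, 1 before clipping)
#' @param a,b beta-distribution shape parameters
#' @param clip clipping interval
#' @return an `stm_saturation`
#' @export
sample_saturation <- function(net, dist = c("uniform", "beta"),
                              lo = 0, hi = 1, a = 2, b = 2,
                              clip = c(0.001, 0.999)) {
  dist <- match.arg(dist)
  mol <- molecularity_matrices(net)
  reg <- regulation_matrices(net)
  draw <- function(pattern) {
    n <- sum(pattern > 0)
    x <- if (dist == "uniform") stats::runif(n, lo, hi) else stats::rbeta(n, a, b)
    x <- pmin(pmax(x, clip[1]), clip[2])
    m <- matrix(NA_real_, nrow(pattern), ncol(pattern), dimnames = dimnames(pattern))
    m[pattern > 0] <- x
    m
  }
  bM <- draw(mol$m_S + mol$m_P); bA <- draw(reg$m_A); bI <- draw(reg$m_I)
  out <- stm_saturation(net)
  out$beta_M <- bM; out$beta_A <- bA; out$beta_I <- bI
  out
}

# regulation prefactor reg(c) = prod (c/(c+kA))^mA * prod (kI/(c+kI))^mI
regulation_prefactor <- function(net, c, k_A, k_I) {
  reg <- regulation_matrices(net)
  n_r <- length(net$reactions)
  pref <- rep(1, n_r)
  for (l in seq_len(n_r)) {
    ia <- which(reg$m_A[l, ] > 0)
    for (i in ia) pref[l] <- pref[l] * (c[i] / (c[i] + k_A[l, i]))^reg$m_A[l, i]
    ii <- which(reg$m_I[l, ] > 0)
    for (i in ii) pref[l] <- pref[l] * (k_I[l, i] / (c[i] + k_I[l, i]))^reg$m_I[l, i]
  }
  pref
}

#' Modular rate laws (rate per enzyme)
#'
#' Evaluates the common modular (`cm`, convenience kinetics), simultaneous
#' binding modular (`sm`) or mass-action (`ma`) rate law of one reaction at
#' concentrations `c`. All three laws share the mass-action-shaped numerator
#' `k_cat+ prod (c/kM)^mS - k_cat- prod (c/kM)^mP`; they differ in the
#' denominator. Regulation enters as a non-competitive prefactor
#' `prod (c/(c+kA))^mA * prod (kI/(c+kI))^mI`. The sign of the returned rate
#' equals the sign of the thermodynamic force.
#'
#' @param model an `stm_kinetic_model`
#' @param reaction reaction id or index
#' @param c concentration vector (mM), named or in metabolite order.
#' @return rate per unit enzyme (1/s).
#' @export
rate_per_enzyme <- function(model, reaction, c) {
  net <- model$network
  c <- resolve_named(c, net$metabolites, "concentration")
  l <- if (is.character(reaction)) match(reaction, net$reactions) else reaction
  if (is.na(l)) stop("unknown reaction")
  law <- model$law[l]
  mol <- molecularity_matrices(net)
  mS <- mol$m_S[l, ]; mP <- mol$m_P[l, ]
  idx <- which(mS + mP > 0)
  kM <- model$k_M[l, ]
  ratio <- c[idx] / kM[idx]
  numer <- model$k_cat_plus[l] * prod(ratio^mS[idx]) -
    model$k_cat_minus[l] * prod(ratio^mP[idx])
  denom <- switch(law,
    ma = 1,
    sm = prod((1 + ratio)^(mS[idx] + mP[idx])),
    cm = {
      psi_plus <- prod((1 + ratio)^mS[idx])
      psi_minus <- prod((1 + ratio)^mP[idx])
      psi_plus + psi_minus - 1
    },
    stop("unknown rate law kind: ", law)
  )
  pref <- regulation_prefactor(net, c, model$k_A, model$k_I)[l]
  pref * numer / denom
}

#' Evaluate all reaction rates of a kinetic model
#'
#' @param model an `stm_kinetic_model`
#' @param c concentrations (mM)
#' @return named flux vector (mM/s), `v_l = e_l * rate_per_enzyme`.
#' @export
model_rates <- function(model, c) {
  net <- model$network
  v <- vapply(seq_along(net$reactions),
              function(l) model$e[l] * rate_per_enzyme(model, l, c),
              numeric(1))
  names(v) <- net$reactions
  v
}

#' Reconstruct a kinetic model from a state and saturation values
#'
#' Dissociation constants follow from `k = c (1-beta)/beta`; the
#' forward/backward turnover split is chosen so that the Haldane relationship
#' `ln keq = ln(kcat+/kcat-) + sum_i n_il ln kM_li` holds exactly; enzyme
#' levels are set so the model reproduces the reference fluxes at the
#' reference concentrations.
#'
#' @param net an `stm_network`
#' @param state a feasible `stm_state`
#' @param sat an `stm_saturation`
#' @param law rate-law kind: "cm", "sm" or "ma" (recycled per reaction).
#' @param basis "kV" (velocity constants, symmetric Haldane split) or
#'   "kcat_plus" (forward turnover rates as basic variables).
#' @param k_V velocity constants (1/s), recycled; used when `basis = "kV"`.
#' @param k_cat_plus forward turnover rates, used when `basis = "kcat_plus"`.
#' @return object of class `stm_kinetic_model`.
#' @export
reconstruct_kinetics <- function(net, state, sat, law = "cm",
                                 basis = c("kV", "kcat_plus"),
                                 k_V = 1, k_cat_plus = NULL) {
  basis <- match.arg(basis)
  n_r <- length(net$reactions)
  law <- rep(law, length.out = n_r)
  stopifnot(all(law %in% c("cm", "sm", "ma")))
  mol <- molecularity_matrices(net)
  pattern <- (mol$m_S + mol$m_P) > 0

  k_M <- matrix(NA_real_, n_r, length(net$metabolites),
                dimnames = dimnames(sat$beta_M))
  cmat <- matrix(rep(state$c, each = n_r), n_r)
  k_M[pattern] <- constants_from_saturation(cmat[pattern], sat$beta_M[pattern])
  reg <- regulation_matrices(net)
  k_A <- k_I <- matrix(NA_real_, n_r, length(net$metabolites),
                       dimnames = dimnames(sat$beta_M))
  k_A[reg$m_A > 0] <- constants_from_saturation(cmat[reg$m_A > 0], sat$beta_A[reg$m_A > 0])
  k_I[reg$m_I > 0] <- constants_from_saturation(cmat[reg$m_I > 0], sat$beta_I[reg$m_I > 0])

  # Haldane: ln(k+/k-) = ln_keq - sum_i n_il ln kM_li
  h <- vapply(seq_len(n_r), function(l) {
    idx <- which(pattern[l, ])
    state$ln_keq[l] - sum(net$stoich[idx, l] * log(k_M[l, idx]))
  }, numeric(1))

  if (basis == "kV") {
    k_V <- rep(k_V, length.out = n_r)
    kcp <- k_V * exp(h / 2)
    kcm <- k_V * exp(-h / 2)
  } else {
    if (is.null(k_cat_plus)) stop("k_cat_plus required for basis 'kcat_plus'")
    kcp <- rep(k_cat_plus, length.out = n_r)
    kcm <- kcp * exp(-h)
    k_V <- sqrt(kcp * kcm)
  }

  model <- structure(
    list(network = net, state = state, law = law,
         k_M = k_M, k_A = k_A, k_I = k_I,
         k_cat_plus = kcp, k_cat_minus = kcm, k_V = k_V,
         e = rep(1, n_r), ln_keq = state$ln_keq),
    class = "stm_kinetic_model"
  )
  u <- vapply(seq_len(n_r), function(l) rate_per_enzyme(model, l, state$c), numeric(1))
  e <- ifelse(state$v == 0, 0, state$v / u)
  if (any(e < 0 | !is.finite(e))) {
    stop("rate per enzyme inconsistent with flux sign; state is infeasible")
  }
  model$e <- e
  names(model$e) <- net$reactions
  model
}

#' @export
print.stm_kinetic_model <- function(x, ...) {
  cat("<stm_kinetic_model> ", length(x$network$reactions), " reactions, law: ",
      paste(unique(x$law), collapse = "/"), "; Haldane max violation ",
      format(max(abs(haldane_residual(x))), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Haldane residuals of a kinetic model
#'
#' `ln keq - ln(kcat+/kcat-) - sum_i n_il ln kM_li`, one value per reaction
#' (all zero for a consistent model).
#' @param model an `stm_kinetic_model`
#' @return numeric vector per reaction.
#' @export
haldane_residual <- function(model) {
  net <- model$network
  mol <- molecularity_matrices(net)
  pattern <- (mol$m_S + mol$m_P) > 0
  vapply(seq_along(net$reactions), function(l) {
    idx <- which(pattern[l, ])
    model$ln_keq[l] - log(model$k_cat_plus[l] / model$k_cat_minus[l]) -
      sum(net$stoich[idx, l] * log(model$k_M[l, idx]))
  }, numeric(1))
}
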
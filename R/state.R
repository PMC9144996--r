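#' Thermodynamic reference state
#'
#' Couples metabolite concentrations, net fluxes and equilibrium constants.
#' Thermodynamic forces are computed as
#' `theta_l = ln_keq_l - sum_i n_il ln c_i` over *all* metabolites (internal
#' and external). Concentrations are in mM (log-referenced to a 1 mM standard
#' state), fluxes in mM/s, forces in units of RT.
#'
#' @param net an `stm_network`
#' @param c concentrations (mM, > 0), named or in metabolite order.
#' @param v net fluxes (mM/s), named or in reaction order.
#' @param ln_keq log equilibrium constants per reaction.
#' @param growth_rate dilution rate lambda (1/s); at lambda > 0 the
#'   stationarity condition becomes `N_int v - lambda c_int = 0`.
#' @param mu optional chemical potentials (kJ/mol) per metabolite.
#' @param check validate feasibility and stationarity (warning on failure).
#' @return object of class `stm_state`.
#' @export
stm_state <- function(net, c, v, ln_keq, growth_rate = 0, mu = NULL, check = TRUE) {
  c <- resolve_named(c, net$metabolites, "concentration")
  v <- resolve_named(v, net$reactions, "flux")
  ln_keq <- resolve_named(ln_keq, net$reactions, "ln_keq")
  if (any(c <= 0)) stop("nonpositive concentration for: ",
                        paste(names(c)[c <= 0], collapse = ", "))
  theta <- compute_forces(net, c, ln_keq)
  st <- structure(
    list(c = c, v = v, ln_keq = ln_keq, theta = theta,
         growth_rate = growth_rate, mu = mu),
    class = "stm_state"
  )
  if (check) {
    fz <- check_feasibility(st, net = net)
    if (length(fz$violations)) {
      warning("flux direction against thermodynamic force for: ",
              paste(fz$violations, collapse = ", "))
    }
    res <- stationarity_residual(net, st)
    if (max(abs(res)) > 1e-9) {
      warning("state is not stationary (max |N_int v - lambda c| = ",
              format(max(abs(res))), ")")
    }
    small <- abs(theta) <= 1 & v != 0
    if (any(small)) {
      # small driving forces degrade enzyme efficiency and inflate elasticities
      warning("driving force |theta| <= 1 RT in active reaction(s): ",
              paste(net$reactions[small], collapse = ", "))
    }
  }
  st
}

#' @export
print.stm_state <- function(x, ...) {
  cat("<stm_state> ", length(x$c), " concentrations, ", length(x$v),
      " fluxes; |theta| range [", format(min(abs(x$theta)), digits = 3), ", ",
      format(max(abs(x$theta)), digits = 3), "] RT; lambda = ",
      x$growth_rate, "\n", sep = "")
  invisible(x)
}

stationarity_residual <- function(net, state) {
  N_int <- internal_stoich(net)
  if (nrow(N_int) == 0) return(0)
  as.numeric(N_int %*% state$v) - state$growth_rate * state$c[!net$external]
}

#' Thermodynamic forces from concentrations and equilibrium constants
#'
#' @param net an `stm_network`
#' @param c concentrations (mM, > 0)
#' @param ln_keq log equilibrium constants
#' @return named numeric vector theta (RT units) per reaction.
#' @export
compute_forces <- function(net, c, ln_keq) {
  c <- resolve_named(c, net$metabolites, "concentration")
  ln_keq <- resolve_named(ln_keq, net$reactions, "ln_keq")
  if (any(c <= 0)) stop("nonpositive concentration")
  theta <- as.numeric(ln_keq - t(net$stoich) %*% log(c))
  names(theta) <- net$reactions
  theta
}

#' Sign feasibility of a state
#'
#' A reaction is infeasible when it carries flux against its thermodynamic
#' force (`v_l != 0` and `v_l * theta_l <= 0`).
#'
#' @param state an `stm_state`
#' @param net the network the state belongs to (used for reaction ids).
#' @return list with `violations` (reaction ids) and `feasible`.
#' @export
check_feasibility <- function(state, net = NULL) {
  ids <- names(state$v)
  bad <- state$v != 0 & state$v * state$theta <= 0
  list(violations = ids[bad], feasible = !any(bad))
}

#' One-way flux decomposition
#'
#' Splits net fluxes into microscopic forward and backward rates oriented
#' along the net flux: `v+ = e^|theta|/(e^|theta|-1) |v|`,
#' `v- = |v|/(e^|theta|-1)`, so that `v+ - v- = |v|` and `v+/v- = e^|theta|`.
#'
#' @param v net fluxes (mM/s)
#' @param theta thermodynamic forces (RT units); must satisfy
#'   `v * theta > 0` wherever `v != 0`.
#' @param equilibrium_exchange one-way rate assigned to reactions with
#'   `v = 0` and `theta = 0` (default 0).
#' @return list with `v_plus`, `v_minus` (both >= 0, flux-oriented).
#' @export
one_way_fluxes <- function(v, theta, equilibrium_exchange = 0) {
  stopifnot(length(v) == length(theta))
  if (any(v != 0 & theta == 0)) stop("infinite one-way flux at equilibrium")
  if (any(v * theta < 0)) stop("flux against force; infeasible state")
  at <- abs(theta); av <- abs(v)
  denom <- expm1(at)                  # e^|theta| - 1, accurate near 0
  v_plus <- ifelse(v == 0 & theta == 0, equilibrium_exchange,
                   ifelse(v == 0, 0, exp(at) / denom * av))
  v_minus <- ifelse(v == 0 & theta == 0, equilibrium_exchange,
                    ifelse(v == 0, 0, av / denom))
  list(v_plus = v_plus, v_minus = v_minus)
}

#' Project fluxes onto the stationary cone
#'
#' Solves `argmin ||v - v_data||_2` subject to `N_int v = 0` and per-reaction
#' sign constraints, as a convex QP.
#'
#' @param net an `stm_network`
#' @param v_data flux data vector (one per reaction).
#' @param sign_constraints character vector per reaction from
#'   `"+"` (v >= 0), `"-"` (v <= 0), `"0"` (v = 0), `"free"`.
#' @return stationary flux vector.
#' @export
project_fluxes <- function(net, v_data, sign_constraints = NULL) {
  n_r <- length(net$reactions)
  v_data <- resolve_named(v_data, net$reactions, "v_data")
  if (is.null(sign_constraints)) sign_constraints <- rep("free", n_r)
  sign_constraints <- resolve_named(sign_constraints, net$reactions, "sign_constraints")
  stopifnot(all(sign_constraints %in% c("+", "-", "0", "free")))
  N_int <- internal_stoich(net)
  lb <- ifelse(sign_constraints %in% c("+", "0"), 0, -Inf)
  ub <- ifelse(sign_constraints %in% c("-", "0"), 0, Inf)
  v <- qp_box(H = diag(n_r), f = -as.numeric(v_data),
              Aeq = N_int, beq = rep(0, nrow(N_int)), lb = lb, ub = ub)
  res <- max(abs(N_int %*% v))
  if (res > 1e-8) stop("flux projection failed: stationarity residual ", format(res))
  names(v) <- net$reactions
  v
}

#' Max-min driving force concentrations
#'
#' Finds log-concentrations maximising the smallest flux-oriented
#' thermodynamic force subject to per-metabolite concentration bounds
#' (a linear program). Reactions with `v = 0` are ignored.
#'
#' @param net an `stm_network`
#' @param v flux vector fixing the orientation.
#' @param ln_keq log equilibrium constants.
#' @param bounds 2-column matrix (or data frame) of `[c_min, c_max]` per
#'   metabolite (mM), rows named or in metabolite order.
#' @return list with `c` (concentrations), `min_force`, and `bottlenecks`
#'   (reactions attaining the minimum).
#' @export
mdf_concentrations <- function(net, v, ln_keq, bounds) {
  v <- resolve_named(v, net$reactions, "v")
  ln_keq <- resolve_named(ln_keq, net$reactions, "ln_keq")
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != length(net$metabolites)) stop("bounds: one row per metabolite")
  if (any(bounds <= 0)) stop("bounds must be positive")
  lo <- log(bounds[, 1]); hi <- log(bounds[, 2])
  if (any(hi < lo)) stop("bounds: c_max < c_min")
  active <- which(v != 0)
  n_m <- length(net$metabolites)

  # variables x = (ln c, t); maximise t s.t. s_l (ln_keq_l - n_l . ln c) >= t
  s <- sign(v[active])
  # one row per active reaction: s*n . lnc + t <= s*ln_keq
  A <- cbind(t(net$stoich[, active, drop = FALSE]) * s, 1)
  b <- s * ln_keq[active]
  sol <- lp_box(obj = c(rep(0, n_m), 1),
                A = A, b = b,
                lb = c(lo, -1e3), ub = c(hi, 1e3), maximize = TRUE)
  if (!sol$ok) {
    stop("MDF infeasible under the given bounds")
  }
  lnc <- sol$x[seq_len(n_m)]
  min_force <- sol$x[n_m + 1]
  cc <- exp(lnc); names(cc) <- net$metabolites
  theta <- compute_forces(net, cc, ln_keq)
  oriented <- sign(v[active]) * theta[active]
  bn <- net$reactions[active][oriented <= min_force + 1e-6]
  if (min_force <= 0) {
    warning("maximal attainable min driving force is non-positive; bottleneck reaction(s): ",
            paste(bn, collapse = ", "))
  }
  list(c = cc, min_force = min_force, bottlenecks = bn)
}
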
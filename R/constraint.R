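# FBA- and MoMA-style knockdown synergies for comparison with control-theory
# predictions.

#' Define a flux optimisation problem
#'
#' @param net an `stm_network`
#' @param objective objective coefficient vector per reaction (maximised).
#' @param lb,ub flux bounds per reaction (defaults 0 / 1000).
#' @return object of class `stm_flux_problem`.
#' @export
flux_problem <- function(net, objective, lb = 0, ub = 1000) {
  n_r <- length(net$reactions)
  objective <- resolve_named(objective, net$reactions, "objective")
  lb <- resolve_named(lb, net$reactions, "lb")
  ub <- resolve_named(ub, net$reactions, "ub")
  structure(list(network = net, objective = objective, lb = lb, ub = ub),
            class = "stm_flux_problem")
}

# FBA solve with optional extra inequality rows; lexicographic secondary
# minimisation of ||v||_1 at the optimal objective for reproducibility.
fba_solve <- function(problem, extra_A = NULL, extra_b = NULL) {
  net <- problem$network
  N_int <- internal_stoich(net)
  n_r <- length(net$reactions)
  sol <- lp_box(obj = problem$objective,
                A = extra_A, b = extra_b,
                Aeq = N_int, beq = rep(0, nrow(N_int)),
                lb = problem$lb, ub = problem$ub, maximize = TRUE)
  if (!sol$ok) stop("FBA problem infeasible or unbounded")
  # secondary: min sum p+q with v = p - q, objective fixed
  obj2 <- rep(1, 2 * n_r)
  Aeq2 <- rbind(cbind(N_int, -N_int),
                c(problem$objective, -problem$objective))
  beq2 <- c(rep(0, nrow(N_int)), sol$value)
  A2 <- NULL; b2 <- NULL
  if (!is.null(extra_A)) { A2 <- cbind(extra_A, -extra_A); b2 <- extra_b }
  lb2 <- c(pmax(problem$lb, 0), pmax(-problem$ub, 0))
  ub2 <- c(pmax(problem$ub, 0), pmax(-problem$lb, 0))
  sol2 <- lp_box(obj = obj2, A = A2, b = b2, Aeq = Aeq2, beq = beq2,
                 lb = lb2, ub = ub2, maximize = FALSE)
  v <- if (sol2$ok) {
    sol2$x[seq_len(n_r)] - sol2$x[n_r + seq_len(n_r)]
  } else sol$x
  names(v) <- net$reactions
  list(v = v, objective_value = sum(problem$objective * v))
}

# inequality rows capping |v_l| at cap in the baseline direction, forbidding
# reversal: 0 <= s v <= cap
cap_rows <- function(net, reaction, s, cap) {
  n_r <- length(net$reactions)
  l <- match(reaction, net$reactions)
  up <- numeric(n_r); up[l] <- s
  dn <- numeric(n_r); dn[l] <- -s
  list(A = rbind(up, dn), b = c(cap, 0))
}

#' FBA knockdown synergy
#'
#' Simulates enzyme inhibition by capping the catalysed flux at
#' `knockdown_factor` times its baseline magnitude (no reversals allowed),
#' re-optimising, and comparing the objective to baseline. A double
#' inhibition of one enzyme applies the cap twice (factor squared).
#'
#' @param problem an `stm_flux_problem`
#' @param pair character vector of two reaction ids.
#' @param knockdown_factor relative cap (default 0.9).
#' @return list with `w_a`, `w_b`, `w_ab`, `eta`, and the baseline solution.
#' @export
fba_synergy <- function(problem, pair, knockdown_factor = 0.9) {
  base <- fba_solve(problem)
  if (base$objective_value == 0) stop("baseline objective is zero")
  perturbed <- function(caps) {
    A <- do.call(rbind, lapply(caps, `[[`, "A"))
    b <- unlist(lapply(caps, `[[`, "b"))
    fba_solve(problem, extra_A = A, extra_b = b)$objective_value /
      base$objective_value
  }
  w_for <- function(rxns, factors) {
    caps <- lapply(seq_along(rxns), function(k) {
      v0 <- base$v[rxns[k]]
      if (v0 == 0) return(NULL)               # capping a zero flux is a no-op
      cap_rows(problem$network, rxns[k], sign(v0), factors[k] * abs(v0))
    })
    caps <- Filter(Negate(is.null), caps)
    if (!length(caps)) return(1)
    perturbed(caps)
  }
  a <- pair[1]; b <- pair[2]
  w_a <- w_for(a, knockdown_factor)
  w_b <- w_for(b, knockdown_factor)
  w_ab <- if (a == b) w_for(a, knockdown_factor^2)
          else w_for(c(a, b), rep(knockdown_factor, 2))
  list(w_a = w_a, w_b = w_b, w_ab = w_ab,
       eta = synergy_eta(w_a, w_b, w_ab), baseline = base)
}

#' MoMA knockdown synergy
#'
#' Perturbed fluxes minimise the Euclidean distance to the baseline flux
#' vector subject to stationarity, bounds, and the knockdown caps; the target
#' value is read off the perturbed flux vector through the objective.
#'
#' @param problem an `stm_flux_problem`
#' @param baseline_v baseline flux vector (default: FBA solution).
#' @inheritParams fba_synergy
#' @return list with `w_a`, `w_b`, `w_ab`, `eta`.
#' @export
moma_synergy <- function(problem, baseline_v = NULL, pair, knockdown_factor = 0.9) {
  net <- problem$network
  N_int <- internal_stoich(net)
  n_r <- length(net$reactions)
  if (is.null(baseline_v)) baseline_v <- fba_solve(problem)$v
  baseline_v <- resolve_named(baseline_v, net$reactions, "baseline_v")
  base_obj <- sum(problem$objective * baseline_v)
  if (base_obj == 0) stop("baseline objective is zero")
  moma_w <- function(rxns, factors) {
    caps <- lapply(seq_along(rxns), function(k) {
      v0 <- baseline_v[rxns[k]]
      if (v0 == 0) return(NULL)
      cap_rows(net, rxns[k], sign(v0), factors[k] * abs(v0))
    })
    caps <- Filter(Negate(is.null), caps)
    A <- if (length(caps)) do.call(rbind, lapply(caps, `[[`, "A")) else NULL
    b <- if (length(caps)) unlist(lapply(caps, `[[`, "b")) else NULL
    v <- qp_box(H = diag(n_r), f = -as.numeric(baseline_v),
                A = A, b = b, Aeq = N_int, beq = rep(0, nrow(N_int)),
                lb = problem$lb, ub = problem$ub)
    sum(problem$objective * v) / base_obj
  }
  a <- pair[1]; b <- pair[2]
  w_a <- moma_w(a, knockdown_factor)
  w_b <- moma_w(b, knockdown_factor)
  w_ab <- if (a == b) moma_w(a, knockdown_factor^2)
          else moma_w(c(a, b), rep(knockdown_factor, 2))
  list(w_a = w_a, w_b = w_b, w_ab = w_ab, eta = synergy_eta(w_a, w_b, w_ab))
}
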
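# Shared fixture helpers. All randomness is seeded by the caller.

# random network + feasible state + sampled saturation, retried until the
# Jacobian of the cm-law linearisation is stable and non-singular
random_stable_fixture <- function(seed, n_met = 4, n_rxn = 5, max_tries = 50) {
  for (t in seq_len(max_tries)) {
    fx <- try(make_fixture("random", n_met = n_met, n_rxn = n_rxn,
                           seed = seed * 1000 + t), silent = TRUE)
    if (inherits(fx, "try-error")) next
    set.seed(seed * 1000 + t)
    sat <- sample_saturation(fx$network)
    ctl <- try(suppressWarnings(
      control_analysis(fx$network, fx$state, sat, "cm")), silent = TRUE)
    if (inherits(ctl, "try-error")) next
    if (!all(Re(ctl$eigenvalues) < -1e-9)) next
    return(list(network = fx$network, state = fx$state, saturation = sat,
                control = ctl))
  }
  stop("no stable random fixture found")
}

# scaled flux/concentration control coefficients by perturbing enzyme levels
# of the reconstructed nonlinear model and re-solving the steady state
fd_scaled_control <- function(model, rel_step = 1e-3) {
  net <- model$network
  red <- reduce_network(net)
  n_r <- length(net$reactions)
  base <- steady_state(model, reduced = red)
  stopifnot(base$converged)
  C_V <- matrix(0, n_r, n_r, dimnames = list(net$reactions, net$reactions))
  int <- !net$external
  C_S <- matrix(0, sum(int), n_r,
                dimnames = list(net$metabolites[int], net$reactions))
  for (j in seq_len(n_r)) {
    up <- model$e; up[j] <- up[j] * (1 + rel_step)
    dn <- model$e; dn[j] <- dn[j] * (1 - rel_step)
    ssu <- steady_state(model, e = up, reduced = red)
    ssd <- steady_state(model, e = dn, reduced = red)
    stopifnot(ssu$converged, ssd$converged)
    dln <- log((1 + rel_step) / (1 - rel_step))
    C_V[, j] <- (log(abs(ssu$v)) - log(abs(ssd$v))) / dln
    C_S[, j] <- (log(ssu$c[int]) - log(ssd$c[int])) / dln
  }
  list(C_V = C_V, C_S = C_S)
}
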
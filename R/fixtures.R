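# Deterministic fixture networks and states, built so that feasibility and
# Wegscheider checks pass by construction.

#' Construct a fixture network with a consistent reference state
#'
#' Kinds:
#' * `linear_chain`: `n` reactions converting `X0 -> X1 -> ... -> Xn`, chain
#'   ends external, equal forces on each step.
#' * `bypass`: conversion `S1 -> S3` either directly or via the intermediate
#'   `S2`, plus supply and demand reactions (5 reactions, 3 internal
#'   metabolites, two stationary flux modes).
#' * `moiety_cycle`: an ATP/ADP pair interconverted by two reactions
#'   (one conservation relation).
#' * `turbo`: a minimal "turbo design" pathway (upper reaction invests one
#'   ATP, lower reaction pays back two, an ATPase drains the surplus) with an
#'   ATP/ADP conservation relation; at strong driving forces the ATPase shows
#'   paradoxical negative control over its own flux.
#' * `random`: random sparse network with a feasible stationary state found
#'   by flux projection (retries until feasible).
#'
#' @param kind fixture kind.
#' @param n chain length (linear_chain) .
#' @param theta per-reaction driving force (RT units) for the deterministic
#'   fixtures.
#' @param flux flux scale (mM/s).
#' @param beta saturation value filled into the returned saturation set.
#' @param n_met,n_rxn,seed random-fixture parameters.
#' @return list with `network`, `state`, `saturation`.
#' @export
make_fixture <- function(kind = c("linear_chain", "bypass", "moiety_cycle",
                                  "turbo", "random"),
                         n = 2, theta = 2, flux = 1, beta = 0.5,
                         n_met = 5, n_rxn = 6, seed = 1) {
  kind <- match.arg(kind)
  fx <- switch(kind,
    linear_chain = fixture_chain(n, theta, flux),
    bypass = fixture_bypass(theta, flux),
    moiety_cycle = fixture_moiety(theta, flux),
    turbo = fixture_turbo(theta, flux),
    random = fixture_random(n_met, n_rxn, seed, flux)
  )
  fx$saturation <- stm_saturation(fx$network, beta_M = beta,
                                  beta_A = beta, beta_I = beta)
  fx
}

fixture_chain <- function(n, theta, flux) {
  stopifnot(n >= 1)
  mets <- paste0("X", 0:n)
  rxns <- paste0("R", 1:n)
  N <- matrix(0, n + 1, n, dimnames = list(mets, rxns))
  for (l in 1:n) { N[l, l] <- -1; N[l + 1, l] <- 1 }
  net <- stm_network(N, external = c("X0", paste0("X", n)))
  state <- stm_state(net, c = rep(1, n + 1), v = rep(flux, n),
                     ln_keq = rep(theta, n), check = FALSE)
  list(network = net, state = state)
}

fixture_bypass <- function(theta = 2, flux = 1) {
  mets <- c("Xin", "S1", "S2", "S3", "Xout")
  rxns <- c("R_in", "R_direct", "R_s12", "R_s23", "R_out")
  N <- matrix(0, 5, 5, dimnames = list(mets, rxns))
  N["Xin", "R_in"] <- -1;  N["S1", "R_in"] <- 1
  N["S1", "R_direct"] <- -1; N["S3", "R_direct"] <- 1
  N["S1", "R_s12"] <- -1;  N["S2", "R_s12"] <- 1
  N["S2", "R_s23"] <- -1;  N["S3", "R_s23"] <- 1
  N["S3", "R_out"] <- -1;  N["Xout", "R_out"] <- 1
  net <- stm_network(N, external = c("Xin", "Xout"))
  # Wegscheider: theta(R_s12) + theta(R_s23) = theta(R_direct) at unit c
  ln_keq <- c(R_in = theta, R_direct = 2 * theta * 0.75,
              R_s12 = theta * 0.75, R_s23 = theta * 0.75, R_out = theta)
  v <- c(R_in = flux, R_direct = flux / 2, R_s12 = flux / 2,
         R_s23 = flux / 2, R_out = flux)
  state <- stm_state(net, c = rep(1, 5), v = v, ln_keq = ln_keq, check = FALSE)
  list(network = net, state = state)
}

fixture_moiety <- function(theta = 2, flux = 1) {
  mets <- c("S", "P", "ATP", "ADP", "X", "Y")
  rxns <- c("R_use", "R_regen")
  N <- matrix(0, 6, 2, dimnames = list(mets, rxns))
  N[c("S", "ATP"), "R_use"] <- -1; N[c("P", "ADP"), "R_use"] <- 1
  N[c("ADP", "X"), "R_regen"] <- -1; N[c("ATP", "Y"), "R_regen"] <- 1
  net <- stm_network(N, external = c("S", "P", "X", "Y"))
  state <- stm_state(net, c = rep(1, 6), v = rep(flux, 2),
                     ln_keq = rep(theta, 2), check = FALSE)
  list(network = net, state = state)
}

fixture_turbo <- function(theta = 4, flux = 1) {
  mets <- c("S", "P", "M", "ATP", "ADP")
  rxns <- c("R_upper", "R_lower", "R_atpase")
  N <- matrix(0, 5, 3, dimnames = list(mets, rxns))
  N[c("S", "ATP"), "R_upper"] <- -1; N[c("M", "ADP"), "R_upper"] <- 1
  N["M", "R_lower"] <- -1; N["ADP", "R_lower"] <- -2
  N["P", "R_lower"] <- 1; N["ATP", "R_lower"] <- 2
  N["ATP", "R_atpase"] <- -1; N["ADP", "R_atpase"] <- 1
  net <- stm_network(N, external = c("S", "P"))
  state <- stm_state(net, c = rep(1, 5), v = rep(flux, 3),
                     ln_keq = rep(theta, 3), check = FALSE)
  list(network = net, state = state)
}

fixture_random <- function(n_met, n_rxn, seed, flux = 1, max_tries = 100) {
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    mets <- c("Xs", paste0("M", seq_len(n_met)), "Xp")
    n_tot <- length(mets)
    N <- matrix(0, n_tot, n_rxn,
                dimnames = list(mets, paste0("R", seq_len(n_rxn))))
    # backbone path Xs -> M... -> Xp keeps the network connected and gives a
    # thermodynamically consistent downhill direction
    path <- c("Xs", sample(paste0("M", seq_len(n_met))), "Xp")
    n_back <- min(n_rxn, length(path) - 1)
    for (l in seq_len(n_back)) {
      N[path[l], l] <- N[path[l], l] - 1
      N[path[l + 1], l] <- N[path[l + 1], l] + 1
    }
    if (n_rxn > n_back) {
      for (l in (n_back + 1):n_rxn) {
        # shortcut between two path positions, written in random direction
        pos <- sort(sample(seq_along(path), 2))
        pick <- path[pos]
        if (stats::runif(1) < 0.5) pick <- rev(pick)
        N[pick[1], l] <- N[pick[1], l] - 1
        N[pick[2], l] <- N[pick[2], l] + 1
      }
    }
    if (any(colSums(abs(N)) == 0)) next
    net <- try(stm_network(N, external = c("Xs", "Xp")), silent = TRUE)
    if (inherits(net, "try-error")) next
    # effective potentials decrease along the path so backbone forces are
    # positive; concentrations add only mild noise
    g <- stats::setNames(numeric(n_tot), mets)
    g[path] <- rev(cumsum(c(0, stats::runif(length(path) - 1, 1, 2.5))))
    lnc <- stats::rnorm(n_tot, 0, 0.2)
    cc <- exp(lnc)
    mu0 <- g - lnc
    ln_keq <- keq_from_mu0(net, mu0, RT = 1)
    theta <- compute_forces(net, cc, ln_keq)
    if (any(abs(theta) < 0.3)) next
    sgn <- ifelse(theta > 0, "+", "-")
    v_data <- sign(theta) * stats::runif(n_rxn, 0.5, 1.5) * flux
    v <- try(project_fluxes(net, v_data, sgn), silent = TRUE)
    if (inherits(v, "try-error")) next
    if (any(abs(v) < 0.05 * flux)) next
    st <- suppressWarnings(stm_state(net, cc, v, ln_keq, check = FALSE))
    if (!check_feasibility(st)$feasible) next
    return(list(network = net, state = st))
  }
  stop("random fixture: no feasible state found after ", max_tries, " tries")
}
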
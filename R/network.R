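#' Define a metabolic reaction network
#'
#' A network couples an ordered set of metabolites to an ordered set of
#' reactions through a signed stoichiometric matrix, flags metabolites as
#' external (clamped boundary species) or internal (dynamic), and optionally
#' carries small-molecule regulation edges (non-competitive activation or
#' inhibition) with molecularities.
#'
#' @param stoich numeric matrix, metabolites in rows, reactions in columns.
#'   Row and column names are used as metabolite and reaction identifiers;
#'   unnamed dimensions get `M1, M2, ...` / `R1, R2, ...`.
#' @param external logical vector (length = number of metabolites, or a
#'   character vector of metabolite ids) marking clamped boundary metabolites.
#' @param regulation optional data frame with columns `reaction`,
#'   `metabolite`, `kind` (`"activator"` or `"inhibitor"`) and optionally
#'   `molecularity` (default 1).
#' @return An object of class `stm_network`.
#' @examples
#' N <- matrix(c(-1, 1, 0, 0, -1, 1), nrow = 3,
#'             dimnames = list(c("X0", "S", "X1"), c("R1", "R2")))
#' net <- stm_network(N, external = c("X0", "X1"))
#' net
#' @export
stm_network <- function(stoich, external = NULL, regulation = NULL) {
  stoich <- as.matrix(stoich)
  if (is.null(rownames(stoich))) rownames(stoich) <- paste0("M", seq_len(nrow(stoich)))
  if (is.null(colnames(stoich))) colnames(stoich) <- paste0("R", seq_len(ncol(stoich)))
  mets <- rownames(stoich)
  rxns <- colnames(stoich)
  if (anyDuplicated(mets)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxns)) stop("duplicate reaction ids")
  if (any(colSums(abs(stoich)) == 0)) {
    stop("all-zero reaction column(s): ",
         paste(rxns[colSums(abs(stoich)) == 0], collapse = ", "))
  }
  if (is.null(external)) external <- rep(FALSE, length(mets))
  if (is.character(external)) {
    bad <- setdiff(external, mets)
    if (length(bad)) stop("unknown external metabolite(s): ", paste(bad, collapse = ", "))
    external <- mets %in% external
  }
  stopifnot(is.logical(external), length(external) == length(mets))
  names(external) <- mets

  regulation <- normalize_regulation(regulation, mets, rxns)

  structure(
    list(metabolites = mets, reactions = rxns, stoich = stoich,
         external = external, regulation = regulation),
    class = "stm_network"
  )
}

normalize_regulation <- function(regulation, mets, rxns) {
  if (is.null(regulation) || nrow(as.data.frame(regulation)) == 0) {
    return(tibble::tibble(reaction = character(), metabolite = character(),
                          kind = character(), molecularity = numeric()))
  }
  reg <- tibble::as_tibble(regulation)
  if (!all(c("reaction", "metabolite", "kind") %in% names(reg))) {
    stop("regulation needs columns reaction, metabolite, kind")
  }
  if (!"molecularity" %in% names(reg)) reg$molecularity <- 1
  reg$molecularity[is.na(reg$molecularity)] <- 1
  if (any(!reg$reaction %in% rxns)) stop("regulation references unknown reaction")
  if (any(!reg$metabolite %in% mets)) stop("regulation references unknown metabolite")
  if (any(!reg$kind %in% c("activator", "inhibitor"))) {
    stop("regulation kind must be 'activator' or 'inhibitor'")
  }
  if (any(reg$molecularity < 0)) stop("regulation molecularity must be >= 0")
  reg[c("reaction", "metabolite", "kind", "molecularity")]
}

#' @export
print.stm_network <- function(x, ...) {
  cat("<stm_network> ", length(x$metabolites), " metabolites (",
      sum(!x$external), " internal), ", length(x$reactions), " reactions, ",
      nrow(x$regulation), " regulation edge(s)\n", sep = "")
  invisible(x)
}

#' Internal stoichiometric matrix (dynamic metabolites only)
#' @param net an `stm_network`
#' @return numeric matrix with one row per internal metabolite.
#' @export
internal_stoich <- function(net) {
  net$stoich[!net$external, , drop = FALSE]
}

# Null space of a matrix via SVD with relative singular-value tolerance.
nullspace_tol <- function(M, tol = 1e-10) {
  M <- as.matrix(M)
  if (nrow(M) == 0 || ncol(M) == 0) return(matrix(0, ncol(M), 0))
  sv <- svd(M, nu = 0, nv = ncol(M))
  smax <- if (length(sv$d)) max(sv$d) else 0
  r <- sum(sv$d > tol * max(smax, 1))
  if (r == ncol(M)) return(matrix(0, ncol(M), 0))
  sv$v[, seq(r + 1, ncol(M)), drop = FALSE]
}

matrix_rank <- function(M, tol = 1e-10) {
  if (nrow(M) == 0 || ncol(M) == 0) return(0L)
  sv <- svd(M)$d
  sum(sv > tol * max(max(sv), 1))
}

#' Structural reduction of a network
#'
#' Splits the internal stoichiometric matrix `N_int` into a full-row-rank part
#' `N_ind` (independent metabolites) and a link matrix `L` with
#' `N_int = L %*% N_ind`. Also returns a left-null basis `G` (conservation
#' relations, `G %*% N_int = 0`) and a right-null basis `K` of `N_int`
#' (stationary flux modes). Independent rows are chosen greedily in metabolite
#' order, so the selection is deterministic.
#'
#' @param net an `stm_network`
#' @param tol relative singular-value tolerance for rank decisions.
#' @return An object of class `stm_reduced` with fields `independent_rows`
#'   (indices into the internal metabolites), `internal_mets`, `N_int`,
#'   `N_ind`, `L`, `G`, `K`.
#' @export
reduce_network <- function(net, tol = 1e-10) {
  N_int <- internal_stoich(net)
  if (nrow(N_int) == 0) stop("no dynamic metabolites")
  n_int <- nrow(N_int)

  # greedy independent-row selection in input order
  idx <- integer(0)
  for (i in seq_len(n_int)) {
    cand <- c(idx, i)
    if (matrix_rank(N_int[cand, , drop = FALSE], tol) == length(cand)) idx <- cand
  }
  N_ind <- N_int[idx, , drop = FALSE]
  # L solves N_int = L N_ind; N_ind has full row rank
  L <- t(solve(N_ind %*% t(N_ind), N_ind %*% t(N_int)))
  dimnames(L) <- list(rownames(N_int), rownames(N_ind))

  G <- t(nullspace_tol(t(N_int), tol))
  if (nrow(G)) colnames(G) <- rownames(N_int)
  K <- nullspace_tol(N_int, tol)
  if (ncol(K)) rownames(K) <- colnames(N_int)

  structure(
    list(independent_rows = idx, internal_mets = rownames(N_int),
         N_int = N_int, N_ind = N_ind, L = L, G = G, K = K),
    class = "stm_reduced"
  )
}

#' @export
print.stm_reduced <- function(x, ...) {
  cat("<stm_reduced> rank ", nrow(x$N_ind), " of ", nrow(x$N_int),
      " internal metabolites; ", nrow(x$G), " conservation relation(s); kernel dim ",
      ncol(x$K), "\n", sep = "")
  invisible(x)
}

#' Wegscheider consistency of equilibrium constants
#'
#' Equilibrium constants derive from chemical potentials, so their logarithms
#' must sum to zero around every stoichiometric cycle. Cycles are taken from
#' the right-null space of the *full* stoichiometric matrix (internal and
#' external rows), since equilibrium constants involve all species.
#'
#' @param net an `stm_network`
#' @param ln_keq numeric vector of log equilibrium constants, one per reaction.
#' @param tol maximal tolerated |k' ln_keq| over kernel basis vectors.
#' @return list with `max_violation` and `pass`.
#' @export
wegscheider_check <- function(net, ln_keq, tol = 1e-9) {
  if (length(ln_keq) != length(net$reactions)) {
    stop("ln_keq length (", length(ln_keq), ") != number of reactions (",
         length(net$reactions), ")")
  }
  K_full <- nullspace_tol(net$stoich)
  if (ncol(K_full)) {
    # rescale each cycle vector to a maximal entry of 1 so violations are in
    # ln-keq units of the dominant reaction
    K_full <- sweep(K_full, 2, apply(abs(K_full), 2, max), "/")
  }
  max_violation <- if (ncol(K_full) == 0) 0 else max(abs(t(K_full) %*% ln_keq))
  list(max_violation = max_violation, pass = max_violation <= tol)
}

#' Equilibrium constants from standard chemical potentials
#'
#' `ln_keq_l = -(sum_i n_il mu0_i) / RT`. The result is a gradient field over
#' the reaction graph and therefore always Wegscheider-consistent.
#'
#' @param net an `stm_network`
#' @param mu0 named or ordered numeric vector of standard chemical potentials
#'   (kJ/mol), one per metabolite.
#' @param RT thermal energy in kJ/mol; default 2.479 (T = 298.15 K).
#' @return numeric vector `ln_keq` (one per reaction).
#' @export
keq_from_mu0 <- function(net, mu0, RT = 2.479) {
  mu0 <- resolve_named(mu0, net$metabolites, "mu0")
  if (any(!is.finite(mu0))) {
    stop("non-finite mu0 for metabolite(s): ",
         paste(net$metabolites[!is.finite(mu0)], collapse = ", "))
  }
  ln_keq <- as.numeric(-t(net$stoich) %*% mu0 / RT)
  names(ln_keq) <- net$reactions
  ln_keq
}

# Match a possibly named vector against an id order; error names missing ids.
resolve_named <- function(x, ids, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing)) stop("missing ", what, " for: ", paste(missing, collapse = ", "))
    x <- x[ids]
  } else if (length(x) == 1L) {
    x <- rep(x, length(ids))
    names(x) <- ids
  } else {
    if (length(x) != length(ids)) stop(what, " has wrong length")
    names(x) <- ids
  }
  x
}

# Substrate/product molecularity matrices (reaction x metabolite), network
# orientation: substrates have negative stoichiometric coefficients.
molecularity_matrices <- function(net) {
  Nt <- t(net$stoich)
  list(m_S = pmax(-Nt, 0), m_P = pmax(Nt, 0))
}

# Regulation molecularity matrices (reaction x metabolite).
regulation_matrices <- function(net) {
  n_r <- length(net$reactions); n_m <- length(net$metabolites)
  m_A <- m_I <- matrix(0, n_r, n_m, dimnames = list(net$reactions, net$metabolites))
  reg <- net$regulation
  for (k in seq_len(nrow(reg))) {
    M <- if (reg$kind[k] == "activator") "m_A" else "m_I"
    if (M == "m_A") m_A[reg$reaction[k], reg$metabolite[k]] <- reg$molecularity[k]
    else m_I[reg$reaction[k], reg$metabolite[k]] <- reg$molecularity[k]
  }
  list(m_A = m_A, m_I = m_I)
}
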
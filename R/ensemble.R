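# Ensembles of sampled models: saturation sampling, stability screening,
# target aggregation, and significance testing between ensembles.

#' Specify a model ensemble
#'
#' @param n_samples number of sampled model instances (>= 1).
#' @param seed RNG seed; per-sample substreams are derived from it by a
#'   counter, so results are reproducible and order-independent.
#' @param beta_dist "uniform" or "beta" for saturation sampling.
#' @param lo,hi,a,b distribution parameters (see [sample_saturation()]).
#' @param law rate-law kind.
#' @param discard_unstable drop unstable samples from summaries (they are
#'   still recorded with `stable = FALSE`).
#' @param c_jitter_sd optional log-normal jitter (sdlog) applied to internal
#'   metabolite concentrations per sample (0 = fixed state).
#' @return object of class `stm_ensemble_spec`.
#' @export
ensemble_spec <- function(n_samples = 100, seed = 1,
                          beta_dist = c("uniform", "beta"),
                          lo = 0, hi = 1, a = 2, b = 2, law = "cm",
                          discard_unstable = TRUE, c_jitter_sd = 0) {
  stopifnot(n_samples >= 1)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 beta_dist = match.arg(beta_dist), lo = lo, hi = hi,
                 a = a, b = b, law = law,
                 discard_unstable = discard_unstable,
                 c_jitter_sd = c_jitter_sd),
            class = "stm_ensemble_spec")
}

sample_seed <- function(seed, k) (as.numeric(seed) * 48271 + k * 1000003) %% 2147483647

#' Sample a model ensemble
#'
#' Repeatedly samples saturation values (and optionally jittered
#' concentrations), computes elasticities and control matrices, screens
#' stability of the Jacobian (max real eigenvalue < -1e-9), and records the
#' requested target quantities per sample.
#'
#' @param net an `stm_network`
#' @param state an `stm_state` (feasible reference).
#' @param spec an `stm_ensemble_spec`.
#' @param targets a function `(control_set) -> named numeric vector`; default
#'   records all scaled flux control coefficients.
#' @return object of class `stm_ensemble_result`: a list with `records`
#'   (long tibble: sample, target, value, stable) and `acceptance_rate`.
#' @export
sample_ensemble <- function(net, state, spec = ensemble_spec(),
                            targets = target_flux_control) {
  recs <- vector("list", spec$n_samples)
  stable_flags <- logical(spec$n_samples)
  for (k in seq_len(spec$n_samples)) {
    set.seed(sample_seed(spec$seed, k))
    sat <- sample_saturation(net, dist = spec$beta_dist,
                             lo = spec$lo, hi = spec$hi, a = spec$a, b = spec$b)
    st <- state
    if (spec$c_jitter_sd > 0) {
      int <- !net$external
      cj <- st$c
      cj[int] <- cj[int] * exp(stats::rnorm(sum(int), 0, spec$c_jitter_sd))
      st <- stm_state(net, cj, st$v, st$ln_keq, st$growth_rate, check = FALSE)
    }
    ctl <- tryCatch(control_analysis(net, st, sat, spec$law),
                    error = function(e) NULL)
    stable <- !is.null(ctl) && all(Re(ctl$eigenvalues) < -1e-9)
    stable_flags[k] <- stable
    vals <- if (!is.null(ctl)) targets(ctl) else
      stats::setNames(NA_real_, "failed")
    recs[[k]] <- tibble::tibble(sample = k, target = names(vals),
                                value = unname(vals), stable = stable)
  }
  acceptance <- mean(stable_flags)
  if (spec$discard_unstable && acceptance == 0) {
    stop("zero accepted samples (acceptance rate 0 of ", spec$n_samples, ")")
  }
  structure(list(records = dplyr::bind_rows(recs),
                 acceptance_rate = acceptance, spec = spec),
            class = "stm_ensemble_result")
}

#' @export
print.stm_ensemble_result <- function(x, ...) {
  cat("<stm_ensemble_result> ", max(x$records$sample), " samples, ",
      dplyr::n_distinct(x$records$target), " targets; acceptance rate ",
      format(x$acceptance_rate, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Default ensemble targets: scaled flux control coefficients
#'
#' @param ctl an `stm_control_set`
#' @return named vector `C[flux<-enzyme]` over all reaction pairs.
#' @export
target_flux_control <- function(ctl) {
  M <- ctl$C_V_scaled
  nm <- outer(rownames(M), colnames(M), function(a, b) paste0("C[", a, "<-", b, "]"))
  stats::setNames(as.numeric(M), as.character(nm))
}

accepted_records <- function(res) {
  r <- res$records
  if (res$spec$discard_unstable) r <- dplyr::filter(r, .data$stable) else r
}

#' Compare two model ensembles target by target
#'
#' Two-sided Mann-Whitney U test per target with Benjamini-Hochberg FDR
#' control across targets. Degenerate (constant) targets get p = 1 and are
#' flagged.
#'
#' @param resA,resB `stm_ensemble_result`s over the same target set.
#' @param alpha FDR level (default 0.05).
#' @return tibble with `target`, `p`, `q`, `significant`, `effect`
#'   (median difference B - A), `degenerate`.
#' @export
compare_ensembles <- function(resA, resB, alpha = 0.05) {
  a <- accepted_records(resA); b <- accepted_records(resB)
  targets <- intersect(unique(a$target), unique(b$target))
  if (!setequal(unique(a$target), unique(b$target))) {
    stop("ensembles have different target sets")
  }
  rows <- lapply(targets, function(tg) {
    xa <- a$value[a$target == tg]; xb <- b$value[b$target == tg]
    degen <- (stats::sd(c(xa, xb)) == 0) || length(unique(c(xa, xb))) == 1
    p <- if (degen) 1 else
      suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
    tibble::tibble(target = tg, p = p,
                   effect = stats::median(xb) - stats::median(xa),
                   degenerate = degen)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q <= alpha & alpha > 0
  out[c("target", "p", "q", "significant", "effect", "degenerate")]
}

#' Scale all thermodynamic forces of a state
#'
#' Multiplies every force by `factor` and re-solves the metabolite
#' concentrations to realise the new forces; where the force pattern cannot
#' be reached by concentrations alone (inconsistent cycle content), the
#' equilibrium constants absorb the residual and a message flags it. Fluxes
#' are unchanged.
#'
#' @param net an `stm_network`
#' @param state an `stm_state`
#' @param factor positive scaling factor (1 = identity).
#' @return a new `stm_state`.
#' @export
scale_forces <- function(net, state, factor) {
  stopifnot(factor > 0)
  theta_new <- factor * state$theta
  # theta = ln_keq - N' ln c  =>  N' dlnc = (1 - factor) theta
  rhs <- (1 - factor) * state$theta
  dlnc <- as.numeric(pracma::pinv(t(net$stoich)) %*% rhs)  # least-norm solution
  c_new <- state$c * exp(dlnc)
  resid <- theta_new - (state$ln_keq - as.numeric(t(net$stoich) %*% log(c_new)))
  ln_keq_new <- state$ln_keq
  if (max(abs(resid)) > 1e-9) {
    message("scale_forces: adjusting ln_keq by up to ",
            format(max(abs(resid)), digits = 3), " to realise scaled forces")
    ln_keq_new <- ln_keq_new + resid
  }
  suppressWarnings(
    stm_state(net, c_new, state$v, ln_keq_new, state$growth_rate, check = FALSE)
  )
}

#' Binomial confidence interval for a fraction-of-models statistic
#'
#' @param successes,n counts
#' @param level confidence level
#' @return tibble with `fraction`, `lower`, `upper`.
#' @export
fraction_ci <- function(successes, n, level = 0.95) {
  bt <- stats::binom.test(successes, n, conf.level = level)
  tibble::tibble(fraction = successes / n,
                 lower = bt$conf.int[1], upper = bt$conf.int[2])
}
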
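# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy elasticities into a long tibble
#'
#' @param x an `stm_elasticities`
#' @param ... unused
#' @return tibble with reaction, metabolite, scaled, unscaled, rev, den, reg.
#' @method tidy stm_elasticities
#' @export
tidy.stm_elasticities <- function(x, ...) {
  long <- function(M, name) {
    tibble::as_tibble(M, rownames = "reaction") |>
      tidyr::pivot_longer(-"reaction", names_to = "metabolite",
                          values_to = name)
  }
  out <- long(x$E_scaled, "scaled")
  out$unscaled <- long(x$E_unscaled, "unscaled")$unscaled
  out$rev <- long(x$E_rev, "rev")$rev
  out$den <- long(x$E_den, "den")$den
  out$reg <- long(x$E_reg, "reg")$reg
  dplyr::filter(out, .data$scaled != 0 | .data$unscaled != 0 |
                  .data$rev != 0 | .data$reg != 0)
}

#' Tidy a control analysis into a long tibble
#'
#' @param x an `stm_control_set`
#' @param ... unused
#' @return tibble: quantity ("flux_control"/"concentration_control"), row,
#'   perturbed reaction, unscaled and scaled values.
#' @method tidy stm_control_set
#' @export
tidy.stm_control_set <- function(x, ...) {
  long <- function(M, Ms, quantity) {
    a <- tibble::as_tibble(M, rownames = "row") |>
      tidyr::pivot_longer(-"row", names_to = "reaction", values_to = "unscaled")
    b <- tibble::as_tibble(Ms, rownames = "row") |>
      tidyr::pivot_longer(-"row", names_to = "reaction", values_to = "scaled")
    a$scaled <- b$scaled
    a$quantity <- quantity
    a
  }
  dplyr::bind_rows(
    long(x$C_V, x$C_V_scaled, "flux_control"),
    long(x$C_S, x$C_S_scaled, "concentration_control")
  )[c("quantity", "row", "reaction", "unscaled", "scaled")]
}

#' One-row summary of a control analysis
#' @param x an `stm_control_set`
#' @param ... unused
#' @method glance stm_control_set
#' @export
glance.stm_control_set <- function(x, ...) {
  tibble::tibble(
    n_reactions = nrow(x$C_V),
    n_internal = nrow(x$C_S),
    max_re_eigenvalue = max(Re(x$eigenvalues)),
    stable = x$stable,
    min_relaxation_time = min(x$relaxation_times),
    max_relaxation_time = max(x$relaxation_times)
  )
}

#' One-row summary of a kinetic model
#' @param x an `stm_kinetic_model`
#' @param ... unused
#' @method glance stm_kinetic_model
#' @export
glance.stm_kinetic_model <- function(x, ...) {
  tibble::tibble(
    n_reactions = length(x$network$reactions),
    n_metabolites = length(x$network$metabolites),
    law = paste(unique(x$law), collapse = "/"),
    haldane_max_violation = max(abs(haldane_residual(x))),
    kcat_plus_range = diff(range(x$k_cat_plus)),
    enzyme_total = sum(x$e)
  )
}

#' Heatmap of scaled control coefficients
#' @param object an `stm_control_set`
#' @param ... unused
#' @method autoplot stm_control_set
#' @export
autoplot.stm_control_set <- function(object, ...) {
  df <- tidy.stm_control_set(object)
  df <- dplyr::filter(df, .data$quantity == "flux_control")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reaction, y = .data$row,
                                   fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::labs(x = "perturbed enzyme", y = "flux",
                  fill = "scaled control") +
    ggplot2::theme_minimal()
}

#' Heatmap of scaled elasticities
#' @param object an `stm_elasticities`
#' @param ... unused
#' @method autoplot stm_elasticities
#' @export
autoplot.stm_elasticities <- function(object, ...) {
  df <- tidy.stm_elasticities(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metabolite, y = .data$reaction,
                                   fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::labs(fill = "scaled elasticity") +
    ggplot2::theme_minimal()
}

#' Spectral density lines per metabolite
#' @param object an `stm_spectra`
#' @param ... unused
#' @method autoplot stm_spectra
#' @export
autoplot.stm_spectra <- function(object, ...) {
  mets <- dimnames(object$S_c)[[1]]
  df <- dplyr::bind_rows(lapply(seq_along(mets), function(i) {
    tibble::tibble(metabolite = mets[i], omega = object$omega,
                   density = Re(object$S_c[i, i, ]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omega, y = .data$density,
                                   colour = .data$metabolite)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (1/s)", y = "spectral density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
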
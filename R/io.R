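# Tab-separated network tables, SBtab quantity tables, JSON state round-trip
# and long-format TSV exports. All tables are UTF-8, tab-separated, '.'
# decimal, with explicit headers.

#' Read a network from a TSV reaction table
#'
#' Expected columns: `reaction` (id), `formula` (sum formula such as
#' `"2 A + B <=> C"`), and optionally `regulation` (comma-separated signed
#' metabolites, e.g. `"+ M1, - M2"` for an activator and an inhibitor;
#' an optional leading integer gives the molecularity).
#'
#' @param path file path
#' @param external character vector of external metabolite ids.
#' @return an `stm_network`
#' @export
load_network_tsv <- function(path, external = character()) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  if (!all(c("reaction", "formula") %in% names(tab))) {
    stop("network table needs columns 'reaction' and 'formula' (", path, ")")
  }
  parsed <- lapply(seq_len(nrow(tab)), function(k) {
    p <- try(parse_sum_formula(tab$formula[k]), silent = TRUE)
    if (inherits(p, "try-error")) {
      stop("cannot parse formula in row ", k, " of ", path, ": ", tab$formula[k])
    }
    p
  })
  mets <- unique(unlist(lapply(parsed, function(p) names(p))))
  N <- matrix(0, length(mets), nrow(tab), dimnames = list(mets, tab$reaction))
  for (k in seq_along(parsed)) N[names(parsed[[k]]), k] <- parsed[[k]]
  reg <- NULL
  if ("regulation" %in% names(tab)) {
    reg <- dplyr::bind_rows(lapply(seq_len(nrow(tab)), function(k) {
      parse_regulation_string(tab$regulation[k], tab$reaction[k])
    }))
  }
  stm_network(N, external = external, regulation = reg)
}

# "2 A + B <=> C" -> named stoichiometric coefficients
parse_sum_formula <- function(s) {
  sides <- strsplit(s, "<=>|<->|=|->", perl = TRUE)[[1]]
  if (length(sides) != 2) stop("formula must have two sides: ", s)
  term <- function(side, sgn) {
    parts <- strsplit(side, "\\+")[[1]]
    parts <- trimws(parts)
    parts <- parts[parts != ""]
    out <- numeric(0)
    for (p in parts) {
      m <- regmatches(p, regexec("^([0-9.]+)?\\s*(\\S+)$", p))[[1]]
      if (length(m) < 3 || m[3] == "") stop("bad term: ", p)
      coef <- if (m[2] == "") 1 else as.numeric(m[2])
      prev <- if (m[3] %in% names(out)) out[[m[3]]] else 0
      out[m[3]] <- prev + sgn * coef
    }
    out
  }
  lhs <- term(sides[1], -1)
  rhs <- term(sides[2], 1)
  all <- unique(c(names(lhs), names(rhs)))
  res <- stats::setNames(numeric(length(all)), all)
  res[names(lhs)] <- res[names(lhs)] + lhs
  res[names(rhs)] <- res[names(rhs)] + rhs
  res[res != 0]
}

parse_regulation_string <- function(s, reaction) {
  if (is.na(s) || !nzchar(trimws(s))) return(NULL)
  parts <- trimws(strsplit(s, ",")[[1]])
  rows <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([+-])\\s*([0-9.]+)?\\s*(\\S+)$", p))[[1]]
    if (length(m) < 4) stop("bad regulation term: ", p)
    tibble::tibble(reaction = reaction, metabolite = m[4],
                   kind = if (m[2] == "+") "activator" else "inhibitor",
                   molecularity = if (m[3] == "") 1 else as.numeric(m[3]))
  })
  dplyr::bind_rows(rows)
}

#' Write a network to a TSV reaction table
#' @param net an `stm_network`, `path` file path
#' @param path output file
#' @export
save_network_tsv <- function(net, path) {
  formula_of <- function(l) {
    n <- net$stoich[, l]
    side <- function(idx) {
      paste(vapply(idx, function(i) {
        coef <- abs(n[i])
        if (coef == 1) net$metabolites[i]
        else paste(format(coef), net$metabolites[i])
      }, character(1)), collapse = " + ")
    }
    paste(side(which(n < 0)), "<=>", side(which(n > 0)))
  }
  reg_of <- function(rxn) {
    rr <- net$regulation[net$regulation$reaction == rxn, ]
    if (!nrow(rr)) return("")
    paste(ifelse(rr$kind == "activator", "+ ", "- "),
          ifelse(rr$molecularity == 1, "", paste0(rr$molecularity, " ")),
          rr$metabolite, sep = "", collapse = ", ")
  }
  tab <- tibble::tibble(
    reaction = net$reactions,
    formula = vapply(seq_along(net$reactions), formula_of, character(1)),
    regulation = vapply(net$reactions, reg_of, character(1))
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a reference state from an SBtab quantity table
#'
#' Accepts `!!SBtab` tables of TableType `Quantity` with columns
#' `!QuantityType`, `!Compound`/`!Reaction`, `!Value`. Recognised quantity
#' types: `concentration` (mM), `flux` (mM/s), `equilibrium constant`
#' (dimensionless; stored as its logarithm), `reaction affinity` (kJ/mol,
#' checked against the computed forces when present).
#'
#' @param path file path
#' @param net the network the state belongs to
#' @param RT thermal energy (kJ/mol) used to convert reaction affinities.
#' @return an `stm_state`
#' @export
load_state_sbtab <- function(path, net, RT = 2.479) {
  lines <- readLines(path, warn = FALSE)
  is_head <- grepl("^!!SBtab", lines)
  if (!any(is_head)) stop("not an SBtab file (missing !!SBtab header): ", path)
  body <- lines[!is_head]
  tab <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(tab) <- sub("^!", "", names(tab))
  qt <- tolower(tab$QuantityType)
  val <- as.numeric(tab$Value)
  pick <- function(type, key, ids) {
    rows <- which(qt == type)
    out <- stats::setNames(rep(NA_real_, length(ids)), ids)
    out[tab[[key]][rows]] <- val[rows]
    out
  }
  cc <- pick("concentration", "Compound", net$metabolites)
  v <- pick("flux", "Reaction", net$reactions)
  keq <- pick("equilibrium constant", "Reaction", net$reactions)
  if (anyNA(cc)) stop("missing concentrations for: ",
                      paste(names(cc)[is.na(cc)], collapse = ", "))
  if (anyNA(v)) stop("missing fluxes")
  if (anyNA(keq)) stop("missing equilibrium constants")
  st <- stm_state(net, cc, v, log(keq), check = FALSE)
  if ("reaction affinity" %in% qt) {
    aff <- pick("reaction affinity", "Reaction", net$reactions)
    ok <- !is.na(aff)
    if (any(abs(aff[ok] / RT - st$theta[ok]) > 1e-6)) {
      warning("reaction affinities in file disagree with computed forces")
    }
  }
  st
}

#' Write a reference state as an SBtab quantity table
#' @param state an `stm_state`, `net` its network, `path` file path
#' @param net network
#' @param path output file
#' @param RT thermal energy (kJ/mol) for the affinity rows.
#' @export
save_state_sbtab <- function(state, net, path, RT = 2.479) {
  rows <- dplyr::bind_rows(
    tibble::tibble(QuantityType = "concentration", Compound = net$metabolites,
                   Reaction = "", Value = unname(state$c)),
    tibble::tibble(QuantityType = "flux", Compound = "",
                   Reaction = net$reactions, Value = unname(state$v)),
    tibble::tibble(QuantityType = "equilibrium constant", Compound = "",
                   Reaction = net$reactions, Value = exp(unname(state$ln_keq))),
    tibble::tibble(QuantityType = "reaction affinity", Compound = "",
                   Reaction = net$reactions, Value = RT * unname(state$theta))
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("!!SBtab TableID='State' TableType='Quantity' ",
                    "Document='stmkin' SBtabVersion='1.0'"), con)
  writeLines(paste(c("!QuantityType", "!Compound", "!Reaction", "!Value"),
                   collapse = "\t"), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' JSON round-trip of a reference state
#' @param state an `stm_state`
#' @return JSON string
#' @export
state_to_json <- function(state) {
  jsonlite::toJSON(list(c = as.list(state$c), v = as.list(state$v),
                        ln_keq = as.list(state$ln_keq),
                        growth_rate = state$growth_rate),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname state_to_json
#' @param json JSON string produced by [state_to_json()]
#' @param net the network
#' @export
state_from_json <- function(json, net) {
  x <- jsonlite::fromJSON(json)
  stm_state(net, unlist(x$c), unlist(x$v), unlist(x$ln_keq),
            growth_rate = x$growth_rate, check = FALSE)
}

#' Export a labelled matrix as TSV (row label column + named columns)
#' @param M matrix with dimnames, `path` file path, `row_label` header for
#'   the label column.
#' @param path output file
#' @param row_label name of the first column
#' @export
export_matrix_tsv <- function(M, path, row_label = "row") {
  df <- tibble::as_tibble(M, rownames = row_label)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Export a 3-d tensor in long format (reaction, i, j, value)
#' @param A 3-d array with dimnames, `path` file path
#' @param path output file
#' @export
export_tensor_tsv <- function(A, path) {
  dn <- dimnames(A)
  df <- expand.grid(reaction = dn[[1]], met_i = dn[[2]], met_j = dn[[3]],
                    stringsAsFactors = FALSE)
  df$value <- as.numeric(A)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Export spectra in long format (omega, i, j, re, im)
#' @param spectra an `stm_spectra`
#' @param path output file
#' @param which "S_c" or "S_v"
#' @export
export_spectra_tsv <- function(spectra, path, which = c("S_c", "S_v")) {
  which <- match.arg(which)
  S <- spectra[[which]]
  dn <- dimnames(S)
  grid <- expand.grid(i = dn[[1]], j = dn[[2]],
                      omega = spectra$omega, stringsAsFactors = FALSE)
  vals <- aperm(S, c(1, 2, 3))
  grid$re <- as.numeric(Re(vals))
  grid$im <- as.numeric(Im(vals))
  readr::write_tsv(tibble::as_tibble(grid[c("omega", "i", "j", "re", "im")]),
                   path, progress = FALSE)
  invisible(path)
}
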
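# Minimal SBML Level 3 reader/writer built on xml2. Covers the subset used
# here: species with boundaryCondition (-> external mask), reactions with
# reactant/product stoichiometries, modifiers with SBO terms (activator
# SBO:0000459, inhibitor SBO:0000020), local parameters, and kinetic-law
# MathML generated from R expression trees for the modular rate laws.

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Read a metabolic network from an SBML file
#'
#' Maps `boundaryCondition="true"` species to external metabolites and
#' modifier species to regulation edges via their SBO terms
#' (459 = activator, 20 = inhibitor; unannotated modifiers are ignored with
#' a warning).
#'
#' @param path SBML file path
#' @return an `stm_network`
#' @export
load_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp)) stop("no species found in ", path)
  met_ids <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rx)) stop("no reactions found in ", path)
  rxn_ids <- xml2::xml_attr(rx, "id")
  N <- matrix(0, length(met_ids), length(rx),
              dimnames = list(met_ids, rxn_ids))
  reg_rows <- list()
  for (k in seq_along(rx)) {
    refs <- function(tag, sgn) {
      nodes <- xml2::xml_find_all(rx[[k]], paste0("./", tag, "/speciesReference"))
      for (nd in nodes) {
        sid <- xml2::xml_attr(nd, "species")
        st <- xml2::xml_attr(nd, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (!sid %in% met_ids) stop("reaction ", rxn_ids[k],
                                    " references unknown species ", sid)
        N[sid, k] <<- N[sid, k] + sgn * st
      }
    }
    refs("listOfReactants", -1)
    refs("listOfProducts", 1)
    mods <- xml2::xml_find_all(rx[[k]], "./listOfModifiers/modifierSpeciesReference")
    for (nd in mods) {
      sid <- xml2::xml_attr(nd, "species")
      sbo <- xml2::xml_attr(nd, "sboTerm")
      kind <- if (identical(sbo, "SBO:0000459")) "activator"
              else if (identical(sbo, "SBO:0000020")) "inhibitor"
              else { warning("modifier without recognised SBO term ignored: ",
                             sid, " in ", rxn_ids[k]); next }
      reg_rows[[length(reg_rows) + 1]] <-
        tibble::tibble(reaction = rxn_ids[k], metabolite = sid,
                       kind = kind, molecularity = 1)
    }
  }
  reg <- if (length(reg_rows)) dplyr::bind_rows(reg_rows) else NULL
  stm_network(N, external = met_ids[boundary], regulation = reg)
}

# --- expression -> MathML ---------------------------------------------------

expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(paste0("<cn>", format(e, digits = 15), "</cn>"))
  if (is.name(e)) return(paste0("<ci>", as.character(e), "</ci>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    args <- lapply(as.list(e)[-1], expr_to_mathml)
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power",
                  stop("unsupported operator in kinetic law: ", op))
    return(paste0("<apply><", tag, "/>", paste(unlist(args), collapse = ""),
                  "</apply>"))
  }
  stop("cannot serialise kinetic-law term of class ", class(e)[1])
}

# rate-law expression for one reaction of a kinetic model, with parameter and
# species identifiers as symbols
rate_law_expression <- function(model, l) {
  net <- model$network
  mol <- molecularity_matrices(net)
  reg <- regulation_matrices(net)
  sym <- function(x) as.name(x)
  pow <- function(b, p) if (p == 1) b else call("^", b, p)
  prod_terms <- function(terms) Reduce(function(a, b) call("*", a, b), terms)
  idx <- which((mol$m_S + mol$m_P)[l, ] > 0)
  ratio <- function(i) call("/", sym(net$metabolites[i]),
                            sym(paste0("kM_", net$metabolites[i])))
  fwd <- c(list(sym("kcat_plus")),
           lapply(idx[mol$m_S[l, idx] > 0],
                  function(i) pow(ratio(i), mol$m_S[l, i])))
  bwd <- c(list(sym("kcat_minus")),
           lapply(idx[mol$m_P[l, idx] > 0],
                  function(i) pow(ratio(i), mol$m_P[l, i])))
  numer <- call("-", prod_terms(fwd), prod_terms(bwd))
  one_plus <- function(i) call("+", 1, ratio(i))
  denom <- switch(model$law[l],
    ma = 1,
    sm = prod_terms(lapply(idx, function(i)
      pow(one_plus(i), mol$m_S[l, i] + mol$m_P[l, i]))),
    cm = {
      psi_p <- prod_terms(c(list(1), lapply(idx[mol$m_S[l, idx] > 0], function(i)
        pow(one_plus(i), mol$m_S[l, i]))))
      psi_m <- prod_terms(c(list(1), lapply(idx[mol$m_P[l, idx] > 0], function(i)
        pow(one_plus(i), mol$m_P[l, i]))))
      call("-", call("+", psi_p, psi_m), 1)
    })
  expr <- call("*", sym("enzyme"), call("/", numer, denom))
  ia <- which(reg$m_A[l, ] > 0); ii <- which(reg$m_I[l, ] > 0)
  for (i in ia) {
    met <- net$metabolites[i]
    expr <- call("*", expr, pow(call("/", sym(met),
                                     call("+", sym(met), sym(paste0("kA_", met)))),
                                reg$m_A[l, i]))
  }
  for (i in ii) {
    met <- net$metabolites[i]
    expr <- call("*", expr, pow(call("/", sym(paste0("kI_", met)),
                                     call("+", sym(met), sym(paste0("kI_", met)))),
                                reg$m_I[l, i]))
  }
  expr
}

#' Write a kinetic model (or bare network) as SBML Level 3
#'
#' Species carry `boundaryCondition` flags; reactions carry stoichiometries,
#' modifiers with SBO terms, and — when a kinetic model is given — a kinetic
#' law with explicit MathML for the modular rate law plus local parameters
#' (kcat, kM, kA, kI, enzyme level).
#'
#' @param x an `stm_kinetic_model` or `stm_network`
#' @param path output file
#' @param model_id SBML model id
#' @export
save_model_sbml <- function(x, path, model_id = "stmkin_model") {
  if (inherits(x, "stm_kinetic_model")) { model <- x; net <- x$network }
  else { model <- NULL; net <- x }
  esc <- function(s) gsub("&", "&amp;", s)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="2">', SBML_NS),
    sprintf('  <model id="%s">', esc(model_id)),
    '    <listOfCompartments>',
    '      <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>'
  )
  for (i in seq_along(net$metabolites)) {
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="cell" initialConcentration="%s" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>',
      net$metabolites[i],
      if (!is.null(model)) format(model$state$c[i], digits = 15) else "1",
      if (net$external[i]) "true" else "false"))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfReactions>')
  for (l in seq_along(net$reactions)) {
    n <- net$stoich[, l]
    lines <- c(lines, sprintf('      <reaction id="%s" reversible="true">',
                              net$reactions[l]))
    refs <- function(idx, tag) {
      if (!length(idx)) return(character(0))
      c(sprintf('        <%s>', tag),
        sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                net$metabolites[idx], format(abs(n[idx]))),
        sprintf('        </%s>', tag))
    }
    lines <- c(lines, refs(which(n < 0), "listOfReactants"),
               refs(which(n > 0), "listOfProducts"))
    rr <- net$regulation[net$regulation$reaction == net$reactions[l], ]
    if (nrow(rr)) {
      lines <- c(lines, '        <listOfModifiers>',
                 sprintf('          <modifierSpeciesReference species="%s" sboTerm="%s"/>',
                         rr$metabolite,
                         ifelse(rr$kind == "activator", "SBO:0000459", "SBO:0000020")),
                 '        </listOfModifiers>')
    }
    if (!is.null(model)) {
      expr <- rate_law_expression(model, l)
      pars <- c(kcat_plus = model$k_cat_plus[l],
                kcat_minus = model$k_cat_minus[l],
                enzyme = model$e[l])
      for (i in which(!is.na(model$k_M[l, ]))) {
        pars[paste0("kM_", net$metabolites[i])] <- model$k_M[l, i]
      }
      for (i in which(!is.na(model$k_A[l, ]))) {
        pars[paste0("kA_", net$metabolites[i])] <- model$k_A[l, i]
      }
      for (i in which(!is.na(model$k_I[l, ]))) {
        pars[paste0("kI_", net$metabolites[i])] <- model$k_I[l, i]
      }
      lines <- c(lines,
        '        <kineticLaw>',
        sprintf('          <math xmlns="%s">', MATHML_NS),
        paste0('            ', expr_to_mathml(expr)),
        '          </math>',
        '          <listOfLocalParameters>',
        sprintf('            <localParameter id="%s" value="%s"/>',
                names(pars), vapply(pars, format, character(1), digits = 15)),
        '          </listOfLocalParameters>',
        '        </kineticLaw>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  # validate well-formedness
  invisible(xml2::read_xml(path))
  invisible(path)
}
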
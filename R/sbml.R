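# Flat SBML L3V2 export of the assembled ODE system. The model is encoded
# as species (amounts) governed by rate rules, with the algebraic
# intermediates (concentrations, reaction fluxes, RTG) as assignment-rule
# parameters -- the same symbolic definitions that drive the solver.

# recursive R-expression -> MathML (subset: arithmetic, names, numbers, max)
.to_mathml <- function(e) {
  if (is.numeric(e)) return(sprintf("<cn> %.12g </cn>", e))
  if (is.name(e)) return(sprintf("<ci> %s </ci>", as.character(e)))
  if (!is.call(e)) stop("cannot translate expression element: ",
                        deparse(e), call. = FALSE)
  op <- as.character(e[[1]])
  args <- as.list(e)[-1]
  if (op == "(") return(.to_mathml(args[[1]]))
  tags <- c("+" = "plus", "-" = "minus", "*" = "times", "/" = "divide",
            "^" = "power")
  if (op %in% names(tags)) {
    inner <- paste(vapply(args, .to_mathml, character(1)), collapse = " ")
    return(sprintf("<apply> <%s/> %s </apply>", tags[[op]], inner))
  }
  if (op == "max" && length(args) == 2L) {
    a <- .to_mathml(args[[1]]); b <- .to_mathml(args[[2]])
    return(sprintf(paste0(
      "<piecewise> <piece> %s <apply> <gt/> %s %s </apply> </piece> ",
      "<otherwise> %s </otherwise> </piecewise>"), a, a, b, b))
  }
  stop("operator not supported in SBML export: ", op, call. = FALSE)
}

.mathml_of <- function(expr_string) {
  sprintf('<math xmlns="http://www.w3.org/1998/Math/MathML"> %s </math>',
          .to_mathml(str2lang(expr_string)))
}

#' Export a scenario's ODE system as flat SBML
#'
#' Produces a single (non-hierarchical) SBML Level 3 Version 2 document:
#' one compartment per organ, one species per model state (amounts, umol),
#' every model parameter as a constant, the algebraic intermediates
#' (including the renal glucose threshold `RTG`) as assignment rules and
#' every state derivative as a rate rule. Doses at t = 0 are encoded as
#' initial amounts; later dose events are not representable in a flat
#' export and raise an error.
#'
#' @param sc A `dapa_scenario`.
#' @param path Optional output path; the document is written when given.
#' @return An `xml2::xml_document`, invisibly when `path` is given.
#' @export
export_sbml <- function(sc, path = NULL) {
  stopifnot(inherits(sc, "dapa_scenario"))
  dose_times <- vapply(sc$doses, `[[`, numeric(1), "time_h")
  if (any(dose_times > 0))
    stop("flat SBML export encodes doses as initial amounts; ",
         "all dose events must be at t = 0", call. = FALSE)
  p <- ode_parameter_vector(sc$physiology, sc$drug, sc$pd)
  eq <- .ode_equations()
  rules <- c(eq$derivs, eq$quadrature)  # UGE is a rate rule in the export
  species_ids <- names(rules)
  y0 <- stats::setNames(numeric(length(species_ids)), species_ids)
  for (d in sc$doses) y0 <- .apply_dose(y0, d, sc$drug)
  comp_of <- c(DAP_lumen = "gut_lumen", DAP_feces_transit = "gut_lumen",
               DAP_feces = "feces", DAP_gu = "gut", DAP_li = "liver",
               DAP_ki = "kidney", DAP_lu = "lung", DAP_re = "rest",
               DAP_bl = "blood", DAP_urine = "urine", D3G_bl = "blood",
               D3G_ki = "kidney", D3G_urine = "urine", UGE_mmol = "urine")
  vols <- c(gut_lumen = 1, feces = 1, urine = 1,
            gut = p[["Vgu"]], liver = p[["Vli"]], kidney = p[["Vki"]],
            lung = p[["Vlu"]], rest = p[["Vre"]], blood = p[["Vbl"]])
  compartments <- paste(sprintf(
    '      <compartment id="%s" size="%.12g" constant="true" spatialDimensions="3"/>',
    names(vols), vols), collapse = "\n")
  species <- paste(sprintf(
    paste0('      <species id="%s" compartment="%s" initialAmount="%.12g"',
           ' hasOnlySubstanceUnits="true" boundaryCondition="false"',
           ' constant="false"/>'),
    species_ids, comp_of[species_ids], y0), collapse = "\n")
  parameters <- paste(sprintf(
    '      <parameter id="%s" value="%.12g" constant="true"/>',
    names(p), p), collapse = "\n")
  aux_params <- paste(sprintf(
    '      <parameter id="%s" constant="false"/>',
    names(eq$aux)), collapse = "\n")
  assignment_rules <- paste(vapply(names(eq$aux), function(nm) sprintf(
    '      <assignmentRule variable="%s">\n        %s\n      </assignmentRule>',
    nm, .mathml_of(eq$aux[[nm]])), character(1)), collapse = "\n")
  rate_rules <- paste(vapply(names(rules), function(nm) sprintf(
    '      <rateRule variable="%s">\n        %s\n      </rateRule>',
    nm, .mathml_of(rules[[nm]])), character(1)), collapse = "\n")
  doc_str <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2">\n',
    sprintf('  <model id="%s" name="%s" timeUnits="hour">\n',
            gsub("[^A-Za-z0-9_]", "_", sc$label), sc$label),
    "    <listOfCompartments>\n", compartments, "\n    </listOfCompartments>\n",
    "    <listOfSpecies>\n", species, "\n    </listOfSpecies>\n",
    "    <listOfParameters>\n", parameters, "\n", aux_params,
    "\n    </listOfParameters>\n",
    "    <listOfRules>\n", assignment_rules, "\n", rate_rules,
    "\n    </listOfRules>\n",
    "  </model>\n</sbml>\n")
  doc <- xml2::read_xml(doc_str)
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}
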
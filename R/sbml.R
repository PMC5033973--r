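# SBML import/export (Level 3 Version 2 core), built on xml2.
#
# Kinetic-law math is emitted as MathML generated from the symbolic
# transcription of each rate law (constants inlined as numbers).  A package
# annotation on each reaction carries the structured kinetics record
# (family, roles, constants) so that a round trip reconstructs the model
# exactly; foreign SBML without the annotation is imported with each
# kinetic law as an opaque expression parsed from its MathML.

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
GLYCO_NS <- "https://glycoMCA.r-pkg/annotation"

# ---- MathML writer -------------------------------------------------------

.mathml_op <- c("+" = "plus", "-" = "minus", "*" = "times",
                "/" = "divide", "^" = "power")

.expr_to_mathml <- function(e) {
  if (is.numeric(e)) {
    return(paste0("<cn type=\"real\">", sprintf("%.17g", e), "</cn>"))
  }
  if (is.name(e)) return(paste0("<ci>", as.character(e), "</ci>"))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (op == "(") return(.expr_to_mathml(e[[2]]))
    if (op %in% names(.mathml_op)) {
      args <- vapply(as.list(e)[-1], .expr_to_mathml, character(1))
      return(paste0("<apply><", .mathml_op[[op]], "/>",
                    paste(args, collapse = ""), "</apply>"))
    }
    stop("cannot serialize operator to MathML: ", op)
  }
  stop("cannot serialize to MathML: ", class(e))
}

# ---- MathML reader -------------------------------------------------------

.mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    return(.mathml_to_expr(kids[[1]]))
  }
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], .mathml_to_expr)
    rop <- names(.mathml_op)[match(op, .mathml_op)]
    if (is.na(rop)) stop("unsupported MathML operator: ", op)
    if (length(args) == 1) {
      if (op != "minus") stop("unary ", op, " not supported")
      return(call("-", args[[1]]))
    }
    e <- call(rop, args[[1]], args[[2]])
    for (a in args[-(1:2)]) e <- call(rop, e, a)
    return(e)
  }
  stop("unsupported MathML node: ", nm)
}

# ---- kinetics (de)serialization -----------------------------------------

.kinetics_to_json <- function(kin) {
  payload <- list(family = kin$family, roles = as.list(kin$roles),
                  constants = kin$constants, isoforms = kin$isoforms,
                  inhibitors = as.list(kin$inhibitors),
                  inhibition = kin$inhibition, mechanism = kin$mechanism,
                  Keq_thermo = kin$Keq_thermo)
  payload <- payload[!vapply(payload, is.null, logical(1))]
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
}

.kinetics_from_json <- function(txt) {
  p <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  to_num <- function(x) if (is.null(x)) NULL else
    lapply(x, function(v) if (is.logical(v)) v else as.numeric(v))
  reaction_kinetics(
    family = p$family,
    roles = unlist(p$roles),
    constants = to_num(p$constants),
    isoforms = if (is.null(p$isoforms)) NULL else
      lapply(p$isoforms, function(i) lapply(i, as.numeric)),
    inhibitors = if (is.null(p$inhibitors)) NULL else
      unlist(lapply(p$inhibitors, as.numeric)),
    inhibition = to_num(p$inhibition),
    mechanism = p$mechanism,
    Keq_thermo = p$Keq_thermo
  )
}

# ---- writer --------------------------------------------------------------

#' Write a model as SBML
#'
#' Emits an SBML Level 3 Version 2 document: compartment, species with
#' initial concentrations (`boundaryCondition` for fixed species),
#' reactions with reactant/product/modifier lists and kinetic laws in
#' MathML, plus a package annotation per reaction carrying the structured
#' kinetics so a round trip is exact.
#'
#' @param model a `glyco_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\" level=\"3\" version=\"2\">", SBML_NS),
    sprintf("<model id=\"%s\" name=\"%s\">",
            gsub("[^A-Za-z0-9_]", "_", model$name), esc(model$name)),
    "<annotation>",
    sprintf("<glycoMCA:model xmlns:glycoMCA=\"%s\">", GLYCO_NS),
    sprintf("<glycoMCA:condition>%s</glycoMCA:condition>", model$condition),
    sprintf("<glycoMCA:fluxReaction>%s</glycoMCA:fluxReaction>",
            model$flux_reaction),
    sprintf("<glycoMCA:units>%s</glycoMCA:units>", esc(model$units)),
    paste0("<glycoMCA:totals>",
           as.character(jsonlite::toJSON(as.list(model$totals),
                                         auto_unbox = TRUE, digits = NA)),
           "</glycoMCA:totals>"),
    "</glycoMCA:model>",
    "</annotation>",
    "<listOfCompartments>",
    "<compartment id=\"cell\" size=\"1\" constant=\"true\"/>",
    "</listOfCompartments>",
    "<listOfSpecies>")
  sp_line <- function(id, conc, boundary) sprintf(
    paste0("<species id=\"%s\" compartment=\"cell\" ",
           "initialConcentration=\"%.17g\" boundaryCondition=\"%s\" ",
           "hasOnlySubstanceUnits=\"false\" constant=\"false\"/>"),
    id, conc, if (boundary) "true" else "false")
  for (s in names(model$initial))
    lines <- c(lines, sp_line(s, model$initial[[s]], FALSE))
  for (s in names(model$fixed))
    lines <- c(lines, sp_line(s, model$fixed[[s]], TRUE))
  lines <- c(lines, "</listOfSpecies>", "<listOfReactions>")
  for (nm in names(model$reactions)) {
    r <- model$reactions[[nm]]
    st <- r$stoich
    reac <- st[st < 0]; prod <- st[st > 0]
    mods <- setdiff(kinetics_species(r$kinetics), names(st))
    lines <- c(lines, sprintf("<reaction id=\"%s\" reversible=\"true\">", nm),
               "<annotation>",
               sprintf(paste0("<glycoMCA:kinetics xmlns:glycoMCA=\"%s\">",
                              "<![CDATA[%s]]></glycoMCA:kinetics>"),
                       GLYCO_NS, .kinetics_to_json(r$kinetics)),
               "</annotation>")
    if (length(reac)) lines <- c(lines, "<listOfReactants>", sprintf(
      "<speciesReference species=\"%s\" stoichiometry=\"%g\" constant=\"true\"/>",
      names(reac), -reac), "</listOfReactants>")
    if (length(prod)) lines <- c(lines, "<listOfProducts>", sprintf(
      "<speciesReference species=\"%s\" stoichiometry=\"%g\" constant=\"true\"/>",
      names(prod), prod), "</listOfProducts>")
    if (length(mods)) lines <- c(lines, "<listOfModifiers>", sprintf(
      "<modifierSpeciesReference species=\"%s\"/>", mods),
      "</listOfModifiers>")
    lines <- c(lines, "<kineticLaw>",
               sprintf("<math xmlns=\"%s\">", MATHML_NS),
               .expr_to_mathml(rate_expression(r$kinetics)),
               "</math>", "</kineticLaw>", "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  # validate well-formedness before writing
  doc <- xml2::read_xml(paste(lines, collapse = "\n"))
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---- reader --------------------------------------------------------------

#' Read a model from SBML
#'
#' Reads an SBML Level 2/3 document with kinetic laws.  Reactions carrying
#' the package's kinetics annotation are reconstructed exactly onto their
#' rate-law families; reactions without it are imported as opaque kinetic
#' laws (the MathML converted to an R expression over species identifiers)
#' with a warning.  Fixed species are honored via `boundaryCondition`.
#'
#' @param path SBML file path.
#' @return a `glyco_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error: ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mnode, "xml_missing")) stop("no <model> element found")

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  ids <- xml2::xml_attr(sp_nodes, "id")
  conc <- as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration"))
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  initial <- stats::setNames(conc[!boundary], ids[!boundary])
  fixed <- stats::setNames(conc[boundary], ids[boundary])

  ann <- function(xpath) {
    n <- xml2::xml_find_first(doc, xpath)
    if (inherits(n, "xml_missing")) NULL else xml2::xml_text(n)
  }
  condition <- ann(".//model/annotation//*[local-name()='condition']")
  flux_reaction <- ann(".//model/annotation//*[local-name()='fluxReaction']")
  units <- ann(".//model/annotation//*[local-name()='units']")
  totals_json <- ann(".//model/annotation//*[local-name()='totals']")
  totals <- if (!is.null(totals_json))
    unlist(jsonlite::fromJSON(totals_json)) else {
      tt <- c(adenylate = sum(initial[c("ATP", "ADP")]),
              nicotinamide = sum(initial[c("NAD", "NADH")]))
      tt[!is.na(tt)]
    }

  reactions <- list()
  for (rn in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    id <- xml2::xml_attr(rn, "id")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      s <- xml2::xml_attr(sr, "species")
      k <- xml2::xml_attr(sr, "stoichiometry")
      st[s] <- -(if (is.na(k)) 1 else as.numeric(k))
    }
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      s <- xml2::xml_attr(sr, "species")
      k <- xml2::xml_attr(sr, "stoichiometry")
      st[s] <- if (is.na(k)) 1 else as.numeric(k)
    }
    kin_json <- xml2::xml_find_first(rn, "./annotation//*[local-name()='kinetics']")
    if (!inherits(kin_json, "xml_missing")) {
      kin <- .kinetics_from_json(xml2::xml_text(kin_json))
    } else {
      math <- xml2::xml_find_first(rn, "./kineticLaw//math")
      if (inherits(math, "xml_missing"))
        stop("reaction ", id, " has no kinetic law")
      expr <- .mathml_to_expr(math)
      # local parameters shadow species symbols
      lp <- xml2::xml_find_all(rn, "./kineticLaw//localParameter")
      lpv <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                             xml2::xml_attr(lp, "id"))
      if (length(lpv)) expr <- do.call(substitute, list(expr, as.list(lpv)))
      warning("reaction ", id,
              ": no kinetics annotation; imported as opaque rate law")
      kin <- structure(list(family = "opaque", expr = expr,
                            roles = character(0),
                            constants = list(Vmf = 1)),
                       class = "reaction_kinetics")
    }
    reactions[[id]] <- list(name = id, stoich = st, kinetics = kin)
  }

  structure(list(
    name = xml2::xml_attr(mnode, "name") %||% xml2::xml_attr(mnode, "id"),
    condition = condition %||% "AS30D",
    initial = initial,
    fixed = fixed,
    totals = totals,
    reactions = reactions,
    flux_reaction = flux_reaction %||% "LDH",
    units = units %||% "model units"
  ), class = "glyco_model")
}
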
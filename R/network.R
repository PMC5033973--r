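# Model assembly: species, stoichiometry, conserved moieties, scenarios
#
# Species name canon (all concentrations in mM):
#   Glc_out, Glc_in  extra-/intracellular glucose
#   Glc6P, Fru6P, FBP (Fru1,6BP), DHAP, G3P (glyceraldehyde-3-phosphate),
#   BPG (1,3-bisphosphoglycerate), PG3 (3-phosphoglycerate),
#   PG2 (2-phosphoglycerate), PEP, Pyr, Lac_in, Lac_out
#   ATP, ADP, NAD, NADH, Pi
#   fixed modulators: Ery4P, PG6 (6-phosphogluconate), F26BP (Fru2,6BP),
#   CIT (citrate), GLY (glycogen pool, HeLa supply)

MODEL_CONDITIONS <- c("AS30D", "HeLa_hyper", "HeLa_normo", "HeLa_hypo")

#' Build a glycolysis model from a parameter source
#'
#' Assembles a validated model definition (species, stoichiometry, fixed
#' species, conserved moiety totals, reaction kinetics) for one cell
#' line/condition.  The parameter source is a structured YAML file (or an
#' already-parsed list) with one record per reaction: rate-law family,
#' stoichiometry, ligand-role bindings and kinetic constants.  Reverse
#' maximal velocities of reversible steps may be omitted, in which case they
#' are derived from the Haldane relationship so every reaction is
#' thermodynamically consistent by construction.
#'
#' @param condition one of `AS30D`, `HeLa_hyper`, `HeLa_normo`, `HeLa_hypo`;
#'   must agree with the `condition` field of the parameter source.
#' @param parameter_source path to a YAML parameter file, or a parsed list.
#' @return an object of class `glyco_model`.
#' @export
build_model <- function(condition, parameter_source) {
  condition <- match.arg(condition, MODEL_CONDITIONS)
  src <- if (is.character(parameter_source)) {
    yaml::read_yaml(parameter_source)
  } else parameter_source
  if (!identical(src$condition, condition))
    stop("parameter source is for condition ", src$condition,
         ", not ", condition)

  fixed <- unlist(src$fixed)
  initial <- unlist(src$initial)
  totals <- unlist(src$totals)

  reactions <- list()
  for (nm in names(src$reactions)) {
    rec <- src$reactions[[nm]]
    kin <- tryCatch(
      reaction_kinetics(
        family = rec$family,
        roles = rec$roles,
        constants = rec$constants,
        isoforms = rec$isoforms,
        inhibitors = rec$inhibitors,
        inhibition = rec$inhibition,
        mechanism = rec$mechanism,
        Keq_thermo = rec$Keq_thermo
      ),
      error = function(e) stop("reaction ", nm, ": ", conditionMessage(e),
                               call. = FALSE))
    reactions[[nm]] <- list(name = nm, stoich = unlist(rec$stoich),
                            kinetics = kin)
  }

  model <- structure(list(
    name = src$name %||% condition,
    condition = condition,
    initial = initial,
    fixed = fixed,
    totals = totals,
    reactions = reactions,
    flux_reaction = src$flux_reaction %||%
      if (condition == "AS30D") "LDH" else "MCT",
    units = src$units %||% "nmol/min/mg protein; mM"
  ), class = "glyco_model")

  issues <- validate_model(model)
  if (length(issues$errors))
    stop("invalid model definition:\n  ",
         paste(issues$errors, collapse = "\n  "))
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a packaged synthetic reference model
#'
#' Reads one of the synthetic reference parameter sets shipped with the
#' package (`inst/extdata/params_*_synthetic.yaml`).  These stand in for a
#' full experimental parameterization: every constant the source study
#' prints is used verbatim, the remainder are physiological literature-scale
#' values, and all equilibrium constants are fixed thermodynamic values.
#'
#' @param condition one of `AS30D`, `HeLa_hyper`, `HeLa_normo`, `HeLa_hypo`.
#' @return a `glyco_model`.
#' @export
reference_model <- function(condition = MODEL_CONDITIONS) {
  condition <- match.arg(condition)
  file <- system.file("extdata",
                      sprintf("params_%s_synthetic.yaml", tolower(condition)),
                      package = "glycoMCA", mustWork = TRUE)
  build_model(condition, file)
}

#' Species referenced by a kinetics record
#' @param kin a `reaction_kinetics`.
#' @return character vector of species names.
#' @keywords internal
kinetics_species <- function(kin) {
  unique(c(unname(kin$roles), names(kin$inhibitors)))
}

#' Model species, free species and stoichiometric matrix
#'
#' @param model a `glyco_model`.
#' @param free_only if `TRUE` (default), rows are restricted to free
#'   (non-boundary) species.
#' @return numeric matrix, species x reactions.
#' @export
stoich_matrix <- function(model, free_only = TRUE) {
  species <- names(model$initial)
  if (!free_only) species <- c(species, names(model$fixed))
  N <- matrix(0, length(species), length(model$reactions),
              dimnames = list(species, names(model$reactions)))
  for (nm in names(model$reactions)) {
    st <- model$reactions[[nm]]$stoich
    keep <- intersect(names(st), species)
    N[keep, nm] <- st[keep]
  }
  N
}

#' Conserved-moiety matrix
#'
#' Returns the matrix of conservation relations declared by the model's
#' moiety totals (rows: moieties, columns: free species), e.g. ATP+ADP and
#' NAD+NADH.
#'
#' @param model a `glyco_model`.
#' @return numeric matrix, moieties x free species.
#' @export
moiety_matrix <- function(model) {
  species <- names(model$initial)
  pools <- list(adenylate = c("ATP", "ADP"), nicotinamide = c("NAD", "NADH"))
  pools <- pools[names(pools) %in% names(model$totals)]
  G <- matrix(0, length(pools), length(species),
              dimnames = list(names(pools), species))
  for (p in names(pools)) G[p, intersect(pools[[p]], species)] <- 1
  G
}

#' Evaluate all reaction rates at a state
#'
#' @param model a `glyco_model`.
#' @param conc named concentrations of the free species (mM); fixed species
#'   are appended automatically.
#' @param clamp clamp transient negative concentrations at zero.
#' @return named numeric vector of rates, one per reaction.
#' @export
model_rates <- function(model, conc, clamp = FALSE) {
  full <- c(conc, model$fixed)
  vapply(model$reactions,
         function(r) eval_rate(r$kinetics, full, clamp = clamp),
         numeric(1))
}

#' Time derivatives of the free species
#' @inheritParams model_rates
#' @return named numeric vector dS/dt (mM per time unit).
#' @export
model_dsdt <- function(model, conc, clamp = TRUE) {
  N <- stoich_matrix(model)
  drop(N %*% model_rates(model, conc, clamp = clamp))
}

#' Feedback-inhibition scenario
#'
#' Constructs the scenario labels of the feedback-toggle experiment:
#' which of HK, HPI, TPI and GAPDH keep their Fru1,6BP/DHAP inhibition
#' terms.  Scenario letters follow the in-silico experiment: (a) no enzyme,
#' (b) HPI only, (c) HK only, (d) HPI+HK, (e) HPI+HK+TPI+GAPDH (the full,
#' unmodified model).
#'
#' @param scenario a letter `"a"`..`"e"`, or a character vector of enzyme
#'   names to keep inhibited (subset of HK, HPI, TPI, GAPDH).
#' @return character vector of enzymes with feedback enabled.
#' @export
feedback_scenario <- function(scenario) {
  if (length(scenario) == 1 && scenario %in% letters[1:5]) {
    switch(scenario,
           a = character(0),
           b = "HPI",
           c = "HK",
           d = c("HPI", "HK"),
           e = c("HPI", "HK", "TPI", "GAPDH"))
  } else {
    bad <- setdiff(scenario, c("HK", "HPI", "TPI", "GAPDH"))
    if (length(bad)) stop("unknown feedback enzymes: ",
                          paste(bad, collapse = ", "))
    scenario
  }
}

#' Apply a feedback-inhibition scenario
#'
#' Returns a copy of the model in which the Fru1,6BP/DHAP inhibition terms
#' are removed (term deletion, not a large Ki) from every enzyme *not*
#' listed in the scenario.  All other kinetics are unchanged.
#'
#' @param model a `glyco_model` (AS-30D shaped: HK/HPI/TPI/GAPDH present).
#' @param scenario scenario letter or enzyme vector, see
#'   [feedback_scenario()].
#' @return modified `glyco_model`.
#' @export
apply_feedback_scenario <- function(model, scenario) {
  keep <- feedback_scenario(scenario)
  targets <- c("HK", "HPI", "TPI", "GAPDH")
  missing <- setdiff(targets, names(model$reactions))
  if (length(missing))
    stop("model lacks feedback-scenario reactions: ",
         paste(missing, collapse = ", "))
  for (enz in setdiff(targets, keep)) {
    kin <- model$reactions[[enz]]$kinetics
    if (kin$family == "hpi_multi_inhib") {
      kin$inhibitors <- kin$inhibitors[
        !names(kin$inhibitors) %in% c("FBP", "DHAP")]
      if (!length(kin$inhibitors)) kin$inhibitors <- NULL
    } else if ("I" %in% names(kin$roles) &&
               kin$roles[["I"]] %in% c("FBP", "DHAP")) {
      kin$roles <- kin$roles[names(kin$roles) != "I"]
      kin$inhibition <- NULL
    }
    model$reactions[[enz]]$kinetics <- kin
  }
  model
}

#' Scale an enzyme's activity
#'
#' Multiplies the forward (and, when present, reverse) maximal velocity of
#' one or more reactions by a common factor, emulating titration of enzyme
#' amount.  Equilibrium constants are untouched, so thermodynamics (and the
#' Haldane residual) are preserved exactly.
#'
#' @param model a `glyco_model`.
#' @param enzyme reaction name(s).
#' @param factor positive scalar.
#' @return modified `glyco_model`.
#' @export
scale_enzyme_activity <- function(model, enzyme, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("activity factor must be a single value > 0")
  for (enz in enzyme) {
    if (!enz %in% names(model$reactions))
      stop("no reaction named ", enz, " in model ", model$name)
    ct <- model$reactions[[enz]]$kinetics$constants
    for (v in intersect(c("Vmf", "Vmr", "Vm"), names(ct)))
      ct[[v]] <- ct[[v]] * factor
    model$reactions[[enz]]$kinetics$constants <- ct
  }
  model
}

#' Validate a model definition
#'
#' Report-only diagnostics: undeclared species referenced by kinetics,
#' moiety-conservation structure (declared pools must lie in the left null
#' space of the stoichiometric matrix), initial pool sizes versus declared
#' totals, and per-reaction Haldane residuals.
#'
#' @param model a `glyco_model`.
#' @return list with `errors` (character), `warnings` (character) and
#'   `haldane` (named residuals for reversible steps).
#' @export
validate_model <- function(model) {
  errors <- character(0); warnings <- character(0)
  declared <- c(names(model$initial), names(model$fixed))
  for (nm in names(model$reactions)) {
    r <- model$reactions[[nm]]
    und <- setdiff(c(names(r$stoich), kinetics_species(r$kinetics)), declared)
    if (length(und))
      errors <- c(errors, paste0(nm, ": undeclared species ",
                                 paste(und, collapse = ", ")))
  }
  # moiety conservation: G N = 0
  N <- stoich_matrix(model)
  G <- moiety_matrix(model)
  if (nrow(G)) {
    drift <- G %*% N
    bad <- rownames(drift)[apply(abs(drift) > 1e-12, 1, any)]
    if (length(bad))
      errors <- c(errors, paste0("moiety not conserved by stoichiometry: ",
                                 paste(bad, collapse = ", ")))
    pools <- drop(G %*% model$initial[colnames(G)])
    for (p in names(pools))
      if (abs(pools[p] - model$totals[p]) > 1e-8)
        warnings <- c(warnings, paste0(
          "initial ", p, " pool (", signif(pools[p], 6),
          ") differs from declared total (", model$totals[p], ")"))
  }
  haldane <- vapply(model$reactions, function(r) {
    if (is.null(r$kinetics$Keq_thermo)) return(NA_real_)
    haldane_residual(r$kinetics, r$kinetics$Keq_thermo)
  }, numeric(1))
  big <- names(haldane)[!is.na(haldane) & haldane > 1e-6]
  if (length(big))
    warnings <- c(warnings, paste0("Haldane residual > 1e-6 for: ",
                                   paste(big, collapse = ", ")))
  unref <- setdiff(names(model$fixed),
                   unique(unlist(lapply(model$reactions, function(r)
                     c(names(r$stoich), kinetics_species(r$kinetics))))))
  if (length(unref))
    warnings <- c(warnings, paste0("unreferenced fixed species: ",
                                   paste(unref, collapse = ", ")))
  list(errors = errors, warnings = warnings, haldane = haldane)
}

#' @export
print.glyco_model <- function(x, ...) {
  cat("<glyco_model>", x$name, sprintf("(%s)\n", x$condition))
  cat("  free species:", length(x$initial),
      " fixed:", length(x$fixed),
      " reactions:", length(x$reactions), "\n")
  cat("  reactions:", paste(names(x$reactions), collapse = ", "), "\n")
  cat("  moiety totals:",
      paste(sprintf("%s=%g mM", names(x$totals), x$totals), collapse = ", "),
      "\n")
  cat("  pathway flux reaction:", x$flux_reaction, "\n")
  invisible(x)
}
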
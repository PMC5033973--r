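# Metabolic control analysis
#
# Two independent routes to the same quantities:
#  * control_coefficients(): perturb each enzyme's Vmf (and Vmr) by a small
#    factor, re-solve the steady state, central log-differences;
#  * mca_matrix_method(): structural MCA from the stoichiometry and the
#    elasticity matrix at the reference steady state (summation theorems
#    hold to machine precision by construction).
# Agreement between the two is itself a test of the implementation.

#' Flux and concentration control coefficients by finite differences
#'
#' For each reaction i, scales the enzyme activity (Vmf and Vmr jointly) by
#' (1 +/- delta), re-solves the steady state, and returns the flux control
#' coefficient C^J_i = d ln J / d ln e_i and the concentration control
#' coefficients C^S_i = d ln S / d ln e_i for the requested metabolites,
#' by central differences in log space.
#'
#' @param model a `glyco_model`.
#' @param metabolites species whose concentration control is reported.
#' @param delta relative perturbation (0 < delta <= 0.05); default 0.01.
#' @param ss optional pre-computed reference `glyco_steady_state`.
#' @param enzymes reactions to perturb (default: all).
#' @param tol,t_max steady-state solver controls passed to
#'   [steady_state()] for the perturbed models.
#' @return object of class `glyco_control`: `CJ` (named vector), `CS`
#'   (matrix enzymes x metabolites), summation-theorem residuals, the
#'   perturbation used and the reference state.  Enzymes whose perturbed
#'   model fails to converge carry `NA` coefficients.
#' @export
control_coefficients <- function(model, metabolites = c("FBP", "DHAP"),
                                 delta = 0.01, ss = NULL, enzymes = NULL,
                                 tol = 1e-9, t_max = 1e6) {
  stopifnot(delta > 0, delta <= 0.05)
  if (is.null(ss)) ss <- steady_state(model, tol = tol, t_max = t_max)
  if (!ss$converged) stop("reference model has no converged steady state")
  if (is.null(enzymes)) enzymes <- names(model$reactions)
  metabolites <- intersect(metabolites, names(ss$concentrations))

  CJ <- stats::setNames(rep(NA_real_, length(enzymes)), enzymes)
  CS <- matrix(NA_real_, length(enzymes), length(metabolites),
               dimnames = list(enzymes, metabolites))
  dln_e <- log(1 + delta) - log(1 - delta)
  for (enz in enzymes) {
    up <- steady_state(scale_enzyme_activity(model, enz, 1 + delta),
                       warm_start = ss, tol = tol, t_max = t_max)
    dn <- steady_state(scale_enzyme_activity(model, enz, 1 - delta),
                       warm_start = ss, tol = tol, t_max = t_max)
    if (!up$converged || !dn$converged) next
    if (up$pathway_flux > 0 && dn$pathway_flux > 0)
      CJ[enz] <- (log(up$pathway_flux) - log(dn$pathway_flux)) / dln_e
    cu <- up$concentrations[metabolites]; cd <- dn$concentrations[metabolites]
    ok <- cu > 0 & cd > 0
    CS[enz, ok] <- (log(cu[ok]) - log(cd[ok])) / dln_e
  }
  structure(list(
    enzymes = enzymes, CJ = CJ, CS = CS, delta = delta,
    method = "finite-difference",
    sum_CJ = sum(CJ, na.rm = TRUE),
    sum_CS = colSums(CS, na.rm = TRUE),
    reference = ss
  ), class = "glyco_control")
}

#' Scaled elasticity matrix
#'
#' Local sensitivities eps[i, s] = (dv_i/dS) (S / v_i) of every rate law to
#' every free species, by central differences at fixed other species.  For
#' reactions with near-zero rate the unscaled derivative dv/dS is reported
#' instead and flagged.
#'
#' @param model a `glyco_model`.
#' @param state named concentrations (e.g. a steady state's
#'   `concentrations`).
#' @param rel relative perturbation for the central difference.
#' @param scaled return scaled (default) or unscaled elasticities.
#' @return matrix reactions x free species; attribute `unscaled_rows` names
#'   reactions reported unscaled because their rate is ~0.
#' @export
elasticities <- function(model, state, rel = 1e-6, scaled = TRUE) {
  species <- names(model$initial)
  v0 <- model_rates(model, state[species])
  E <- matrix(0, length(v0), length(species),
              dimnames = list(names(v0), species))
  for (s in species) {
    h <- rel * max(state[[s]], 1e-6)
    up <- state; up[s] <- up[s] + h
    dn <- state; dn[s] <- max(dn[s] - h, 0)
    dv <- (model_rates(model, up[species]) -
             model_rates(model, dn[species])) / (up[[s]] - dn[[s]])
    E[, s] <- dv
  }
  if (!scaled) return(E)
  tiny <- abs(v0) < 1e-9 * max(abs(v0))
  Es <- E * outer(1 / ifelse(tiny, 1, v0), state[species])
  attr(Es, "unscaled_rows") <- names(v0)[tiny]
  Es
}

#' Control coefficients by the structural matrix method
#'
#' Computes the unscaled concentration-control matrix
#' Gamma = -L (N_R E L)^{-1} N_R and the flux-control matrix
#' C = I + E Gamma from the reduced stoichiometry N_R, the link matrix L
#' (conserved moieties eliminated) and the unscaled elasticity matrix E at
#' the steady state, then scales by fluxes and concentrations.  The
#' summation theorems hold by construction, so this route is the structural
#' oracle for the finite-difference coefficients.
#'
#' @param model a `glyco_model`.
#' @param metabolites species whose concentration control is reported.
#' @param ss optional pre-computed reference `glyco_steady_state`.
#' @return a `glyco_control` (same shape as [control_coefficients()]).
#' @export
mca_matrix_method <- function(model, metabolites = c("FBP", "DHAP"),
                              ss = NULL) {
  if (is.null(ss)) ss <- steady_state(model)
  if (!ss$converged) stop("model has no converged steady state")
  N <- stoich_matrix(model)
  species <- rownames(N)
  state <- ss$concentrations[species]

  # reduced system: drop one dependent row per conserved moiety
  sets <- .reduced_sets(model)
  Nr <- N[sets$ind, , drop = FALSE]
  # link matrix L: full species rows as linear combinations of independent
  # rows; dependent pool species have coefficient -1 against their partner
  L <- matrix(0, length(species), length(sets$ind),
              dimnames = list(species, sets$ind))
  L[sets$ind, sets$ind] <- diag(length(sets$ind))
  if ("ADP" %in% sets$dep) L["ADP", "ATP"] <- -1
  if ("NADH" %in% sets$dep) L["NADH", "NAD"] <- -1

  E <- elasticities(model, state, scaled = FALSE)   # reactions x species
  M <- Nr %*% E %*% L
  qrM <- qr(M)
  if (qrM$rank < nrow(M)) {
    null_dirs <- sets$ind[abs(diag(qr.R(qrM))) < 1e-10]
    stop("singular reduced Jacobian; redundant/conserved directions near: ",
         paste(null_dirs, collapse = ", "))
  }
  Gamma <- -L %*% solve(M, Nr)                      # species x reactions
  Cu <- diag(length(ss$fluxes)) + E %*% Gamma       # reactions x reactions
  v <- ss$fluxes
  metabolites <- intersect(metabolites, species)
  CS <- t(t(Gamma[metabolites, , drop = FALSE]) * v) /
    state[metabolites]
  # scaled coefficients are undefined for extinct metabolites/fluxes
  CS[state[metabolites] < 1e-12, ] <- NA_real_
  iflux <- model$flux_reaction
  CJ <- if (abs(v[[iflux]]) > 1e-9 * max(abs(v), 1e-300))
    Cu[iflux, ] * v / v[[iflux]] else
    stats::setNames(rep(NA_real_, length(v)), names(v))
  structure(list(
    enzymes = names(v), CJ = CJ, CS = t(CS), delta = 0,
    method = "matrix",
    sum_CJ = sum(CJ), sum_CS = colSums(t(CS)),
    reference = ss
  ), class = "glyco_control")
}

#' @export
print.glyco_control <- function(x, ...) {
  cat("<glyco_control>", x$method,
      if (x$delta > 0) sprintf("(delta = %g)", x$delta), "\n")
  tab <- cbind(CJ = round(x$CJ, 4), round(x$CS, 4))
  print(tab)
  cat(sprintf("  sum C^J = %.4f;  sum C^S = %s\n", x$sum_CJ,
              paste(sprintf("%s: %.4f", names(x$sum_CS), x$sum_CS),
                    collapse = ", ")))
  invisible(x)
}

#' Control coefficients as a printed-precision table
#'
#' Returns the concentration-control matrix rounded the way such tables are
#' usually printed (2 significant figures), alongside the unrounded values.
#'
#' @param cc a `glyco_control`.
#' @return data.frame with enzyme, metabolite, value, printed.
#' @export
control_table <- function(cc) {
  df <- expand.grid(enzyme = rownames(cc$CS), metabolite = colnames(cc$CS),
                    stringsAsFactors = FALSE)
  df$value <- mapply(function(e, m) cc$CS[e, m], df$enzyme, df$metabolite)
  df$printed <- signif(df$value, 2)
  df
}
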
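# Synthetic kinetic parameter sets and noisy observation tables.
#
# Equilibrium constants are physical constants and are never sampled; the
# sampler draws binding constants and maximal velocities and then closes
# every reversible reaction through the Haldane relationship, so random
# models are thermodynamically consistent by construction.

#' Parameter prior for the synthetic model sampler
#'
#' Log-uniform ranges per constant class.  Defaults span physiological
#' ranges: binding and inhibition constants 0.01-10 mM, maximal velocities
#' 1-1000 flux units, allosteric transition constant 1-1e6, interaction
#' factors 0.1-10.
#'
#' @param km_range,ki_range,vmax_range,L_range,alpha_range two-element
#'   positive ranges sampled log-uniformly.
#' @return list of class `glyco_prior`.
#' @export
parameter_prior <- function(km_range = c(0.01, 10),
                            ki_range = c(0.01, 10),
                            vmax_range = c(1, 1000),
                            L_range = c(1, 1e6),
                            alpha_range = c(0.1, 10)) {
  ranges <- list(km = km_range, ki = ki_range, vmax = vmax_range,
                 L = L_range, alpha = alpha_range)
  for (r in ranges) stopifnot(length(r) == 2, all(r > 0), r[1] <= r[2])
  structure(ranges, class = "glyco_prior")
}

.runif_log <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Sample a random glycolysis model from a prior
#'
#' Starts from the condition's reference model structure (species,
#' stoichiometry, fixed species, moiety totals, equilibrium constants) and
#' redraws all binding/inhibition constants, maximal velocities and
#' interaction factors from the prior.  Reverse maximal velocities are then
#' set from the Haldane relationship, so every reversible reaction in the
#' sampled model is thermodynamically consistent (residual 0 by
#' construction).  Same seed, same model.
#'
#' @param prior a `glyco_prior`.
#' @param condition model condition (see [build_model()]).
#' @param seed integer seed for reproducibility.
#' @return a `glyco_model`.
#' @export
sample_model <- function(prior = parameter_prior(), condition = "AS30D",
                         seed = 1) {
  set.seed(seed)
  model <- reference_model(condition)
  # auxiliary closure steps (ATP demand, mitochondrial drains, glycogen
  # supply) define the cellular context and keep their reference kinetics;
  # the prior expresses uncertainty in the glycolytic enzymes proper
  aux <- c("ATPase", "PYRox", "NADHox", "GLYdeg")
  for (nm in setdiff(names(model$reactions), aux)) {
    kin <- model$reactions[[nm]]$kinetics
    ct <- kin$constants
    for (cn in names(ct)) {
      if (cn %in% c("Keq", "cross_terms")) next
      if (cn %in% c("Vmf", "Vmr", "Vm")) {
        if (cn != "Vmr") ct[[cn]] <- .runif_log(1, prior$vmax)
      } else if (cn == "L") {
        ct[[cn]] <- .runif_log(1, prior$L)
      } else if (cn %in% c("alpha", "alpha1", "alpha2", "beta")) {
        ct[[cn]] <- .runif_log(1, prior$alpha)
      } else if (grepl("^K", cn)) {
        ct[[cn]] <- .runif_log(1, prior$km)
      }
    }
    kin$constants <- ct
    if (!is.null(kin$isoforms)) {
      for (i in seq_along(kin$isoforms)) {
        for (cn in setdiff(names(kin$isoforms[[i]]), "f"))
          kin$isoforms[[i]][[cn]] <- .runif_log(1, prior$km)
      }
    }
    if (length(kin$inhibitors))
      kin$inhibitors[] <- .runif_log(length(kin$inhibitors), prior$ki)
    if (!is.null(kin$inhibition)) {
      kin$inhibition$Ki <- .runif_log(1, prior$ki)
      if (!is.null(kin$inhibition$alpha))
        kin$inhibition$alpha <- .runif_log(1, prior$alpha)
      if (!is.null(kin$inhibition$alpha2))
        kin$inhibition$alpha2 <- .runif_log(1, prior$alpha)
    }
    # thermodynamic closure: Keq values are physical constants, Vmr follows
    if (!is.null(kin$Keq_thermo)) {
      vmr <- haldane_vmr(kin, kin$Keq_thermo)
      if (!is.na(vmr)) kin$constants$Vmr <- vmr
    }
    model$reactions[[nm]]$kinetics <- kin
  }
  model$name <- sprintf("%s_synthetic_seed%d", condition, seed)
  model
}

#' Simulate noisy steady-state observation tables
#'
#' For each treatment (a named list of enzyme-activity scaling maps,
#' emulating inhibitor incubations), solves the steady state and draws
#' `n_reps` replicates of each readout under multiplicative lognormal noise
#' with the given coefficient of variation, then reports mean, sd and n per
#' metabolite — the shape of an experimental metabolite table.
#'
#' @param model a `glyco_model`.
#' @param treatments named list; each element is a named numeric vector of
#'   activity factors (empty vector = untreated control).
#' @param noise_cv coefficient of variation of the multiplicative noise,
#'   in [0, 1].
#' @param n_reps replicates per treatment (>= 1).
#' @param seed integer seed.
#' @param readouts metabolites (plus `"flux"`) to report.
#' @return a `glyco_observations` table; treatments whose model does not
#'   converge are omitted and listed in the `failed` attribute.
#' @export
simulate_observations <- function(model,
                                  treatments = list(control = numeric(0)),
                                  noise_cv = 0.3, n_reps = 3, seed = 1,
                                  readouts = c("FBP", "DHAP", "ATP",
                                               "Glc6P", "Fru6P", "flux")) {
  stopifnot(noise_cv >= 0, noise_cv <= 1, n_reps >= 1)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- list(); failed <- character(0)
  for (trt in names(treatments)) {
    m <- model
    fac <- treatments[[trt]]
    for (enz in names(fac)) m <- scale_enzyme_activity(m, enz, fac[[enz]])
    ss <- steady_state(m)
    if (!ss$converged) { failed <- c(failed, trt); next }
    truth <- c(ss$concentrations[intersect(readouts,
                                           names(ss$concentrations))],
               if ("flux" %in% readouts) c(flux = ss$pathway_flux))
    for (met in names(truth)) {
      reps <- truth[[met]] * stats::rlnorm(n_reps, -sdlog^2 / 2, sdlog)
      rows[[length(rows) + 1]] <- data.frame(
        metabolite = met, treatment = trt, mean = mean(reps),
        sd = if (n_reps > 1) stats::sd(reps) else 0, n = n_reps,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite = character(0), treatment = character(0),
               mean = numeric(0), sd = numeric(0), n = numeric(0),
               stringsAsFactors = FALSE)
  class(out) <- c("glyco_observations", class(out))
  attr(out, "failed") <- failed
  out
}

#' Recover a joint enzyme-activity scaling factor from observations
#'
#' One-dimensional search for the activity factor of the target enzymes
#' that minimizes the squared log-residuals between the model's predicted
#' steady-state readouts and the observed means — the inverse of the
#' titration experiment.
#'
#' @param model the generating `glyco_model` (untreated parameterization).
#' @param observed a `glyco_observations` table for a single treatment.
#' @param target_enzymes enzymes assumed to have been scaled jointly.
#' @param interval search interval for the factor.
#' @return list: `factor` (estimate), `objective` (residual at optimum),
#'   `flat` flag (TRUE when the objective is insensitive to the factor).
#' @export
recover_activity_factor <- function(model, observed,
                                    target_enzymes = c("ENO", "PYK"),
                                    interval = c(0.05, 1.4)) {
  obs <- stats::setNames(observed$mean, observed$metabolite)
  obs <- obs[obs > 0]
  warm <- steady_state(model)
  objective <- function(f) {
    ss <- steady_state(scale_enzyme_activity(model, target_enzymes, f),
                       warm_start = warm)
    if (!ss$converged) return(1e6)
    warm <<- ss
    pred <- c(ss$concentrations, flux = ss$pathway_flux)
    keep <- intersect(names(obs), names(pred))
    sum((log(pred[keep]) - log(obs[keep]))^2)
  }
  opt <- stats::optimize(objective, interval = interval, tol = 1e-4)
  probe <- objective(min(interval) * 1.5)
  flat <- abs(probe - opt$objective) < 1e-10
  list(factor = opt$minimum, objective = opt$objective, flat = flat)
}
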
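# In-silico experiment drivers: enzyme titrations, feedback-scenario
# comparisons, inhibition-mechanism/Ki scans, and model-vs-measurement
# comparison.

.scan_readouts <- c("FBP", "DHAP", "ATP", "Glc6P", "Fru6P")

#' Titrate enzyme activity and record steady-state responses
#'
#' Scales the activity (Vmf and Vmr jointly) of one or more enzymes by each
#' factor in turn — when several enzymes are listed the identical factor is
#' applied to all simultaneously — re-solves the steady state (warm-started
#' from the previous point) and records pathway flux and key metabolite
#' concentrations.  The reference (factor 1) row is always included.
#'
#' @param model a `glyco_model`.
#' @param enzymes reaction name(s) to titrate jointly.
#' @param factors activity factors in (0, 1.5]; 1 = reference activity.
#' @param scenario_tag optional label copied into every row.
#' @return data.frame of class `glyco_scan`: factor, scenario, flux,
#'   one column per readout metabolite, converged flag.
#' @export
titration_scan <- function(model, enzymes, factors = seq(1, 0.1, by = -0.1),
                           scenario_tag = NA_character_) {
  stopifnot(length(enzymes) >= 1, all(factors > 0), all(factors <= 1.5))
  factors <- sort(unique(c(1, factors)), decreasing = TRUE)
  ref <- steady_state(model)
  rows <- vector("list", length(factors))
  warm <- ref
  readouts <- intersect(.scan_readouts, names(model$initial))
  for (i in seq_along(factors)) {
    m <- scale_enzyme_activity(model, enzymes, factors[i])
    ss <- steady_state(m, warm_start = warm)
    if (ss$converged) warm <- ss
    row <- data.frame(factor = factors[i], scenario = scenario_tag,
                      flux = ss$pathway_flux, converged = ss$converged,
                      stringsAsFactors = FALSE)
    for (r in readouts) row[[r]] <- unname(ss$concentrations[r])
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("glyco_scan", class(out))
  out
}

#' Feedback-scenario titration experiment
#'
#' Runs [titration_scan()] of ENO+PYK (by default) under each
#' feedback-inhibition scenario: (a) no Fru1,6BP/DHAP inhibition anywhere,
#' (b) on HPI only, (c) on HK only, (d) on HPI+HK, (e) the full model.
#' Without any feedback the titration still accumulates Fru1,6BP and DHAP
#' but leaves pathway flux and ATP essentially unchanged; with feedback on
#' the flux-controlling steps, flux and ATP fall.
#'
#' @param model an AS-30D shaped `glyco_model`.
#' @param scenarios subset of letters a-e.
#' @param enzymes enzymes titrated jointly (default ENO and PYK).
#' @param factors activity factors.
#' @return `glyco_scan` data.frame with a `scenario` column.
#' @export
scenario_experiment <- function(model, scenarios = letters[1:5],
                                enzymes = c("ENO", "PYK"),
                                factors = seq(1, 0.2, by = -0.2)) {
  out <- lapply(scenarios, function(sc) {
    m <- apply_feedback_scenario(model, sc)
    titration_scan(m, enzymes, factors, scenario_tag = sc)
  })
  res <- do.call(rbind, out)
  class(res) <- c("glyco_scan", class(res))
  res
}

# replace the HPI mechanism and scale its inhibition constants
.set_hpi_mechanism <- function(model, mechanism, ki_scale, alpha = 2,
                               inhibitors = NULL) {
  kin <- model$reactions[["HPI"]]$kinetics
  if (is.null(inhibitors)) inhibitors <- names(kin$inhibitors)
  kin$mechanism <- mechanism
  if (mechanism == "mixed") kin$constants$alpha <- alpha
  kin$inhibitors[inhibitors] <- kin$inhibitors[inhibitors] * ki_scale
  model$reactions[["HPI"]]$kinetics <- kin
  model
}

#' Inhibition-mechanism / Ki scan on HPI
#'
#' Jointly rescales the HPI inhibition constants (Ery4P, Fru1,6BP and 6PG;
#' DHAP is excluded as an HPI inhibitor here) by each factor of a
#' logarithmic grid, under a chosen inhibition mechanism (competitive,
#' uncompetitive, or mixed with interaction factor `alpha`), and records
#' steady-state pathway flux, Glc6P, and the HPI flux-control coefficient
#' (computed with the same finite-difference operator as
#' [control_coefficients()]).  Scale 1 is the experimentally anchored
#' reference.
#'
#' @param model a HeLa-shaped `glyco_model` (default use: hypoglycemia).
#' @param mechanism `competitive`, `uncompetitive` or `mixed`.
#' @param ki_scale numeric grid of joint Ki multipliers; default
#'   logarithmic over [0.01, 100] with 25 points.
#' @param alpha interaction factor for the mixed mechanism.
#' @param delta finite-difference perturbation for the control coefficient.
#' @return `glyco_scan` data.frame: ki_scale, mechanism, flux, Glc6P,
#'   CJ_HPI, converged.
#' @export
ki_scan <- function(model, mechanism = c("competitive", "uncompetitive",
                                         "mixed"),
                    ki_scale = 10^seq(-2, 2, length.out = 25),
                    alpha = 2, delta = 0.01) {
  mechanism <- match.arg(mechanism)
  ki_scale <- sort(ki_scale)
  # march outward from scale 1 so warm starts stay near the attractor
  order_idx <- order(abs(log10(ki_scale)))
  ref <- steady_state(model)
  rows <- vector("list", length(ki_scale))
  warm <- ref
  for (i in order_idx) {
    m <- .set_hpi_mechanism(model, mechanism, ki_scale[i], alpha = alpha)
    ss <- steady_state(m, warm_start = warm)
    if (ss$converged) warm <- ss
    cj <- NA_real_
    if (ss$converged) {
      cc <- control_coefficients(m, metabolites = "Glc6P", delta = delta,
                                 ss = ss, enzymes = "HPI")
      cj <- unname(cc$CJ["HPI"])
    }
    rows[[i]] <- data.frame(ki_scale = ki_scale[i], mechanism = mechanism,
                            flux = ss$pathway_flux,
                            Glc6P = unname(ss$concentrations["Glc6P"]),
                            CJ_HPI = cj, converged = ss$converged,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[order(ki_scale)])
  class(out) <- c("glyco_scan", class(out))
  out
}

#' Build an observation table
#'
#' Container for experimental-style readouts: per metabolite/flux and
#' treatment, a mean, standard deviation and number of preparations.
#'
#' @param metabolite character vector.
#' @param treatment character vector (e.g. `control`, `oxamate_20`).
#' @param mean,sd,n numeric vectors (sd >= 0, n >= 1).
#' @return data.frame of class `glyco_observations`.
#' @export
observation_table <- function(metabolite, treatment, mean, sd, n) {
  stopifnot(all(sd >= 0), all(n >= 1))
  out <- data.frame(metabolite = metabolite, treatment = treatment,
                    mean = mean, sd = sd, n = n, stringsAsFactors = FALSE)
  class(out) <- c("glyco_observations", class(out))
  out
}

# Welch two-sample t-test from summary statistics
.welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2 || (s1 == 0 && s2 == 0))
    return(list(statistic = NA_real_, df = NA_real_, p.value = NA_real_))
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  list(statistic = t, df = df,
       p.value = 2 * stats::pt(-abs(t), df))
}

#' Compare model predictions with observed metabolite tables
#'
#' For each metabolite present in both inputs: predicted value, observed
#' mean +/- sd, the prediction's z-score under the observed spread, the
#' fold-change of each treatment relative to the control observations, and
#' a Welch two-sample t-test (from summary statistics) of treatment vs
#' control.
#'
#' @param predicted named numeric vector of model predictions (same units
#'   as the observations), e.g. a row of a titration scan.
#' @param observed a `glyco_observations` table.
#' @param treatment treatment label to compare (default: all non-control).
#' @param control label of the control rows.
#' @return data.frame with one row per (metabolite, treatment); metabolites
#'   present on only one side are listed in the `unmatched` attribute.
#' @export
compare_observations <- function(predicted, observed,
                                 treatment = NULL, control = "control") {
  obs <- observed[observed$treatment != control, , drop = FALSE]
  if (!is.null(treatment)) obs <- obs[obs$treatment %in% treatment, ]
  ctrl <- observed[observed$treatment == control, , drop = FALSE]
  matched <- intersect(names(predicted), obs$metabolite)
  rows <- lapply(seq_len(nrow(obs)), function(i) {
    met <- obs$metabolite[i]
    if (!met %in% matched) return(NULL)
    pred <- unname(predicted[met])
    z <- if (obs$sd[i] > 0) (pred - obs$mean[i]) / obs$sd[i] else
      ifelse(pred == obs$mean[i], 0, Inf)
    ci <- ctrl[ctrl$metabolite == met, , drop = FALSE]
    fold <- tt <- NA_real_
    if (nrow(ci) == 1) {
      fold <- obs$mean[i] / ci$mean[1]
      w <- .welch_from_summary(obs$mean[i], obs$sd[i], obs$n[i],
                               ci$mean[1], ci$sd[1], ci$n[1])
      tt <- w$p.value
    }
    data.frame(metabolite = met, treatment = obs$treatment[i],
               predicted = pred, observed_mean = obs$mean[i],
               observed_sd = obs$sd[i], n = obs$n[i], z = z,
               fold_change_vs_control = fold, p_value_vs_control = tt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "unmatched") <- setdiff(obs$metabolite, names(predicted))
  out
}
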
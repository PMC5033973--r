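# Rate-law families
#
# Every enzyme/transporter step in the glycolysis models is evaluated by one
# of the family functions below.  Concentrations are in mM; rates are in the
# units of Vmax in the parameter record (nmol/min/mg protein for the shipped
# reference sets).  Ligand roles (A/B/C/P/Q/S/I...) are bound by species
# *name*, never by position, so the rate seen by the integrator cannot
# depend on the order in which a reaction's participants are written down.

RATE_FAMILIES <- c(
  "transporter_rev_mm", "hk_random_bibi", "hpi_multi_inhib", "pfk1_mwc",
  "aldo_unibi", "uni_uni_rev_mm", "gapdh_terbi", "random_bibi", "mm_irrev"
)

INHIBITION_MECHANISMS <- c("competitive", "uncompetitive", "mixed")

#' Construct a reaction kinetics record
#'
#' Bundles a rate-law family identifier with its named kinetic constants and
#' ligand-role bindings.  The record is validated eagerly: a missing constant
#' or a non-positive binding constant is an error at construction time, not
#' at the first integrator step.
#'
#' @param family one of `transporter_rev_mm`, `hk_random_bibi`,
#'   `hpi_multi_inhib`, `pfk1_mwc`, `aldo_unibi`, `uni_uni_rev_mm`,
#'   `gapdh_terbi`, `random_bibi`, `mm_irrev`.
#' @param roles named character vector mapping ligand roles (e.g. `A`, `B`,
#'   `P`, `Q`, `S`, `I`) to species names.
#' @param constants named list of kinetic constants (`Vmf`, `Vmr`, `Keq`,
#'   `Ka`..`Kq`, `alpha`, `beta`, `L`, ...); units mM for binding constants,
#'   flux units for maximal velocities.
#' @param isoforms optional list of per-isoform overrides, each a list with a
#'   fraction `f` (summing to 1 over isoforms) and Km overrides.
#' @param inhibitors optional named numeric vector of inhibition constants
#'   `Ki` keyed by inhibitor species (multi-inhibitor families).
#' @param inhibition optional list with `Ki` and interaction factor(s) for
#'   single-inhibitor mixed-type terms (`alpha`, or `alpha2` for hexokinase).
#' @param mechanism for `hpi_multi_inhib`: `competitive`, `uncompetitive` or
#'   `mixed`; mixed requires `alpha` in `constants`.
#' @param Keq_thermo optional thermodynamic equilibrium constant
#'   (concentration scale).  When given and `Vmr` is absent from
#'   `constants`, the reverse maximal velocity is derived from the Haldane
#'   relationship, making the reaction thermodynamically consistent by
#'   construction.
#' @return an object of class `reaction_kinetics`.
#' @export
reaction_kinetics <- function(family, roles, constants, isoforms = NULL,
                              inhibitors = NULL, inhibition = NULL,
                              mechanism = NULL, Keq_thermo = NULL) {
  family <- match.arg(family, RATE_FAMILIES)
  k <- structure(
    list(family = family, roles = unlist(roles), constants = constants,
         isoforms = isoforms, inhibitors = unlist(inhibitors),
         inhibition = inhibition, mechanism = mechanism,
         Keq_thermo = Keq_thermo),
    class = "reaction_kinetics")
  if (!is.null(Keq_thermo) && is.null(k$constants$Vmr)) {
    capable <- c("hpi_multi_inhib", "uni_uni_rev_mm", "aldo_unibi",
                 "gapdh_terbi", "random_bibi")
    if (!family %in% capable)
      stop("Keq_thermo given but family ", family,
           " has no Vmr parameterization")
    vmr <- haldane_vmr(k, Keq_thermo)
    # NA here means a constant is missing; let validation name it
    if (!is.na(vmr)) k$constants$Vmr <- vmr
  }
  validate_kinetics(k)
  k
}

# required top-level constants per family (isoform-level handled separately)
.family_required <- list(
  transporter_rev_mm = c("Vmf", "Keq"),
  hk_random_bibi     = c("Vmf", "Keq", "Kb", "Kp", "Kq", "alpha1"),
  hpi_multi_inhib    = c("Vmf", "Vmr", "Ks", "Kp"),
  pfk1_mwc           = c("Vm", "KATP", "KFru6P", "L", "KaF26BP", "KiCIT",
                         "KiATP", "alpha", "beta", "KADP", "KFBP", "Keq"),
  aldo_unibi         = c("Vmf", "Vmr", "Ks", "Kp1", "Kp2"),
  uni_uni_rev_mm     = c("Vmf", "Vmr", "Ks", "Kp"),
  gapdh_terbi        = c("Vmf", "Vmr", "Ka", "Kb", "Kc", "Kp", "Kq"),
  random_bibi        = c("Vmf", "Ka", "Kb", "Kp", "Kq", "alpha", "beta"),
  mm_irrev           = c("Vmf", "Ks")
)

#' Validate a reaction kinetics record
#'
#' Checks that all constants the family requires are present, that binding
#' constants are positive, maximal velocities non-negative, isoform
#' fractions sum to one, and that a mixed inhibition mechanism carries its
#' interaction factor.
#'
#' @param k a `reaction_kinetics` object.
#' @return `k`, invisibly; errors name the offending constant.
#' @export
validate_kinetics <- function(k) {
  stopifnot(inherits(k, "reaction_kinetics"))
  req <- .family_required[[k$family]]
  have <- names(k$constants)
  # isoform-carrying families hold some constants per isoform
  if (!is.null(k$isoforms)) {
    iso_keys <- unique(unlist(lapply(k$isoforms, names)))
    req <- setdiff(req, iso_keys)
    f <- vapply(k$isoforms, function(i) i$f, numeric(1))
    if (abs(sum(f) - 1) > 1e-9)
      stop("isoform fractions must sum to 1 (got ", sum(f), ")")
    for (iso in k$isoforms)
      for (nm in setdiff(names(iso), "f"))
        if (!is.numeric(iso[[nm]]) || iso[[nm]] <= 0)
          stop("isoform constant ", nm, " must be > 0")
  } else if (k$family == "transporter_rev_mm") {
    req <- c(req, "Ks", "Kp")
  } else if (k$family == "hk_random_bibi") {
    req <- c(req, "Ka")
  }
  miss <- setdiff(req, have)
  if (length(miss))
    stop("missing kinetic constant(s) for family ", k$family, ": ",
         paste(miss, collapse = ", "))
  for (nm in have) {
    val <- k$constants[[nm]]
    if (nm == "cross_terms") {
      if (!is.logical(val)) stop("cross_terms must be TRUE/FALSE")
      next
    }
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val))
      stop("constant ", nm, " must be a finite scalar")
    if (grepl("^K", nm) && val <= 0)
      stop("binding constant ", nm, " must be > 0 (got ", val, ")")
    if (nm %in% c("Vmf", "Vmr", "Vm") && val < 0)
      stop("maximal velocity ", nm, " must be >= 0")
    if (nm == "L" && val < 0) stop("allosteric constant L must be >= 0")
    if (nm %in% c("alpha", "alpha1", "alpha2", "beta") && val <= 0)
      stop("interaction factor ", nm, " must be > 0")
  }
  if (!is.null(k$inhibitors) && any(k$inhibitors <= 0))
    stop("inhibition constants must be > 0")
  if (!is.null(k$inhibition)) {
    if (is.null(k$inhibition$Ki) || k$inhibition$Ki <= 0)
      stop("inhibition requires Ki > 0")
  }
  if (identical(k$mechanism, "mixed") && is.null(k$constants$alpha))
    stop("mixed-type inhibition requires interaction factor alpha")
  invisible(k)
}

# concentration lookup with a clear error on missing species
.cc <- function(conc, sp) {
  v <- conc[sp]
  if (anyNA(v))
    stop("species not present in state: ",
         paste(sp[is.na(v)], collapse = ", "))
  unname(v)
}

#' Evaluate a rate law
#'
#' Dispatches on the kinetics family and returns the net rate (flux units)
#' at the given concentration state.
#'
#' @param k a `reaction_kinetics` object.
#' @param conc named numeric vector of concentrations (mM); must contain
#'   every species the law references.
#' @param clamp if `TRUE`, negative concentrations (possible transiently in
#'   stiff integration) are clamped to 0 instead of raising an error.
#' @return net rate, a single number.
#' @export
eval_rate <- function(k, conc, clamp = FALSE) {
  if (any(conc < 0)) {
    if (clamp) conc[conc < 0] <- 0
    else stop("negative concentration in state: ",
              paste(names(conc)[conc < 0], collapse = ", "))
  }
  switch(k$family,
    transporter_rev_mm = .rate_transporter(k, conc),
    hk_random_bibi     = .rate_hk(k, conc),
    hpi_multi_inhib    = .rate_hpi(k, conc),
    pfk1_mwc           = .rate_pfk1(k, conc),
    aldo_unibi         = .rate_aldo(k, conc),
    uni_uni_rev_mm     = .rate_uniuni(k, conc),
    gapdh_terbi        = .rate_gapdh(k, conc),
    random_bibi        = .rate_random_bibi(k, conc),
    mm_irrev           = .rate_mm_irrev(k, conc),
    opaque             = .rate_opaque(k, conc),
    stop("unknown rate-law family: ", k$family))
}

# normalized isoform list: every transporter/HK evaluates over >=1 isoform
.isoforms_of <- function(k, keys) {
  if (!is.null(k$isoforms)) return(k$isoforms)
  iso <- c(list(f = 1), k$constants[keys])
  list(iso)
}

# reversible monosubstrate carrier (Haldane form); sums over isoforms
.rate_transporter <- function(k, conc) {
  S <- .cc(conc, k$roles[["S"]]); P <- .cc(conc, k$roles[["P"]])
  ct <- k$constants
  drive <- S - P / ct$Keq
  v <- 0
  for (iso in .isoforms_of(k, c("Ks", "Kp"))) {
    v <- v + ct$Vmf * iso$f * drive / (iso$Ks * (1 + P / iso$Kp) + S)
  }
  v
}

# random Bi-Bi hexokinase; optional mixed-type inhibition (dead-end EI/EAI)
# and optional isoforms differing in the glucose Km.
.rate_hk <- function(k, conc) {
  A <- .cc(conc, k$roles[["A"]]); B <- .cc(conc, k$roles[["B"]])
  P <- .cc(conc, k$roles[["P"]]); Q <- .cc(conc, k$roles[["Q"]])
  ct <- k$constants
  a1 <- ct$alpha1
  has_I <- "I" %in% names(k$roles) && !is.null(k$inhibition)
  if (has_I) {
    I <- .cc(conc, k$roles[["I"]])
    Ki <- k$inhibition$Ki; a2 <- k$inhibition$alpha2
    if (is.null(a2)) a2 <- 1
  }
  v <- 0
  for (iso in .isoforms_of(k, c("Ka"))) {
    Ka <- iso$Ka
    num <- ct$Vmf * iso$f / (a1 * Ka * ct$Kb) * (A * B - P * Q / ct$Keq)
    den <- 1 + A / Ka + B / ct$Kb + A * B / (a1 * Ka * ct$Kb) +
      P / ct$Kp + Q / ct$Kq + P * Q / (ct$Kp * ct$Kq) +
      A * Q / (Ka * ct$Kq) + P * B / (ct$Kp * ct$Kb)
    if (has_I)
      den <- den + I / Ki + A * I / (a2 * Ka * Ki) +
        A * I * B / (a1 * Ka * ct$Kb * a2 * Ki)
    v <- v + num / den
  }
  v
}

# reversible uni-uni isomerase with a set of dead-end inhibitors acting by a
# competitive, uncompetitive or mixed (shared alpha) mechanism.
.rate_hpi <- function(k, conc) {
  S <- .cc(conc, k$roles[["S"]]); P <- .cc(conc, k$roles[["P"]])
  ct <- k$constants
  Tsum <- 0
  if (length(k$inhibitors))
    Tsum <- sum(.cc(conc, names(k$inhibitors)) / k$inhibitors)
  num <- ct$Vmf * S / ct$Ks - ct$Vmr * P / ct$Kp
  mech <- if (is.null(k$mechanism)) "competitive" else k$mechanism
  den <- switch(mech,
    competitive   = 1 + S / ct$Ks + P / ct$Kp + Tsum,
    uncompetitive = 1 + (S / ct$Ks) * (1 + Tsum) + (P / ct$Kp) * (1 + Tsum),
    mixed         = 1 + Tsum + (S / ct$Ks) * (1 + Tsum / ct$alpha) +
                    (P / ct$Kp) * (1 + Tsum / ct$alpha),
    stop("unknown inhibition mechanism: ", mech))
  num / den
}

# Monod-Wyman-Changeux PFK-1 (tetramer, exclusive binding): Fru2,6BP is a
# mixed-type activator (alpha < 1 lowers the Fru6P K, beta > 1 raises Vm),
# citrate and MgATP are allosteric inhibitors loading the T state; the
# reverse reaction is a simple Michaelis-Menten block.
.rate_pfk1 <- function(k, conc) {
  S  <- .cc(conc, k$roles[["S"]])     # Fru6P
  ATP <- .cc(conc, k$roles[["ATP"]])
  F26 <- .cc(conc, k$roles[["ACT"]])  # Fru2,6BP
  CIT <- .cc(conc, k$roles[["INH"]])
  ADP <- .cc(conc, k$roles[["P1"]])
  FBP <- .cc(conc, k$roles[["P2"]])
  ct <- k$constants
  mm_atp <- (ATP / ct$KATP) / (1 + ATP / ct$KATP)
  act <- (1 + ct$beta * F26 / (ct$alpha * ct$KaF26BP)) /
         (1 + F26 / (ct$alpha * ct$KaF26BP))
  phi <- S * (1 + F26 / (ct$alpha * ct$KaF26BP)) /
         (ct$KFru6P * (1 + F26 / ct$KaF26BP))
  Leff <- ct$L * (1 + CIT / ct$KiCIT)^4 * (1 + ATP / ct$KiATP)^4 /
          (1 + F26 / ct$KaF26BP)^4
  fwd <- mm_atp * act * phi * (1 + phi)^3 / (Leff + (1 + phi)^4)
  rev <- (ADP * FBP / (ct$KADP * ct$KFBP * ct$Keq)) /
         (1 + ADP / ct$KADP + FBP / ct$KFBP + ADP * FBP / (ct$KADP * ct$KFBP))
  ct$Vm * (fwd - rev)
}

# reversible random Uni-Bi aldolase
.rate_aldo <- function(k, conc) {
  S <- .cc(conc, k$roles[["S"]])
  P1 <- .cc(conc, k$roles[["P1"]]); P2 <- .cc(conc, k$roles[["P2"]])
  ct <- k$constants
  num <- ct$Vmf * S / ct$Ks - ct$Vmr * P1 * P2 / (ct$Kp1 * ct$Kp2)
  den <- 1 + S / ct$Ks + P1 / ct$Kp1 + P2 / ct$Kp2 +
    P1 * P2 / (ct$Kp1 * ct$Kp2)
  num / den
}

# reversible uni-uni Michaelis-Menten; optional mixed-type dead-end
# inhibitor with interaction factor alpha on both Ks and Kp.
.rate_uniuni <- function(k, conc) {
  S <- .cc(conc, k$roles[["S"]]); P <- .cc(conc, k$roles[["P"]])
  ct <- k$constants
  num <- ct$Vmf * S / ct$Ks - ct$Vmr * P / ct$Kp
  if ("I" %in% names(k$roles) && !is.null(k$inhibition)) {
    I <- .cc(conc, k$roles[["I"]])
    Ki <- k$inhibition$Ki; a <- k$inhibition$alpha
    Ts <- I / Ki
    den <- 1 + Ts + (S / ct$Ks) * (1 + Ts / a) + (P / ct$Kp) * (1 + Ts / a)
  } else {
    den <- 1 + S / ct$Ks + P / ct$Kp
  }
  num / den
}

# simplified ordered Ter-Bi GAPDH; optional mixed-type Fru1,6BP terms
.rate_gapdh <- function(k, conc) {
  A <- .cc(conc, k$roles[["A"]]); B <- .cc(conc, k$roles[["B"]])
  C <- .cc(conc, k$roles[["C"]])
  P <- .cc(conc, k$roles[["P"]]); Q <- .cc(conc, k$roles[["Q"]])
  ct <- k$constants
  abc <- A * B * C / (ct$Ka * ct$Kb * ct$Kc)
  pq <- P * Q / (ct$Kp * ct$Kq)
  num <- ct$Vmf * abc - ct$Vmr * pq
  den <- 1 + A / ct$Ka + A * B / (ct$Ka * ct$Kb) + abc + pq + Q / ct$Kq
  if ("I" %in% names(k$roles) && !is.null(k$inhibition)) {
    I <- .cc(conc, k$roles[["I"]])
    Ki <- k$inhibition$Ki; a <- k$inhibition$alpha
    den <- den + I / Ki + (A * B / (ct$Ka * ct$Kb)) * I / (a * Ki) +
      abc * I / (a * Ki) + pq * I / (a * Ki)
  }
  num / den
}

# random bisubstrate Michaelis-Menten; numerator either in the Keq form
# (mass-action drive) or the Vmf/Vmr form; the dead-end A.Q and P.B cross
# terms are optional (present for PYK, absent for PGK/LDH as printed).
.rate_random_bibi <- function(k, conc) {
  A <- .cc(conc, k$roles[["A"]]); B <- .cc(conc, k$roles[["B"]])
  P <- .cc(conc, k$roles[["P"]]); Q <- .cc(conc, k$roles[["Q"]])
  ct <- k$constants
  ab <- A * B / (ct$alpha * ct$Ka * ct$Kb)
  pq <- P * Q / (ct$beta * ct$Kp * ct$Kq)
  if (!is.null(ct$Keq)) {
    num <- ct$Vmf / (ct$alpha * ct$Ka * ct$Kb) * (A * B - P * Q / ct$Keq)
  } else {
    num <- ct$Vmf * ab - ct$Vmr * pq
  }
  den <- 1 + A / ct$Ka + B / ct$Kb + ab + P / ct$Kp + Q / ct$Kq + pq
  if (isTRUE(ct$cross_terms))
    den <- den + A * Q / (ct$Ka * ct$Kq) + P * B / (ct$Kp * ct$Kb)
  num / den
}

# irreversible Michaelis-Menten (auxiliary closure steps: ATPase, glycogen
# phosphorolysis supply)
.rate_mm_irrev <- function(k, conc) {
  S <- .cc(conc, k$roles[["S"]])
  ct <- k$constants
  ct$Vmf * S / (ct$Ks + S)
}

# opaque kinetic law imported from foreign SBML: an R expression over
# species names, with Vmf/Vmr multipliers so activity scaling still works
.rate_opaque <- function(k, conc) {
  scale <- if (is.null(k$constants$Vmf)) 1 else k$constants$Vmf
  scale * eval(k$expr, envir = as.list(conc))
}

#' Haldane-consistent reverse maximal velocity
#'
#' For families parameterized with both `Vmf` and `Vmr`, returns the `Vmr`
#' implied by the Haldane relationship so that the net rate vanishes exactly
#' at thermodynamic equilibrium (mass-action ratio equal to `Keq`).
#'
#' @param k a `reaction_kinetics` object.
#' @param Keq equilibrium constant on the concentration scale.
#' @return the Haldane-consistent `Vmr`, or `NA` for families whose reverse
#'   rate is already expressed through `Keq`.
#' @export
haldane_vmr <- function(k, Keq) {
  ct <- k$constants
  vmr <- switch(k$family,
    hpi_multi_inhib = ct$Vmf * ct$Kp / (ct$Ks * Keq),
    uni_uni_rev_mm  = ct$Vmf * ct$Kp / (ct$Ks * Keq),
    aldo_unibi      = ct$Vmf * ct$Kp1 * ct$Kp2 / (ct$Ks * Keq),
    gapdh_terbi     = ct$Vmf * ct$Kp * ct$Kq / (ct$Ka * ct$Kb * ct$Kc * Keq),
    random_bibi     = ct$Vmf * ct$beta * ct$Kp * ct$Kq /
                      (ct$alpha * ct$Ka * ct$Kb * Keq),
    NA_real_)
  # a missing constant must surface as the named validation error, not here
  if (length(vmr) != 1) NA_real_ else vmr
}

#' Relative Haldane residual of a kinetics record
#'
#' Measures how far the stored `Vmr` is from the value the Haldane
#' relationship implies: `|Vmr - Vmr_haldane| / Vmr_haldane`.  Zero means
#' the rate law vanishes exactly at equilibrium.
#'
#' @param k a `reaction_kinetics` object.
#' @param Keq equilibrium constant (concentration scale).
#' @return non-negative relative residual, or `NA` when not applicable.
#' @export
haldane_residual <- function(k, Keq) {
  vh <- haldane_vmr(k, Keq)
  if (is.na(vh) || is.null(k$constants$Vmr)) return(NA_real_)
  abs(k$constants$Vmr - vh) / vh
}
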
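# Symbolic transcriptions of the rate equations
#
# Each family is transcribed a second time, independently of the numeric
# evaluators in rate-laws.R, as a plain R expression over species names with
# numeric constants inlined.  The expressions serve two purposes: they are
# the oracle against which the numeric evaluators are verified on random
# states, and they are the source from which SBML kinetic-law MathML is
# generated.  The algebra is deliberately written in a different
# factorization (fully expanded denominators, no shared sub-terms) so that a
# transcription slip in one path cannot hide in the other.

.n <- function(x) sprintf("%.17g", x)

# expanded denominator strings built term by term
.sym_transporter <- function(k) {
  r <- k$roles; ct <- k$constants
  isos <- if (!is.null(k$isoforms)) k$isoforms else
    list(list(f = 1, Ks = ct$Ks, Kp = ct$Kp))
  terms <- vapply(isos, function(iso) {
    sprintf("(%s * %s * (%s - %s/%s) / (%s * (1 + %s/%s) + %s))",
            .n(ct$Vmf), .n(iso$f), r[["S"]], r[["P"]], .n(ct$Keq),
            .n(iso$Ks), r[["P"]], .n(iso$Kp), r[["S"]])
  }, character(1))
  paste(terms, collapse = " + ")
}

.sym_hk <- function(k) {
  r <- k$roles; ct <- k$constants
  A <- r[["A"]]; B <- r[["B"]]; P <- r[["P"]]; Q <- r[["Q"]]
  isos <- if (!is.null(k$isoforms)) k$isoforms else list(list(f = 1, Ka = ct$Ka))
  terms <- vapply(isos, function(iso) {
    Ka <- iso$Ka
    den <- sprintf(
      "1 + %s/%s + %s/%s + %s*%s/(%s*%s*%s) + %s/%s + %s/%s + %s*%s/(%s*%s) + %s*%s/(%s*%s) + %s*%s/(%s*%s)",
      A, .n(Ka), B, .n(ct$Kb), A, B, .n(ct$alpha1), .n(Ka), .n(ct$Kb),
      P, .n(ct$Kp), Q, .n(ct$Kq), P, Q, .n(ct$Kp), .n(ct$Kq),
      A, Q, .n(Ka), .n(ct$Kq), P, B, .n(ct$Kp), .n(ct$Kb))
    if ("I" %in% names(r) && !is.null(k$inhibition)) {
      I <- r[["I"]]; Ki <- k$inhibition$Ki
      a2 <- if (is.null(k$inhibition$alpha2)) 1 else k$inhibition$alpha2
      den <- sprintf("%s + %s/%s + %s*%s/(%s*%s*%s) + %s*%s*%s/(%s*%s*%s*%s*%s)",
                     den, I, .n(Ki), A, I, .n(a2), .n(Ka), .n(Ki),
                     A, I, B, .n(ct$alpha1), .n(Ka), .n(ct$Kb), .n(a2), .n(Ki))
    }
    sprintf("((%s*%s/(%s*%s*%s)) * (%s*%s - %s*%s/%s) / (%s))",
            .n(ct$Vmf), .n(iso$f), .n(ct$alpha1), .n(Ka), .n(ct$Kb),
            A, B, P, Q, .n(ct$Keq), den)
  }, character(1))
  paste(terms, collapse = " + ")
}

.sym_hpi <- function(k) {
  r <- k$roles; ct <- k$constants
  S <- r[["S"]]; P <- r[["P"]]
  tsum <- if (length(k$inhibitors)) {
    paste(vapply(seq_along(k$inhibitors), function(i) {
      sprintf("%s/%s", names(k$inhibitors)[i], .n(k$inhibitors[[i]]))
    }, character(1)), collapse = " + ")
  } else "0"
  num <- sprintf("%s*%s/%s - %s*%s/%s",
                 .n(ct$Vmf), S, .n(ct$Ks), .n(ct$Vmr), P, .n(ct$Kp))
  mech <- if (is.null(k$mechanism)) "competitive" else k$mechanism
  den <- switch(mech,
    competitive = sprintf("1 + %s/%s + %s/%s + (%s)",
                          S, .n(ct$Ks), P, .n(ct$Kp), tsum),
    uncompetitive = sprintf("1 + (%s/%s)*(1 + (%s)) + (%s/%s)*(1 + (%s))",
                            S, .n(ct$Ks), tsum, P, .n(ct$Kp), tsum),
    mixed = sprintf(
      "1 + (%s) + (%s/%s)*(1 + (%s)/%s) + (%s/%s)*(1 + (%s)/%s)",
      tsum, S, .n(ct$Ks), tsum, .n(ct$alpha), P, .n(ct$Kp), tsum,
      .n(ct$alpha)))
  sprintf("(%s) / (%s)", num, den)
}

.sym_pfk1 <- function(k) {
  r <- k$roles; ct <- k$constants
  S <- r[["S"]]; ATP <- r[["ATP"]]; F26 <- r[["ACT"]]; CIT <- r[["INH"]]
  ADP <- r[["P1"]]; FBP <- r[["P2"]]
  aK <- sprintf("(%s*%s)", .n(ct$alpha), .n(ct$KaF26BP))
  phi <- sprintf("(%s*(1 + %s/%s)/(%s*(1 + %s/%s)))",
                 S, F26, aK, .n(ct$KFru6P), F26, .n(ct$KaF26BP))
  leff <- sprintf(
    "(%s*(1 + %s/%s)^4*(1 + %s/%s)^4/(1 + %s/%s)^4)",
    .n(ct$L), CIT, .n(ct$KiCIT), ATP, .n(ct$KiATP), F26, .n(ct$KaF26BP))
  fwd <- sprintf(
    "((%s/%s)/(1 + %s/%s)) * ((1 + %s*%s/%s)/(1 + %s/%s)) * (%s*(1 + %s)^3/(%s + (1 + %s)^4))",
    ATP, .n(ct$KATP), ATP, .n(ct$KATP),
    .n(ct$beta), F26, aK, F26, aK, phi, phi, leff, phi)
  rev <- sprintf(
    "((%s*%s/(%s*%s*%s)) / (1 + %s/%s + %s/%s + %s*%s/(%s*%s)))",
    ADP, FBP, .n(ct$KADP), .n(ct$KFBP), .n(ct$Keq),
    ADP, .n(ct$KADP), FBP, .n(ct$KFBP), ADP, FBP, .n(ct$KADP), .n(ct$KFBP))
  sprintf("%s * (%s - %s)", .n(ct$Vm), fwd, rev)
}

.sym_aldo <- function(k) {
  r <- k$roles; ct <- k$constants
  S <- r[["S"]]; P1 <- r[["P1"]]; P2 <- r[["P2"]]
  sprintf(
    "(%s*%s/%s - %s*%s*%s/(%s*%s)) / (1 + %s/%s + %s/%s + %s/%s + %s*%s/(%s*%s))",
    .n(ct$Vmf), S, .n(ct$Ks), .n(ct$Vmr), P1, P2, .n(ct$Kp1), .n(ct$Kp2),
    S, .n(ct$Ks), P1, .n(ct$Kp1), P2, .n(ct$Kp2),
    P1, P2, .n(ct$Kp1), .n(ct$Kp2))
}

.sym_uniuni <- function(k) {
  r <- k$roles; ct <- k$constants
  S <- r[["S"]]; P <- r[["P"]]
  num <- sprintf("%s*%s/%s - %s*%s/%s",
                 .n(ct$Vmf), S, .n(ct$Ks), .n(ct$Vmr), P, .n(ct$Kp))
  if ("I" %in% names(r) && !is.null(k$inhibition)) {
    I <- r[["I"]]; Ki <- k$inhibition$Ki; a <- k$inhibition$alpha
    den <- sprintf(
      "1 + %s/%s + (%s/%s)*(1 + %s/(%s*%s)) + (%s/%s)*(1 + %s/(%s*%s))",
      I, .n(Ki), S, .n(ct$Ks), I, .n(a), .n(Ki),
      P, .n(ct$Kp), I, .n(a), .n(Ki))
  } else {
    den <- sprintf("1 + %s/%s + %s/%s", S, .n(ct$Ks), P, .n(ct$Kp))
  }
  sprintf("(%s) / (%s)", num, den)
}

.sym_gapdh <- function(k) {
  r <- k$roles; ct <- k$constants
  A <- r[["A"]]; B <- r[["B"]]; C <- r[["C"]]; P <- r[["P"]]; Q <- r[["Q"]]
  num <- sprintf("%s*%s*%s*%s/(%s*%s*%s) - %s*%s*%s/(%s*%s)",
                 .n(ct$Vmf), A, B, C, .n(ct$Ka), .n(ct$Kb), .n(ct$Kc),
                 .n(ct$Vmr), P, Q, .n(ct$Kp), .n(ct$Kq))
  den <- sprintf(
    "1 + %s/%s + %s*%s/(%s*%s) + %s*%s*%s/(%s*%s*%s) + %s*%s/(%s*%s) + %s/%s",
    A, .n(ct$Ka), A, B, .n(ct$Ka), .n(ct$Kb),
    A, B, C, .n(ct$Ka), .n(ct$Kb), .n(ct$Kc),
    P, Q, .n(ct$Kp), .n(ct$Kq), Q, .n(ct$Kq))
  if ("I" %in% names(r) && !is.null(k$inhibition)) {
    I <- r[["I"]]; Ki <- k$inhibition$Ki; a <- k$inhibition$alpha
    den <- sprintf(
      "%s + %s/%s + %s*%s*%s/(%s*%s*%s*%s) + %s*%s*%s*%s/(%s*%s*%s*%s*%s) + %s*%s*%s/(%s*%s*%s*%s)",
      den, I, .n(Ki),
      A, B, I, .n(ct$Ka), .n(ct$Kb), .n(a), .n(Ki),
      A, B, C, I, .n(ct$Ka), .n(ct$Kb), .n(ct$Kc), .n(a), .n(Ki),
      P, Q, I, .n(ct$Kp), .n(ct$Kq), .n(a), .n(Ki))
  }
  sprintf("(%s) / (%s)", num, den)
}

.sym_random_bibi <- function(k) {
  r <- k$roles; ct <- k$constants
  A <- r[["A"]]; B <- r[["B"]]; P <- r[["P"]]; Q <- r[["Q"]]
  if (!is.null(ct$Keq)) {
    num <- sprintf("(%s/(%s*%s*%s))*(%s*%s - %s*%s/%s)",
                   .n(ct$Vmf), .n(ct$alpha), .n(ct$Ka), .n(ct$Kb),
                   A, B, P, Q, .n(ct$Keq))
  } else {
    num <- sprintf("%s*%s*%s/(%s*%s*%s) - %s*%s*%s/(%s*%s*%s)",
                   .n(ct$Vmf), A, B, .n(ct$alpha), .n(ct$Ka), .n(ct$Kb),
                   .n(ct$Vmr), P, Q, .n(ct$beta), .n(ct$Kp), .n(ct$Kq))
  }
  den <- sprintf(
    "1 + %s/%s + %s/%s + %s*%s/(%s*%s*%s) + %s/%s + %s/%s + %s*%s/(%s*%s*%s)",
    A, .n(ct$Ka), B, .n(ct$Kb), A, B, .n(ct$alpha), .n(ct$Ka), .n(ct$Kb),
    P, .n(ct$Kp), Q, .n(ct$Kq), P, Q, .n(ct$beta), .n(ct$Kp), .n(ct$Kq))
  if (isTRUE(ct$cross_terms))
    den <- sprintf("%s + %s*%s/(%s*%s) + %s*%s/(%s*%s)",
                   den, A, Q, .n(ct$Ka), .n(ct$Kq),
                   P, B, .n(ct$Kp), .n(ct$Kb))
  sprintf("(%s) / (%s)", num, den)
}

.sym_mm_irrev <- function(k) {
  r <- k$roles; ct <- k$constants
  sprintf("%s*%s/(%s + %s)", .n(ct$Vmf), r[["S"]], .n(ct$Ks), r[["S"]])
}

#' Symbolic transcription of a rate law
#'
#' Returns the rate equation of a kinetics record as an unevaluated R
#' expression over species names, with the numeric constants inlined.  The
#' transcription is maintained independently of [eval_rate()] and is used
#' both as a verification oracle and as the source for SBML kinetic-law
#' math.
#'
#' @param k a `reaction_kinetics` object.
#' @return an unevaluated R expression (call).
#' @export
rate_expression <- function(k) {
  s <- switch(k$family,
    transporter_rev_mm = .sym_transporter(k),
    hk_random_bibi     = .sym_hk(k),
    hpi_multi_inhib    = .sym_hpi(k),
    pfk1_mwc           = .sym_pfk1(k),
    aldo_unibi         = .sym_aldo(k),
    uni_uni_rev_mm     = .sym_uniuni(k),
    gapdh_terbi        = .sym_gapdh(k),
    random_bibi        = .sym_random_bibi(k),
    mm_irrev           = .sym_mm_irrev(k),
    opaque             = return(k$expr),
    stop("no symbolic transcription for family ", k$family))
  str2lang(s)
}

#' Evaluate the symbolic transcription of a rate law
#'
#' @param k a `reaction_kinetics` object.
#' @param conc named numeric vector of concentrations (mM).
#' @return the rate computed from the independent symbolic transcription.
#' @export
eval_rate_symbolic <- function(k, conc) {
  eval(rate_expression(k), envir = as.list(conc))
}
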
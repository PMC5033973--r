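# Rate-law families: hand-computed values, equilibrium behavior, reductions,
# scaling laws, and agreement with the independent symbolic transcription.

state0 <- function(...) {
  # zero state over the full species set, overridden by named args
  sp <- c("Glc_out", "Glc_in", "Glc6P", "Fru6P", "FBP", "DHAP", "G3P",
          "BPG", "PG3", "PG2", "PEP", "Pyr", "Lac", "Lac_in", "Lac_out",
          "ATP", "ADP", "NAD", "NADH", "Pi", "Ery4P", "PG6", "F26BP", "CIT")
  s <- stats::setNames(rep(0, length(sp)), sp)
  over <- list(...)
  s[names(over)] <- unlist(over)
  s
}

test_that("reversible carrier law matches direct substitution and vanishes at equilibrium", {
  k <- reaction_kinetics("transporter_rev_mm",
                         roles = c(S = "Glc_out", P = "Glc_in"),
                         constants = list(Vmf = 100, Keq = 1, Ks = 1, Kp = 1))
  # direct substitution: 100*(5-1)/(1*(1+1)+5)
  expect_equal(eval_rate(k, state0(Glc_out = 5, Glc_in = 1)), 400 / 7)
  # equilibrium: Glc_out = Keq * Glc_in
  expect_equal(eval_rate(k, state0(Glc_out = 2, Glc_in = 2)), 0)
  # two identical isoforms at f = 0.5 equal a single carrier
  k2 <- reaction_kinetics("transporter_rev_mm",
                          roles = c(S = "Glc_out", P = "Glc_in"),
                          constants = list(Vmf = 100, Keq = 1),
                          isoforms = list(list(f = 0.5, Ks = 1, Kp = 1),
                                          list(f = 0.5, Ks = 1, Kp = 1)))
  st <- state0(Glc_out = 5, Glc_in = 1)
  expect_equal(eval_rate(k2, st), eval_rate(k, st))
  # lactate carrier orientation: substrate inside, product outside
  mct <- reaction_kinetics("transporter_rev_mm",
                           roles = c(S = "Lac_in", P = "Lac_out"),
                           constants = list(Vmf = 50, Keq = 1,
                                            Ks = 4.5, Kp = 30))
  expect_gt(eval_rate(mct, state0(Lac_in = 5, Lac_out = 1)), 0)
  expect_equal(eval_rate(mct, state0(Lac_in = 2, Lac_out = 2)), 0)
})

test_that("hexokinase random Bi-Bi law: substitution, equilibrium, inhibitor-free reduction", {
  mk <- function(Ki = NULL) reaction_kinetics(
    "hk_random_bibi",
    roles = c(A = "Glc_in", B = "ATP", P = "Glc6P", Q = "ADP",
              if (!is.null(Ki)) c(I = "FBP")),
    constants = list(Vmf = 10, Keq = 1000, Ka = 1, Kb = 1, Kp = 1, Kq = 1,
                     alpha1 = 1),
    inhibition = if (!is.null(Ki)) list(Ki = Ki, alpha2 = 1))
  # round numbers: denominator 1+1+1+1 + 2+2+2 = 10, numerator 10
  st <- state0(Glc_in = 1, ATP = 1, FBP = 2)
  expect_equal(eval_rate(mk(Ki = 1), st), 1.0)
  # equilibrium: [P][Q]/([A][B]) = Keq
  steq <- state0(Glc_in = 1, ATP = 1, Glc6P = 50, ADP = 20)
  expect_equal(eval_rate(mk(Ki = 1), steq), 0)
  # I = 0 equals the uninhibited form, and Ki -> Inf approaches it
  st2 <- state0(Glc_in = 0.7, ATP = 3, Glc6P = 2, ADP = 1)
  expect_equal(eval_rate(mk(Ki = 1), st2), eval_rate(mk(NULL), st2))
  st3 <- state0(Glc_in = 0.7, ATP = 3, Glc6P = 2, ADP = 1, FBP = 4)
  expect_equal(eval_rate(mk(Ki = 1e12), st3), eval_rate(mk(NULL), st3),
               tolerance = 1e-9)
  # strictly decreasing in the inhibitor when forward-operating
  rates <- vapply(c(0, 1, 2, 5), function(i)
    eval_rate(mk(Ki = 1), state0(Glc_in = 1, ATP = 2, FBP = i)), numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("isomerase multi-inhibitor law: all mechanisms agree without inhibitors and at equilibrium", {
  mk <- function(mechanism, inhibitors = c(FBP = 1), alpha = 2)
    reaction_kinetics("hpi_multi_inhib",
                      roles = c(S = "Glc6P", P = "Fru6P"),
                      constants = list(Vmf = 10, Vmr = 0, Ks = 1, Kp = 1,
                                       alpha = alpha),
                      inhibitors = inhibitors, mechanism = mechanism)
  # hand substitution: competitive 10/(1+1+3) and uncompetitive 10/(1+1*(1+3))
  st <- state0(Glc6P = 1, FBP = 3)
  expect_equal(eval_rate(mk("competitive"), st), 2.0)
  expect_equal(eval_rate(mk("uncompetitive"), st), 2.0)
  # they diverge when the product is present
  stp <- state0(Glc6P = 1, Fru6P = 2, FBP = 3)
  expect_false(isTRUE(all.equal(eval_rate(mk("competitive"), stp),
                                eval_rate(mk("uncompetitive"), stp))))
  # all mechanisms identical with all inhibitors at zero
  st0 <- state0(Glc6P = 2, Fru6P = 0.3)
  r <- vapply(c("competitive", "uncompetitive", "mixed"),
              function(m) eval_rate(mk(m), st0), numeric(1))
  expect_equal(max(r) - min(r), 0)
  # equilibrium (Fru6P/Glc6P = Keq with Haldane Vmr) is preserved by all
  # mechanisms, inhibitors present or not
  mkh <- function(mechanism) reaction_kinetics(
    "hpi_multi_inhib", roles = c(S = "Glc6P", P = "Fru6P"),
    constants = list(Vmf = 10, Ks = 0.9, Kp = 0.12, alpha = 2),
    inhibitors = c(FBP = 0.6, Ery4P = 0.002), mechanism = mechanism,
    Keq_thermo = 0.29)
  steq <- state0(Glc6P = 2, Fru6P = 2 * 0.29, FBP = 1.5, Ery4P = 0.004)
  for (m in c("competitive", "uncompetitive", "mixed"))
    expect_equal(eval_rate(mkh(m), steq), 0, tolerance = 1e-14)
})

test_that("uncompetitive inhibition is not relieved by saturating substrate", {
  mk <- function(mechanism) reaction_kinetics(
    "hpi_multi_inhib", roles = c(S = "Glc6P", P = "Fru6P"),
    constants = list(Vmf = 10, Vmr = 0, Ks = 1, Kp = 1, alpha = 2),
    inhibitors = c(FBP = 1), mechanism = mechanism)
  st_inf <- state0(Glc6P = 1e7, FBP = 3)
  v_comp <- eval_rate(mk("competitive"), st_inf)
  v_unc <- eval_rate(mk("uncompetitive"), st_inf)
  v_mix <- eval_rate(mk("mixed"), st_inf)
  expect_equal(v_comp, 10, tolerance = 1e-4)          # Vmax recovered
  expect_equal(v_unc, 10 / (1 + 3), tolerance = 1e-4) # Vmax/(1+I/Ki)
  expect_lt(v_unc, v_comp)
  expect_lt(v_unc, v_mix); expect_lt(v_mix, v_comp)
})

test_that("mixed mechanism requires its interaction factor", {
  expect_error(reaction_kinetics(
    "hpi_multi_inhib", roles = c(S = "Glc6P", P = "Fru6P"),
    constants = list(Vmf = 10, Vmr = 0, Ks = 1, Kp = 1),
    inhibitors = c(FBP = 1), mechanism = "mixed"), "alpha")
})

test_that("PFK-1 MWC law: substrate dependence, allosteric limits and effector monotonicity", {
  ct <- list(Vm = 40, KATP = 0.06, KFru6P = 1, L = 10, KaF26BP = 0.005,
             KiCIT = 3.9, KiATP = 2.5, alpha = 0.32, beta = 1.2,
             KADP = 0.7, KFBP = 5, Keq = 247)
  roles <- c(S = "Fru6P", ATP = "ATP", ACT = "F26BP", INH = "CIT",
             P1 = "ADP", P2 = "FBP")
  k <- reaction_kinetics("pfk1_mwc", roles = roles, constants = ct)
  # no substrate and no reverse ligands: rate is zero
  expect_equal(eval_rate(k, state0(ATP = 2, CIT = 1)), 0)
  # monotonically increasing in the activator at fixed substrates
  v_act <- vapply(c(0, 0.002, 0.01, 0.05), function(a)
    eval_rate(k, state0(Fru6P = 1, ATP = 2, F26BP = a, CIT = 1)),
    numeric(1))
  expect_true(all(diff(v_act) > 0))
  # monotonically decreasing in citrate
  v_cit <- vapply(c(0, 1, 3, 10), function(cit)
    eval_rate(k, state0(Fru6P = 1, ATP = 2, F26BP = 0.005, CIT = cit)),
    numeric(1))
  expect_true(all(diff(v_cit) < 0))
  # L = 0, citrate = 0: hyperbolic in Fru6P (Hill coefficient ~ 1)
  ct0 <- ct; ct0$L <- 0
  k0 <- reaction_kinetics("pfk1_mwc", roles = roles, constants = ct0)
  svals <- 10^seq(-2, 2, length.out = 25)
  v <- vapply(svals, function(s)
    eval_rate(k0, state0(Fru6P = s, ATP = 2)), numeric(1))
  vmax <- eval_rate(k0, state0(Fru6P = 1e7, ATP = 2))
  y <- v / vmax
  keep <- y > 0.05 & y < 0.95
  hill <- stats::coef(stats::lm(log(y / (1 - y))[keep] ~ log(svals)[keep]))[2]
  expect_equal(unname(hill), 1, tolerance = 0.05)
  # with L > 0 the same fit is sigmoidal (Hill > 1)
  vL <- vapply(svals, function(s)
    eval_rate(k, state0(Fru6P = s, ATP = 2, CIT = 1)), numeric(1))
  vmaxL <- eval_rate(k, state0(Fru6P = 1e7, ATP = 2, CIT = 1))
  yL <- vL / vmaxL
  keepL <- yL > 0.05 & yL < 0.95
  hillL <- stats::coef(stats::lm(log(yL / (1 - yL))[keepL] ~
                                   log(svals)[keepL]))[2]
  expect_gt(unname(hillL), 1.5)
})

test_that("aldolase Uni-Bi law: substitution, zero states, product monotonicity", {
  k <- reaction_kinetics("aldo_unibi",
                         roles = c(S = "FBP", P1 = "DHAP", P2 = "G3P"),
                         constants = list(Vmf = 10, Vmr = 5, Ks = 1,
                                          Kp1 = 1, Kp2 = 1))
  expect_equal(eval_rate(k, state0(FBP = 1)), 5.0)  # 10*1/(1+1)
  expect_equal(eval_rate(k, state0()), 0)
  # strictly decreasing as DHAP rises at fixed FBP, G3P
  v <- vapply(c(0, 0.5, 1, 2), function(d)
    eval_rate(k, state0(FBP = 1, DHAP = d, G3P = 0.5)), numeric(1))
  expect_true(all(diff(v) < 0))
  # Haldane-consistent equilibrium: FBP = DHAP*G3P/Keq
  kh <- reaction_kinetics("aldo_unibi",
                          roles = c(S = "FBP", P1 = "DHAP", P2 = "G3P"),
                          constants = list(Vmf = 10, Ks = 0.5, Kp1 = 2,
                                           Kp2 = 1),
                          Keq_thermo = 0.069)
  expect_equal(eval_rate(kh, state0(FBP = 1 * 0.5 / 0.069, DHAP = 1,
                                    G3P = 0.5)), 0, tolerance = 1e-13)
})

test_that("reversible uni-uni law with mixed inhibition reduces and limits correctly", {
  mk <- function(inhib) reaction_kinetics(
    "uni_uni_rev_mm",
    roles = c(S = "DHAP", P = "G3P", if (inhib) c(I = "FBP")),
    constants = list(Vmf = 10, Vmr = 0, Ks = 1, Kp = 1),
    inhibition = if (inhib) list(Ki = 2, alpha = 5))
  expect_equal(eval_rate(mk(FALSE), state0(DHAP = 1)), 5.0)
  # inhibited form at I = 0 equals the plain form
  st <- state0(DHAP = 0.8, G3P = 0.2)
  expect_equal(eval_rate(mk(TRUE), st), eval_rate(mk(FALSE), st))
  # I -> Inf tends to the alpha-rescaled closed form:
  # den -> 1 + I/Ki (dead-end), so the rate tends to 0 like Ki/I
  v_big <- eval_rate(mk(TRUE), state0(DHAP = 1, FBP = 1e8))
  expect_lt(abs(v_big), 1e-5)
  # Haldane equilibrium
  kh <- reaction_kinetics("uni_uni_rev_mm",
                          roles = c(S = "PG2", P = "PEP"),
                          constants = list(Vmf = 10, Ks = 0.038, Kp = 0.06),
                          Keq_thermo = 4.6)
  expect_equal(eval_rate(kh, state0(PG2 = 0.5, PEP = 0.5 * 4.6)), 0,
               tolerance = 1e-13)
})

test_that("GAPDH Ter-Bi law reduces to the uninhibited form at I = 0 and vanishes at the balance point", {
  roles_i <- c(A = "NAD", B = "G3P", C = "Pi", P = "BPG", Q = "NADH",
               I = "FBP")
  ct <- list(Vmf = 10, Vmr = 4, Ka = 0.1, Kb = 0.3, Kc = 3, Kp = 0.02,
             Kq = 0.01)
  ki <- reaction_kinetics("gapdh_terbi", roles = roles_i, constants = ct,
                          inhibition = list(Ki = 2, alpha = 4))
  k0 <- reaction_kinetics("gapdh_terbi", roles = roles_i[1:5],
                          constants = ct)
  set.seed(42)
  for (i in 1:100) {
    st <- random_state(c("NAD", "G3P", "Pi", "BPG", "NADH", "FBP"))
    st["FBP"] <- 0
    expect_equal(eval_rate(ki, st), eval_rate(k0, st))
  }
  # numerator balance: Vmf*ABC/(KaKbKc) = Vmr*PQ/(KpKq) gives zero rate
  st <- state0(NAD = 0.1, G3P = 0.3, Pi = 3, NADH = 0.01, FBP = 1)
  st["BPG"] <- (10 * 1 / 4) * 0.02 * 0.01 / 0.01   # solve P from balance
  expect_equal(eval_rate(ki, st), 0, tolerance = 1e-13)
})

test_that("random bisubstrate law: substitution and Keq/Vmr form equivalence under Haldane", {
  roles <- c(A = "PEP", B = "ADP", P = "Pyr", Q = "ATP")
  # alpha=beta=1, all K=1, Vmf=10, Vmr=0, A=B=1: 10/(1+1+1+1)
  kv <- reaction_kinetics("random_bibi", roles = roles,
                          constants = list(Vmf = 10, Vmr = 0, Ka = 1, Kb = 1,
                                           Kp = 1, Kq = 1, alpha = 1,
                                           beta = 1))
  expect_equal(eval_rate(kv, state0(PEP = 1, ADP = 1)), 2.5)
  # Keq-numerator form equals Vmr-numerator form when Vmr is Haldane-chosen
  Keq <- 120
  ct <- list(Vmf = 7, Ka = 0.4, Kb = 0.3, Kp = 2, Kq = 0.9,
             alpha = 1, beta = 1, cross_terms = TRUE)
  k_keq <- reaction_kinetics("random_bibi", roles = roles,
                             constants = c(ct, list(Keq = Keq)))
  k_vmr <- reaction_kinetics("random_bibi", roles = roles,
                             constants = c(ct, list(
                               Vmr = 7 * 2 * 0.9 / (0.4 * 0.3 * Keq))))
  set.seed(7)
  for (i in 1:100) {
    st <- random_state(c("PEP", "ADP", "Pyr", "ATP"))
    expect_equal(eval_rate(k_keq, st), eval_rate(k_vmr, st),
                 tolerance = 1e-12)
  }
  # both forms vanish at equilibrium
  steq <- state0(PEP = 0.5, ADP = 0.2, Pyr = 4, ATP = 0.5 * 0.2 * Keq / 4)
  expect_equal(eval_rate(k_keq, steq), 0, tolerance = 1e-13)
  expect_equal(eval_rate(k_vmr, steq), 0, tolerance = 1e-13)
})

test_that("every rate law is 1-homogeneous in (Vmf, Vmr) and matches its symbolic transcription", {
  m <- ref_as30d()
  mh <- ref_hela_hypo()
  set.seed(11)
  sp_as <- all_species_as30d()
  sp_he <- c(names(mh$initial), names(mh$fixed))
  for (mod in list(list(m, sp_as), list(mh, sp_he))) {
    model <- mod[[1]]; sp <- mod[[2]]
    doubled <- model
    for (nm in names(model$reactions)) {
      doubled <- scale_enzyme_activity(doubled, nm, 2)
    }
    for (i in 1:50) {
      st <- random_state(sp)
      v1 <- model_rates(model, st[names(model$initial)])
      # symbolic oracle on every reaction (relative error < 1e-10)
      full <- c(st[names(model$initial)], model$fixed)
      for (nm in names(model$reactions)) {
        a <- eval_rate(model$reactions[[nm]]$kinetics, full)
        b <- eval_rate_symbolic(model$reactions[[nm]]$kinetics, full)
        expect_lt(abs(a - b), 1e-10 * max(abs(a), 1e-6))
      }
      # doubling Vmf and Vmr doubles every rate
      v2 <- model_rates(doubled, st[names(model$initial)])
      expect_equal(v2, 2 * v1, tolerance = 1e-12)
    }
  }
})

test_that("negative concentrations raise a state error unless clamped", {
  k <- reaction_kinetics("transporter_rev_mm",
                         roles = c(S = "Glc_out", P = "Glc_in"),
                         constants = list(Vmf = 10, Keq = 1, Ks = 1, Kp = 1))
  st <- state0(Glc_out = 1)
  st["Glc_in"] <- -0.5
  expect_error(eval_rate(k, st), "negative")
  expect_equal(eval_rate(k, st, clamp = TRUE),
               eval_rate(k, state0(Glc_out = 1)))
  # missing species is a parameter/state error naming the species
  expect_error(eval_rate(k, c(Glc_out = 1)), "Glc_in")
})
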
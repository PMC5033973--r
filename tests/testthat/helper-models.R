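# Shared fixtures: toy models with analytic steady states, random states,
# and cached reference models.

# reference models are loaded once per test run
ref_as30d <- function() {
  if (is.null(.glyco_test_env$as30d))
    .glyco_test_env$as30d <- reference_model("AS30D")
  .glyco_test_env$as30d
}
ref_hela_hypo <- function() {
  if (is.null(.glyco_test_env$hela_hypo))
    .glyco_test_env$hela_hypo <- reference_model("HeLa_hypo")
  .glyco_test_env$hela_hypo
}
ss_as30d <- function() {
  if (is.null(.glyco_test_env$ss_as30d))
    .glyco_test_env$ss_as30d <- steady_state(ref_as30d())
  .glyco_test_env$ss_as30d
}
ss_hela_hypo <- function() {
  if (is.null(.glyco_test_env$ss_hela))
    .glyco_test_env$ss_hela <- steady_state(ref_hela_hypo())
  .glyco_test_env$ss_hela
}
.glyco_test_env <- new.env(parent = emptyenv())

# random positive concentration state over a species set
random_state <- function(species, lo = 0.01, hi = 5) {
  stats::setNames(exp(stats::runif(length(species), log(lo), log(hi))),
                  species)
}

# 2-step irreversible chain with analytic steady state:
#   Sin (fixed, 2 mM) --v1--> S1 --v2--> (drain)
# v1 = V1 Sin/(K1+Sin) is constant, so J = v1 and S1 = K2 J/(V2 - J).
toy_chain2 <- function(V1 = 10, K1 = 1, V2 = 40, K2 = 0.5, Sin = 2) {
  build_model("AS30D", list(
    name = "toy_chain2", condition = "AS30D",
    fixed = list(Sin = Sin),
    initial = list(S1 = 0.1),
    totals = list(),
    flux_reaction = "STEP2",
    reactions = list(
      STEP1 = list(family = "mm_irrev",
                   stoich = list(Sin = -1, S1 = 1),
                   roles = list(S = "Sin"),
                   constants = list(Vmf = V1, Ks = K1)),
      STEP2 = list(family = "mm_irrev",
                   stoich = list(S1 = -1),
                   roles = list(S = "S1"),
                   constants = list(Vmf = V2, Ks = K2))
    )))
}

# 3-step linear chain, all irreversible MM; flux is set by the first step
toy_chain3 <- function(V = c(8, 30, 50), K = c(1, 0.5, 0.2), Sin = 5) {
  build_model("AS30D", list(
    name = "toy_chain3", condition = "AS30D",
    fixed = list(Sin = Sin),
    initial = list(S1 = 0.1, S2 = 0.1),
    totals = list(),
    flux_reaction = "STEP3",
    reactions = list(
      STEP1 = list(family = "mm_irrev", stoich = list(Sin = -1, S1 = 1),
                   roles = list(S = "Sin"),
                   constants = list(Vmf = V[1], Ks = K[1])),
      STEP2 = list(family = "mm_irrev", stoich = list(S1 = -1, S2 = 1),
                   roles = list(S = "S1"),
                   constants = list(Vmf = V[2], Ks = K[2])),
      STEP3 = list(family = "mm_irrev", stoich = list(S2 = -1),
                   roles = list(S = "S2"),
                   constants = list(Vmf = V[3], Ks = K[3]))
    )))
}

# species present in the reference models (for random rate-law states)
all_species_as30d <- function() {
  m <- ref_as30d()
  c(names(m$initial), names(m$fixed))
}
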
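---
title: "Kinetic modeling and control analysis of cancer glycolysis with glycoMCA"
author: "glycoMCA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling and control analysis of cancer glycolysis with glycoMCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoMCA)
```

## The model and its assumptions

`glycoMCA` models glycolysis of AS-30D rat hepatocarcinoma and human HeLa
cells as a deterministic ODE system $\dot S = N\,v(S)$ over 15–16 free
metabolites, with every reaction rate given by a mechanistic enzyme rate
law. The biological question the package is built around is a control
question: the steps that *control* glycolytic flux (GLUT, HK, HPI) are not
the steps classical inhibitors hit (ENO, PYK, LDH, GAPDH), and the model
resolves this through the feedback inhibition of HK and HPI by
fructose-1,6-bisphosphate (Fru1,6BP) and dihydroxyacetone phosphate
(DHAP), the metabolites that the downstream steps control.

Key structural assumptions:

* **Conserved pools.** ATP+ADP and NAD⁺+NADH are conserved moieties; their
  totals are parameters (8.5 and 0.5 mM in AS-30D). There is no adenylate
  kinase/AMP and no oxidative phosphorylation coupling — ATP/ADP interplay
  with mitochondria is out of scope.
* **Boundary species.** Extracellular glucose and lactate, inorganic
  phosphate, and the regulatory inputs Ery4P, 6-phosphogluconate,
  Fru2,6BP and citrate are fixed; they act as inhibitor/activator inputs,
  not state variables.
* **Auxiliary closure.** Three small irreversible Michaelis–Menten steps
  close the network: an ATP demand (ATPase), and mitochondrial pyruvate
  oxidation plus NADH re-oxidation (shuttle) drains. Without the latter
  two, GAPDH and LDH would be the only NADH producer/consumer and the
  lower pathway would carry a spurious conservation (NADH minus
  lower-glycolytic carbon), making the steady state depend on the initial
  condition. HeLa models add a glycogen→Glc6P supply and the lactate
  exporter MCT; AS-30D treats intracellular lactate as a boundary sink and
  defines pathway flux as the LDH rate (the lactate-based experimental flux
  definition), while HeLa uses the MCT export flux.

## Rate laws

Each family is evaluated from named ligand roles (A/B/C/P/Q/S/I bound by
species *name*, never by position — an explicit guard against the
substrate-ordering hazard of GUI simulators where the reaction syntax need
not reflect the order stated in the rate equation). The families:
reversible carrier (Haldane form, 1–2 isoforms), random Bi–Bi HK with
dead-end mixed-type Fru1,6BP terms, reversible uni-uni isomerase with a
*set* of dead-end inhibitors under a selectable mechanism, MWC PFK-1,
random Uni-Bi aldolase, reversible uni-uni (TPI/PGAM/ENO; optional
mixed-type inhibitor), ordered Ter-Bi GAPDH (optional mixed-type
Fru1,6BP), and random bisubstrate kinases (PYK with the A·Q/P·B dead-end
cross terms and a mass-action Keq numerator; PGK/LDH without cross terms
and a Vmf/Vmr numerator).

Numerical/algebraic choices worth recording:

* **Mixed-type inhibition** is implemented in the canonical Segel dead-end
  form
  $v = (V_{mf}S/K_s - V_{mr}P/K_p) / \big(1 + \Sigma_j I_j/K_{i,j} +
  (S/K_s)(1+\Sigma_j I_j/(\alpha K_{i,j})) + (P/K_p)(1+\ldots)\big)$.
  Printed layouts of such equations are ambiguous about where the
  $(1+I/K_i)$ factors sit; the form above is the one that reduces to the
  uninhibited law at $I=0$, stays bounded as $I\to\infty$, and preserves
  the equilibrium zero, so it was frozen as the package's single reading.
  A single interaction factor $\alpha$ is shared by all inhibitors of one
  enzyme.
* **PFK-1** is transcribed once into a documented canonical form: forward
  $= V_m \cdot \mathrm{MM}(ATP) \cdot \mathrm{act}(F26BP) \cdot
  \phi(1+\phi)^3 / (L_\mathrm{eff} + (1+\phi)^4)$ with
  $\phi = S(1+F/(\alpha K_a)) / (K_S (1+F/K_a))$ and
  $L_\mathrm{eff} = L (1+CIT/K_{iCIT})^4 (1+ATP/K_{iATP})^4 /
  (1+F/K_a)^4$; the reverse reaction is a separate simple MM block. The
  exponents 3 and 4 are the tetramer's occupancy structure. Because the
  forward and reverse blocks are structurally different, this is the one
  family that does not vanish *exactly* at the mass-action equilibrium;
  it is excluded from the equilibrium-zero property test.
* **Haldane closure.** Reversible laws are parameterized by $V_{mf}$ and a
  fixed thermodynamic $K_{eq}$; $V_{mr}$ is derived at build time
  ($V_{mr} = V_{mf} K_p / (K_s K_{eq})$ and family analogues), so every
  model is thermodynamically consistent by construction, and enzyme
  titration (which scales $V_{mf}$ and $V_{mr}$ jointly) cannot break it.
* Every family has an **independent symbolic transcription**
  (`rate_expression()`), written in a different factorization; the numeric
  evaluators are verified against it on random states to $10^{-10}$
  relative. The same transcription generates the SBML MathML and the
  compiled per-model rate function used inside the solver loops (which is
  itself checked against the numeric evaluators at build time).

## Parameters

A fully experimentally fitted parameter set is not shipped; the
packaged sets (`inst/extdata/params_*_synthetic.yaml`, one per condition)
are *synthetic reference* parameterizations, chosen once and frozen:

* every constant the source measurements fix is used verbatim — the HPI
  inhibition constants of hypoglycemic HeLa cells ($K_i$(Ery4P) = 1 µM,
  $K_i$(Fru1,6BP) = 60 µM, $K_i$(6PG) = 15 µM), the AS-30D HPI
  $K_i$(DHAP) = 9.4 mM (which is why DHAP is dropped as an HPI inhibitor
  in HeLa, where DHAP is 0.5–0.8 mM), the mixed-mechanism default
  $\alpha = 2$;
* equilibrium constants are textbook thermodynamic values on the
  concentration scale (e.g. $K_{eq}$(HPI) = 0.29, $K_{eq}$(ALDO) =
  0.069 mM, $K_{eq}$(PGK) = 1800, $K_{eq}$(GAPDH) = 8·10⁻⁵ mM⁻¹) and are
  never sampled or tuned — they are physical constants;
* the remaining $K_m$/$V_{max}$ values are physiological literature-scale
  choices calibrated so the untreated AS-30D steady state falls in the
  experimentally reported control ranges (Glc6P ≈ 10 ± 5 mM, Fru1,6BP ≈
  2.4 ± 1.7 mM, DHAP ≈ 1.8 ± 0.4 mM, ATP ≈ 6 ± 2 mM, lactate flux ≈ 8 ±
  3 nmol·min⁻¹·mg⁻¹) with upstream steps carrying the main flux control.
  GAPDH and LDH operate near equilibrium (large $V_{max}$, physiological
  $K_{eq}$), which is what gives them modest concentration control
  despite carrying the full flux — and is also what transmits downstream
  back-pressure to the triose pools.

Quantitative control-coefficient values therefore depend on this synthetic
parameterization; the *sign structure* (producers positive, consumers
negative on Fru1,6BP/DHAP), the summation theorems, the mechanism
hierarchy and the feedback-scenario dissociation are parameterization-
robust and are what the test suite asserts.

Units: concentrations mM; rates in the units of the $V_{max}$ entries
(nmol·min⁻¹·(mg protein)⁻¹ in the shipped files). The equations never fix
units themselves; a single configuration-level convention covers the
model.

## Steady states

Two-phase strategy: stiff integration (`lsoda`, relative tolerance 10⁻⁷)
over geometrically growing horizons, with a damped Newton refinement on
the moiety-reduced system attempted after every span (tolerance 10⁻¹²
on the scaled residual $\max_i |\dot S_i| / \max(S_i, 1\,\mathrm{mM})$).
The Newton step uses an SVD pseudo-inverse (numerically flat directions
are truncated) and falls back to a log-concentration iteration, which is
positivity-preserving and well-conditioned across concentration decades —
that variant is what closes in on steady states sitting across slow
manifolds (e.g. near-equilibrium hexose pools). Convergence defaults:
integration milestone 10⁻⁹, Newton 10⁻¹².

For *randomly sampled* models the test suite and the acceptance script use
a relaxed steady tolerance (10⁻⁶ scaled) and a bounded horizon: extreme
random parameterizations produce kinetically frozen modes whose
equilibration times exceed any relevant horizon while their residual is
already negligible relative to gross turnover. This is a numerical-policy
choice, stated here once; the reference models always use the strict
defaults.

## Metabolic control analysis

Finite-difference coefficients scale $V_{mf}$ and $V_{mr}$ jointly by
$(1\pm\delta)$, $\delta = 0.01$ by default — inside the linear regime but
large enough that re-solved steady states differ well above solver noise —
and use central differences of logarithms. The structural matrix method
computes $\Gamma = -L (N_R\,\varepsilon\,L)^{-1} N_R$ and
$C = I + \varepsilon\,\Gamma$ from the reduced stoichiometry, the link
matrix of the two conserved pools, and the unscaled elasticity matrix
(central differences of each rate law, step $10^{-6}$ relative). The two
routes agree to < 0.02 on every model tested, and the matrix route
satisfies $\Sigma_i C^J_i = 1$ and $\Sigma_i C^{S}_i = 0$ to machine
precision by construction, which makes it the structural oracle for the
finite-difference operator. Near-zero rates are reported with unscaled
elasticities and flagged rather than dividing by ~0.

## In-silico experiments

* `titration_scan()` scales enzyme activities (identical factor when
  several enzymes are titrated jointly) and records steady-state flux and
  readout metabolites, warm-starting each point from the previous one.
* `apply_feedback_scenario()` *removes* the Fru1,6BP/DHAP inhibition
  terms (term deletion, not a large $K_i$ — avoiding conditioning
  artifacts) from any subset of HK, HPI, TPI, GAPDH; the scenario letters
  a–e run from "no feedback anywhere" to the full model.
* `ki_scan()` rescales the three HPI inhibition constants jointly under a
  chosen mechanism and reports flux, Glc6P and the HPI flux-control
  coefficient, computed by the same `control_coefficients()` operator
  (single source of truth), default grid logarithmic over [0.01, 100].
  Inhibitor treatments (oxamate, iodoacetate) are modeled only as activity
  scalings of their target enzymes, not as explicit inhibitor species.
* The nominal "oxamate-like" point is ENO+PYK at 25 % activity; scans
  report a neighborhood rather than a single point.

## Synthetic data and what it does (not) show

`sample_model()` redraws binding/inhibition constants ($K$: 0.01–10 mM),
maximal velocities (1–1000 flux units), the allosteric constant $L$
(1–10⁶) and interaction factors (0.1–10) log-uniformly, keeps the
equilibrium constants fixed, derives $V_{mr}$ by Haldane, and leaves the
auxiliary closure steps (ATP demand, mitochondrial drains, glycogen
supply) at their reference kinetics — the prior expresses uncertainty in
the glycolytic enzymes proper, not in the cellular context. Observation
tables draw multiplicative lognormal noise (mean-preserving; CV default
0.3, resembling the dispersion of experimental metabolite tables) around
steady-state readouts. `recover_activity_factor()` inverts a joint
titration by 1-D least squares on log-residuals.

Passing tests on synthetic models show that the *pipeline* (assembly →
steady state → MCA → scans → comparison) is correct and calibrated under
the model's own assumptions. They do not show that real cells obey the
synthetic parameterization: no enzyme-level fitting to progress curves, no
pH/temperature corrections, no isoform-expression differences beyond the
two-isoform carriers, and no OxPhos coupling are included.

## Degenerate inputs and edge policies

* Transiently negative concentrations inside the stiff integrator are
  clamped to zero inside the rate laws (`clamp = TRUE` path); user-facing
  evaluation raises a state error instead.
* Missing species or constants are hard errors naming the reaction and
  the constant; isoform fractions must sum to 1 within 10⁻⁹.
* A perturbed model that fails to converge inside the finite-difference
  MCA is flagged `NA` and the run continues.
* Multistability has not been observed for the shipped models (steady
  states agree from 10× spread starting points to 10⁻⁶ relative); if a
  Newton polish lands on a different root than the integrator limit, the
  discrepancy surfaces in exactly that test.

## Known limitations

* The packaged parameterizations are synthetic stand-ins; quantitative
  control coefficients are parameterization-specific (signs and theorem
  structure are not).
* SBML import reconstructs rate-law families only for documents carrying
  the package's annotation; foreign kinetic laws are imported as opaque
  MathML-derived expressions (evaluable, scalable by an overall activity
  factor, but not family-aware).
* One in ~50 random prior draws has a steady state our solver does not
  reach within the bounded horizon (slow hexose-pool creep); it is
  reported as non-converged, never silently.

## Problem sizes used by the test and acceptance runs

Symbolic-vs-numeric agreement: 100 random states per model (both cell
lines). Equilibrium-zero: 10 random states per reversible reaction.
Synthetic sweeps: 50 models (test suite) / 30 models (acceptance script);
finite-difference cross-checks on a 4-enzyme subset of the first 5.
Recovery: 20 noise seeds (suite) / 10 (script), 3 replicates each. These
sizes were chosen to exercise every code path at stable statistics.
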
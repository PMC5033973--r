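# Synthetic reference parameter set: AS-30D rat hepatocarcinoma glycolysis.
#
# This file is a stand-in for a full experimental parameterization.  Every
# constant the source measurements fix is used verbatim (HPI Ki_DHAP =
# 9.4 mM; equilibrium constants are textbook thermodynamic values on the
# concentration scale); the remaining constants are physiological,
# literature-scale values chosen once so that the untreated steady state
# falls in the experimentally reported range (Fru1,6BP ~ 2.4 mM, DHAP ~
# 1.8 mM, Glc6P ~ 10 mM, ATP ~ 6 mM, lactate flux ~ 8 nmol/min/mg).
#
# Units: concentrations mM; maximal velocities nmol/min/mg protein.
# Species: FBP = Fru1,6BP; BPG = 1,3-bisphosphoglycerate; PG3/PG2 =
# 3-/2-phosphoglycerate; PG6 = 6-phosphogluconate; GLY = glycogen pool.
# Keq_thermo triggers Haldane closure of Vmr at build time.

name: AS30D_synthetic_reference
condition: AS30D
units: "nmol/min/mg protein; mM"
flux_reaction: LDH

fixed:
  Glc_out: 5.0
  Lac: 8.0
  Ery4P: 0.004
  PG6: 0.03
  F26BP: 0.005
  CIT: 1.5
  Pi: 5.0

initial:
  Glc_in: 0.7
  Glc6P: 8.0
  Fru6P: 2.0
  FBP: 2.5
  DHAP: 1.8
  G3P: 0.08
  BPG: 0.06
  PG3: 0.4
  PG2: 0.06
  PEP: 0.1
  Pyr: 1.0
  ATP: 6.0
  ADP: 2.5
  NAD: 0.45
  NADH: 0.05

totals:
  adenylate: 8.5
  nicotinamide: 0.5

reactions:
  GLUT:
    family: transporter_rev_mm
    stoich: {Glc_out: -1, Glc_in: 1}
    roles: {S: Glc_out, P: Glc_in}
    constants: {Vmf: 20.0, Keq: 1.0, Ks: 9.0, Kp: 9.0}
  HK:
    family: hk_random_bibi
    stoich: {Glc_in: -1, ATP: -1, Glc6P: 1, ADP: 1}
    roles: {A: Glc_in, B: ATP, P: Glc6P, Q: ADP, I: FBP}
    constants: {Vmf: 24.0, Keq: 651.0, Ka: 0.1, Kb: 1.1, Kp: 0.3,
                Kq: 3.5, alpha1: 1.0}
    inhibition: {Ki: 1.7, alpha2: 1.0}
  HPI:
    family: hpi_multi_inhib
    stoich: {Glc6P: -1, Fru6P: 1}
    roles: {S: Glc6P, P: Fru6P}
    constants: {Vmf: 60.0, Ks: 0.9, Kp: 0.12}
    mechanism: competitive
    inhibitors: {Ery4P: 0.002, PG6: 0.015, FBP: 0.6, DHAP: 9.4}
    Keq_thermo: 0.29
  PFK1:
    family: pfk1_mwc
    stoich: {Fru6P: -1, ATP: -1, FBP: 1, ADP: 1}
    roles: {S: Fru6P, ATP: ATP, ACT: F26BP, INH: CIT, P1: ADP, P2: FBP}
    constants: {Vm: 40.0, KATP: 0.06, KFru6P: 1.0, L: 10.0, KaF26BP: 0.005,
                KiCIT: 3.9, KiATP: 2.5, alpha: 0.32, beta: 1.2,
                KADP: 0.7, KFBP: 5.0, Keq: 247.0}
  ALDO:
    family: aldo_unibi
    stoich: {FBP: -1, DHAP: 1, G3P: 1}
    roles: {S: FBP, P1: DHAP, P2: G3P}
    constants: {Vmf: 12.0, Ks: 0.5, Kp1: 2.0, Kp2: 1.0}
    Keq_thermo: 0.069
  TPI:
    family: uni_uni_rev_mm
    stoich: {DHAP: -1, G3P: 1}
    roles: {S: DHAP, P: G3P, I: FBP}
    constants: {Vmf: 3000.0, Ks: 1.6, Kp: 0.4}
    inhibition: {Ki: 4.0, alpha: 5.0}
    Keq_thermo: 0.045
  GAPDH:
    family: gapdh_terbi
    stoich: {G3P: -1, NAD: -1, Pi: -1, BPG: 1, NADH: 1}
    roles: {A: NAD, B: G3P, C: Pi, P: BPG, Q: NADH, I: FBP}
    constants: {Vmf: 250.0, Ka: 0.09, Kb: 0.3, Kc: 3.5, Kp: 0.022,
                Kq: 0.01}
    inhibition: {Ki: 2.5, alpha: 4.0}
    Keq_thermo: 8.0e-05
  PGK:
    family: random_bibi
    stoich: {BPG: -1, ADP: -1, PG3: 1, ATP: 1}
    roles: {A: BPG, B: ADP, P: PG3, Q: ATP}
    constants: {Vmf: 2000.0, Ka: 0.025, Kb: 0.1, Kp: 0.6, Kq: 0.4,
                alpha: 1.0, beta: 1.0, cross_terms: false}
    Keq_thermo: 1800.0
  PGAM:
    family: uni_uni_rev_mm
    stoich: {PG3: -1, PG2: 1}
    roles: {S: PG3, P: PG2}
    constants: {Vmf: 1500.0, Ks: 0.19, Kp: 0.12}
    Keq_thermo: 0.15
  ENO:
    family: uni_uni_rev_mm
    stoich: {PG2: -1, PEP: 1}
    roles: {S: PG2, P: PEP}
    constants: {Vmf: 100.0, Ks: 0.038, Kp: 0.06}
    Keq_thermo: 4.6
  PYK:
    family: random_bibi
    stoich: {PEP: -1, ADP: -1, Pyr: 1, ATP: 1}
    roles: {A: PEP, B: ADP, P: Pyr, Q: ATP}
    constants: {Vmf: 200.0, Ka: 0.4, Kb: 0.3, Kp: 10.0, Kq: 0.86,
                alpha: 1.0, beta: 1.0, Keq: 10000.0, cross_terms: true}
  LDH:
    family: random_bibi
    stoich: {Pyr: -1, NADH: -1, Lac: 1, NAD: 1}
    roles: {A: NADH, B: Pyr, P: Lac, Q: NAD}
    constants: {Vmf: 8000.0, Ka: 0.01, Kb: 0.3, Kp: 4.7, Kq: 0.07,
                alpha: 1.0, beta: 1.0, cross_terms: false}
    Keq_thermo: 16000.0
  ATPase:
    family: mm_irrev
    stoich: {ATP: -1, ADP: 1}
    roles: {S: ATP}
    constants: {Vmf: 60.0, Ks: 30.0}
  # Auxiliary mitochondrial drains closing the redox/carbon balance:
  # pyruvate oxidation and NADH re-oxidation (shuttles).  Without them the
  # lower pathway + NADH would carry an artificial conservation.
  PYRox:
    family: mm_irrev
    stoich: {Pyr: -1}
    roles: {S: Pyr}
    constants: {Vmf: 3.0, Ks: 0.5}
  NADHox:
    family: mm_irrev
    stoich: {NADH: -1, NAD: 1}
    roles: {S: NADH}
    constants: {Vmf: 3.0, Ks: 0.05}
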
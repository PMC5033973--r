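# Synthetic reference parameter set: HeLa glycolysis, normoglycemic (5 mM glucose) culture.
#
# Stand-in for a full experimental parameterization (see the AS-30D file
# for conventions).  The HPI inhibition constants are the experimentally
# anchored values (Ki_Ery4P = 1 uM, Ki_Fru1,6BP = 60 uM, Ki_6PG = 15 uM);
# DHAP is not an HPI inhibitor here (Ki_DHAP = 9.4 mM is far above its
# physiological 0.5-0.8 mM).  The glucose transporter and hexokinase are
# two-isoform forms; glycogen degradation supplies Glc6P; the
# monocarboxylate transporter (MCT) exports lactate and defines the
# pathway flux.  Under hypoglycemia extracellular glucose and the GLUT
# maximal velocity intermediate; control shared by GLUT and HK.

name: HeLa_normo_synthetic_reference
condition: HeLa_normo
units: "nmol/min/mg protein; mM"
flux_reaction: MCT

fixed:
  Glc_out: 5.0
  Lac_out: 1.0
  Ery4P: 0.004
  PG6: 0.03
  F26BP: 0.005
  CIT: 1.5
  Pi: 5.0
  GLY: 1.0

initial:
  Glc_in: 0.2
  Glc6P: 2.0
  Fru6P: 0.5
  FBP: 2.0
  DHAP: 0.6
  G3P: 0.03
  BPG: 0.001
  PG3: 0.1
  PG2: 0.015
  PEP: 0.03
  Pyr: 0.1
  Lac_in: 2.0
  ATP: 5.0
  ADP: 2.5
  NAD: 0.45
  NADH: 0.01

totals:
  adenylate: 7.5
  nicotinamide: 0.46

reactions:
  GLUT:
    family: transporter_rev_mm
    stoich: {Glc_out: -1, Glc_in: 1}
    roles: {S: Glc_out, P: Glc_in}
    constants: {Vmf: 14.0, Keq: 1.0}
    isoforms:
      - {f: 0.65, Ks: 1.5, Kp: 1.5}
      - {f: 0.35, Ks: 9.0, Kp: 9.0}
  HK:
    family: hk_random_bibi
    stoich: {Glc_in: -1, ATP: -1, Glc6P: 1, ADP: 1}
    roles: {A: Glc_in, B: ATP, P: Glc6P, Q: ADP}
    constants: {Vmf: 12.0, Keq: 651.0, Kb: 1.1, Kp: 0.1, Kq: 3.5,
                alpha1: 1.0}
    isoforms:
      - {f: 0.7, Ka: 0.1}
      - {f: 0.3, Ka: 0.35}
  HPI:
    family: hpi_multi_inhib
    stoich: {Glc6P: -1, Fru6P: 1}
    roles: {S: Glc6P, P: Fru6P}
    constants: {Vmf: 250.0, Ks: 0.9, Kp: 0.12}
    mechanism: competitive
    inhibitors: {Ery4P: 0.001, FBP: 0.06, PG6: 0.015}
    Keq_thermo: 0.29
  PFK1:
    family: pfk1_mwc
    stoich: {Fru6P: -1, ATP: -1, FBP: 1, ADP: 1}
    roles: {S: Fru6P, ATP: ATP, ACT: F26BP, INH: CIT, P1: ADP, P2: FBP}
    constants: {Vm: 35.0, KATP: 0.06, KFru6P: 1.0, L: 10.0, KaF26BP: 0.005,
                KiCIT: 3.9, KiATP: 2.5, alpha: 0.32, beta: 1.2,
                KADP: 0.7, KFBP: 5.0, Keq: 247.0}
  ALDO:
    family: aldo_unibi
    stoich: {FBP: -1, DHAP: 1, G3P: 1}
    roles: {S: FBP, P1: DHAP, P2: G3P}
    constants: {Vmf: 14.0, Ks: 0.5, Kp1: 2.0, Kp2: 1.0}
    Keq_thermo: 0.069
  TPI:
    family: uni_uni_rev_mm
    stoich: {DHAP: -1, G3P: 1}
    roles: {S: DHAP, P: G3P}
    constants: {Vmf: 3000.0, Ks: 1.6, Kp: 0.4}
    Keq_thermo: 0.045
  GAPDH:
    family: gapdh_terbi
    stoich: {G3P: -1, NAD: -1, Pi: -1, BPG: 1, NADH: 1}
    roles: {A: NAD, B: G3P, C: Pi, P: BPG, Q: NADH}
    constants: {Vmf: 400.0, Ka: 0.09, Kb: 0.3, Kc: 3.5, Kp: 0.022,
                Kq: 0.01}
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
    stoich: {Pyr: -1, NADH: -1, Lac_in: 1, NAD: 1}
    roles: {A: NADH, B: Pyr, P: Lac_in, Q: NAD}
    constants: {Vmf: 8000.0, Ka: 0.01, Kb: 0.3, Kp: 4.7, Kq: 0.07,
                alpha: 1.0, beta: 1.0, cross_terms: false}
    Keq_thermo: 16000.0
  MCT:
    family: transporter_rev_mm
    stoich: {Lac_in: -1, Lac_out: 1}
    roles: {S: Lac_in, P: Lac_out}
    constants: {Vmf: 120.0, Keq: 1.0, Ks: 4.5, Kp: 30.0}
  GLYdeg:
    family: mm_irrev
    stoich: {GLY: -1, Glc6P: 1}
    roles: {S: GLY}
    constants: {Vmf: 1.5, Ks: 0.5}
  ATPase:
    family: mm_irrev
    stoich: {ATP: -1, ADP: 1}
    roles: {S: ATP}
    constants: {Vmf: 60.0, Ks: 30.0}
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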
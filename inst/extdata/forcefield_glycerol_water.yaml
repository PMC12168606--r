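# Reference force-field parameters for the glycerol-water mixture model.
#
# Charges and Lennard-Jones values for glycerol are adapted from the
# OPLS-derived set used in published empirical-potential structure-refinement
# studies of glycerol-water mixtures (Towey, Soper & Dougan, J. Phys. Chem. B
# 2011, 115, 7799); water is the SPC/E model of Berendsen, Grigera &
# Straatsma (J. Phys. Chem. 1987, 91, 6269). Harmonic bond force constants
# are nominal AMBER-like values; molecular skeletons are propagated rigidly
# during Monte Carlo so only the equilibrium lengths shape the results.
#
# units: charge e, epsilon kJ/mol, sigma A, bond length A,
#        bond force constant kJ/mol/A^2
atom_types:
  C:  {epsilon: 0.276, sigma: 3.50}   # glycerol carbon
  OG: {epsilon: 0.711, sigma: 3.12}   # glycerol hydroxyl oxygen
  HC: {epsilon: 0.126, sigma: 2.40}   # glycerol aliphatic hydrogen
  HG: {epsilon: 0.0,   sigma: 0.0}    # glycerol hydroxyl hydrogen
  OW: {epsilon: 0.6502, sigma: 3.166} # water oxygen (SPC/E)
  HW: {epsilon: 0.0,   sigma: 0.0}    # water hydrogen (SPC/E)
charges:
  glycerol:
    C_terminal: 0.145     # C1, C3
    C_central:  0.205     # C2
    OG: -0.683
    HG: 0.418
    HC: 0.060
  water:
    OW: -0.8476
    HW: 0.4238
geometry:
  glycerol:
    cc_bond: 1.526
    co_bond: 1.430
    ch_bond: 1.090
    oh_bond: 0.970
    ccc_angle: 112.0
    cco_angle: 110.0
    coh_angle: 108.5
  water:
    oh_bond: 1.000
    hoh_angle: 109.47
bond_force_constants:
  cc: 2600.0
  co: 2700.0
  ch: 2900.0
  oh: 4600.0
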
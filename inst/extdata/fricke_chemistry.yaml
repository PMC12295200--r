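# Species registry and reaction network for acidic (sulfuric) water radiolysis
# and Fricke dosimeter chemistry at 25 C.
#
# Units: diffusion coefficients D in m^2/s (unscaled, aqueous solution at
# 25 C); bimolecular rate constants k in 1/M/s at infinite dilution (zero
# ionic strength). Element counts refer to atoms; charge in elementary units.
#
# D values are standard aqueous compilations; Fe3+ uses 2.0e-9 m^2/s, the
# value adopted for the standard Fricke solution in this model.
#
# sigma_class assigns each species to one of the two Gaussian width classes of
# the synthetic 1-ps track generator: "electron" (thermalised hydrated
# electrons, wide) or "radical" (species born at ionisation/excitation sites,
# narrow).

species:
  e_aq:   {charge: -1, D: 4.90e-9, elements: {},                   sigma_class: electron}
  H3Op:   {charge:  1, D: 9.46e-9, elements: {H: 3, O: 1},         sigma_class: radical}
  OHm:    {charge: -1, D: 5.30e-9, elements: {H: 1, O: 1},         sigma_class: radical}
  H:      {charge:  0, D: 7.00e-9, elements: {H: 1},               sigma_class: radical}
  H2:     {charge:  0, D: 4.80e-9, elements: {H: 2},               sigma_class: radical}
  OH:     {charge:  0, D: 2.20e-9, elements: {H: 1, O: 1},         sigma_class: radical}
  H2O2:   {charge:  0, D: 2.30e-9, elements: {H: 2, O: 2},         sigma_class: radical}
  HO2:    {charge:  0, D: 2.30e-9, elements: {H: 1, O: 2},         sigma_class: radical}
  HO2m:   {charge: -1, D: 2.30e-9, elements: {H: 1, O: 2},         sigma_class: radical}
  O2:     {charge:  0, D: 2.40e-9, elements: {O: 2},               sigma_class: radical}
  O2m:    {charge: -1, D: 2.40e-9, elements: {O: 2},               sigma_class: radical}
  H2O:    {charge:  0, D: 2.30e-9, elements: {H: 2, O: 1},         sigma_class: radical}
  Fe2p:   {charge:  2, D: 0.72e-9, elements: {Fe: 1},              sigma_class: radical}
  Fe3p:   {charge:  3, D: 2.00e-9, elements: {Fe: 1},              sigma_class: radical}
  HSO4m:  {charge: -1, D: 1.39e-9, elements: {H: 1, S: 1, O: 4},   sigma_class: radical}
  SO4m2:  {charge: -2, D: 1.07e-9, elements: {S: 1, O: 4},         sigma_class: radical}
  SO4rm:  {charge: -1, D: 1.00e-9, elements: {S: 1, O: 4},         sigma_class: radical}
  S2O8m2: {charge: -2, D: 1.00e-9, elements: {S: 2, O: 8},         sigma_class: radical}

# control:
#   fully      - diffusion limited; k_act treated as infinite, effective
#                reaction radius solved from k = 4 pi (D1+D2) R N_A.
#   partial    - partially diffusion controlled; contact radius assumed
#                (R_contact below), k_act solved from the Noyes relation
#                1/k = 1/k_act + 1/k_diff.
#   activation - far below the diffusion limit; treated with the same
#                radiation-boundary partition (encounter probability is
#                negligible, scavenging-style kinetics dominate).
# water: net number of H2O molecules appearing as implicit reactant (negative)
# or product (positive); the solvent is not tracked as particles but enters
# the charge/element balance.
# salt_exempt: excluded from the kinetic ionic-strength correction
# (hydrated-electron self-recombination only).

R_contact: 0.45e-9   # m; assumed encounter distance for partial/activation reactions

reactions:
  - {id: e_e,       reactants: [e_aq, e_aq],   products: [H2, OHm, OHm], water: -2, k: 5.5e9,  control: partial, salt_exempt: true}
  - {id: e_H,       reactants: [e_aq, H],      products: [H2, OHm],      water: -1, k: 2.5e10, control: fully}
  - {id: e_OH,      reactants: [e_aq, OH],     products: [OHm],          water: 0,  k: 3.0e10, control: fully}
  - {id: e_H2O2,    reactants: [e_aq, H2O2],   products: [OH, OHm],      water: 0,  k: 1.1e10, control: fully}
  - {id: e_H3Op,    reactants: [e_aq, H3Op],   products: [H, H2O],       water: 0,  k: 2.1e10, control: fully}
  - {id: e_O2,      reactants: [e_aq, O2],     products: [O2m],          water: 0,  k: 1.9e10, control: fully}
  - {id: H_H,       reactants: [H, H],         products: [H2],           water: 0,  k: 7.8e9,  control: partial}
  - {id: H_OH,      reactants: [H, OH],        products: [H2O],          water: 0,  k: 7.0e9,  control: partial}
  - {id: H_H2O2,    reactants: [H, H2O2],      products: [OH, H2O],      water: 0,  k: 9.0e7,  control: activation}
  - {id: OH_OH,     reactants: [OH, OH],       products: [H2O2],         water: 0,  k: 5.5e9,  control: partial}
  - {id: OH_H2,     reactants: [OH, H2],       products: [H, H2O],       water: 0,  k: 4.2e7,  control: activation}
  - {id: H_O2,      reactants: [H, O2],        products: [HO2],          water: 0,  k: 1.3e10, control: fully}
  - {id: OH_HO2,    reactants: [OH, HO2],      products: [O2, H2O],      water: 0,  k: 8.8e9,  control: partial}
  - {id: H_HO2,     reactants: [H, HO2],       products: [H2O2],         water: 0,  k: 1.0e10, control: fully}
  - {id: OH_Fe2p,   reactants: [OH, Fe2p],     products: [Fe3p, OHm],    water: 0,  k: 3.4e8,  control: partial}
  - {id: HO2_Fe2p,  reactants: [HO2, Fe2p],    products: [Fe3p, HO2m],   water: 0,  k: 7.9e5,  control: activation}
  - {id: H2O2_Fe2p, reactants: [H2O2, Fe2p],   products: [Fe3p, OH, OHm], water: 0, k: 52,     control: activation}
  - {id: OH_HSO4m,  reactants: [OH, HSO4m],    products: [SO4rm, H2O],   water: 0,  k: 1.5e5,  control: activation}
  - {id: SO4_Fe2p,  reactants: [SO4rm, Fe2p],  products: [Fe3p, SO4m2],  water: 0,  k: 9.9e8,  control: partial}
  - {id: SO4_SO4,   reactants: [SO4rm, SO4rm], products: [S2O8m2],       water: 0,  k: 8.1e8,  control: partial}

# Acid-side prototropic equilibria: at pH <= 1.3 these lie fully on the acid
# side and protonation by bulk H3O+ is complete on sub-ns timescales, i.e.
# faster than any competing channel by >= 10^3. They are applied as immediate
# transformations of the basic form, consuming one bulk hydronium each.
instant_transforms:
  - {id: OHm_H3Op,  from: OHm,  to: ~,    water: 2, k: 1.1e11}   # neutralisation; product is solvent
  - {id: HO2m_H3Op, from: HO2m, to: H2O2, water: 1, k: 5.0e10}
  - {id: O2m_H3Op,  from: O2m,  to: HO2,  water: 1, k: 5.0e10}
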
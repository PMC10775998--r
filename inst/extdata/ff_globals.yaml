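# Global constants of the coarse-grained HPS energy model.
# Units: bond_k kcal/(mol A^2); bond_b0 A; epsilon kcal/mol; debye_kappa A.
# b0_ref is the rounded equilibrium bond length used in the reference
# pervaded volume V0 = (4*pi/3) * b0_ref^3 * (N/6)^(3/2).
# coulomb_const is e^2/(4*pi*eps0) in kcal*A/mol, so that
# phi_el = coulomb_const * qi*qj / (dielectric * r) * exp(-r/debye_kappa).
bond_k: 10.0
bond_b0: 3.82
epsilon: 0.2
dielectric: 80.0
debye_kappa: 10.0
b0_ref: 3.8
coulomb_const: 332.0637
temperature: 300.0
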
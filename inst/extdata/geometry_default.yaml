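# Standard unstirred skin-PAMPA sandwich.
# Units: cm^3, cm^2, s, mol cm^-3. Every value can be overridden.
V_D: 0.3
V_A: 0.4
A_filter: 0.28
porosity: 0.7
t_incubation: 25200
tau_lag: 1200
C_D0_nominal: 1.0e-7
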
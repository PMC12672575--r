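# RSFP photocycle rate parameters
# units: cross-sections cm^2, rates 1/s, lifetimes s, yields dimensionless
label: rsEGFP2-default-v1
sigma.C_MINUS.488: 2.34e-16
sigma.C_MINUS.405: 5e-18
sigma.C_INT.405: 3e-17
sigma.C_INT.488: 2e-16
sigma.TH.405: 8.4e-17
sigma.T1.405: 1e-18
sigma.T1.488: 5e-20
sigma.T1.592: 6.6326518e-18
sigma.T1.810: 6.6326518e-18
sigma.T1.900: 3.3163259e-17
sigma.T1.915: 1.5642061e-17
sigma.D_REV.488: 1e-16
phi_off: 0.005373435947
phi_isc: 0.008
phi_bleach_on: 1e-07
phi_on: 0.33
phi_int_off: 0.4876449681
phi_int_bleach: 2e-05
phi_risc: 0.1
phi_tn: 1e-05
tau_t: 0.00140450144
f_drev: 0.1827094108
phi_t1: 0.0004214479226
k_prot: 20000
k_deprot: 200000
k_int: 1000
k_drev: 8.822458156
beta: 1
w_cint: 1
phi_drev_bleach: 9.258046336e-07
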
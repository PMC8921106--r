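# chlordecone PBPK parameter set
# units: clearances L/h, rates 1/h, binding capacity ug/L,
# partition coefficients and fractions dimensionless
species: rat
BIND: 0.9
CL_bile: 0.0028674172
f_dead_space: 0.33
f_dist: 0.02
f_lymph: 0.3
f_prox: 0.98
F_reab: 0.88432914
f_reconv: 0.9
f_skin_exposed: 0.1
k_abs: 3.0
k_ent: 0.00044701498
k_fec: 0.35
k_lymph: 0.1
k_urine: 2.9951299e-05
KA: 0.9
KBILE: 0.0
KD_LIV: 10.0
KP_derm: 0.01
KST: 0.25
LIBMAXCD1: 4249.204499999999825
P_adipose: 220.475619999999992
P_blood_air: 20.0
P_brain: 8.0
P_liver: 10.0
P_lung: 5.0
P_rest: 4.0
P_skin: 7.0
PA_adipose: 0.00085411782
PA_brain: 0.05
PA_liver: 1.5
PA_skin: 0.05
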
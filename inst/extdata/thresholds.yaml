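# Default categorization cut-points for continuous covariates.
# These are clinically conventional reference-range placeholders chosen by
# this package; they are NOT taken from any study's supplementary materials.
# Units: labs as in patients.csv (mmol/L unless noted).
ldl_c: [3.4]        # mmol/L
hcy: [15]           # umol/L
hs_crp: [3]         # mg/L
nt_probnp: [1800]   # pg/mL
k: [3.5, 5.5]
na: [135, 145]
cl: [96, 106]
mg: [0.75, 1.02]
lvef: [40, 50]      # percent
lvmi: [115]         # g/m^2
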
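# Propofol (2,6-diisopropylphenol) physicochemical and disposition parameters
# used to build the canine PBPK model. Units as stated per field.
name: propofol
molecular_weight: 178.27      # g/mol
pka_acid: 11.1                # acid dissociation constant (neutral at physiologic pH)
logp: 3.49                    # lipophilicity (optimized value; literature 3.79)
solubility_ref: 0.12          # mg/mL at reference pH
bp_ratio: 2.36                # blood:plasma concentration ratio (optimized)
fu_plasma: 0.02               # unbound fraction in plasma (2%)
hepatic_clearance_spec: 47.08 # mL/min/kg, specified unspecific hepatic clearance
kp_scale: 1.0                 # global tissue:plasma partition calibration factor
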
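# Reference canine whole-body physiology for the flow-limited PBPK model.
#
# Assembled from published canine anatomy/physiology compilations (reference
# organ weights, regional blood flows and tissue composition tables commonly
# used to parameterize small-molecule PBPK models). Values are for a healthy,
# lean adult laboratory dog (skeletal muscle ~50% of body weight, adipose
# ~10%, adipose perfusion ~2% of cardiac output) and scale with body weight:
# volumes linearly (BW^1.0), cardiac output and all regional flows
# allometrically (BW^0.75 by default).
#
# volume_fraction: organ volume as fraction of body weight (1 kg/L density)
# flow_fraction:   organ blood flow as fraction of cardiac output; the sum
#                  over systemic organs is exactly 1 (lung carries the whole
#                  cardiac output in series and is listed with 1.0)
# f_*:             tissue composition mass fractions (water, neutral lipid,
#                  phospholipid, protein) used by the partition-coefficient
#                  schemes
reference_body_weight_kg: 10.5
cardiac_output_ml_min_per_kg075: 240.0   # CO = 240 * BW^0.75 mL/min (~1.4 L/min at 10.5 kg)
flow_exponent: 0.75
hematocrit: 0.45
venous_blood_fraction: 0.055
arterial_blood_fraction: 0.027
plasma_composition:
  f_water: 0.945
  f_neutral_lipid: 0.0023
  f_phospholipid: 0.0013
  f_protein: 0.074
organs:
  - {name: lung,   volume_fraction: 0.0080, flow_fraction: 1.000, f_water: 0.81, f_neutral_lipid: 0.022,  f_phospholipid: 0.0128, f_protein: 0.130}
  - {name: liver,  volume_fraction: 0.0330, flow_fraction: 0.045, f_water: 0.75, f_neutral_lipid: 0.014,  f_phospholipid: 0.0240, f_protein: 0.160}
  - {name: kidney, volume_fraction: 0.0055, flow_fraction: 0.170, f_water: 0.79, f_neutral_lipid: 0.012,  f_phospholipid: 0.0242, f_protein: 0.130}
  - {name: brain,  volume_fraction: 0.0080, flow_fraction: 0.060, f_water: 0.77, f_neutral_lipid: 0.051,  f_phospholipid: 0.0565, f_protein: 0.080}
  - {name: heart,  volume_fraction: 0.0080, flow_fraction: 0.045, f_water: 0.76, f_neutral_lipid: 0.014,  f_phospholipid: 0.0111, f_protein: 0.150}
  - {name: muscle, volume_fraction: 0.5000, flow_fraction: 0.270, f_water: 0.76, f_neutral_lipid: 0.022,  f_phospholipid: 0.0072, f_protein: 0.177}
  - {name: fat,    volume_fraction: 0.1000, flow_fraction: 0.020, f_water: 0.18, f_neutral_lipid: 0.790,  f_phospholipid: 0.0020, f_protein: 0.020}
  - {name: skin,   volume_fraction: 0.0900, flow_fraction: 0.060, f_water: 0.72, f_neutral_lipid: 0.060,  f_phospholipid: 0.0044, f_protein: 0.160}
  - {name: gut,    volume_fraction: 0.0400, flow_fraction: 0.180, f_water: 0.74, f_neutral_lipid: 0.049,  f_phospholipid: 0.0163, f_protein: 0.150}
  - {name: spleen, volume_fraction: 0.0026, flow_fraction: 0.020, f_water: 0.78, f_neutral_lipid: 0.0077, f_phospholipid: 0.0136, f_protein: 0.130}
  - {name: bone,   volume_fraction: 0.0800, flow_fraction: 0.040, f_water: 0.44, f_neutral_lipid: 0.074,  f_phospholipid: 0.0011, f_protein: 0.200}
  - {name: rest,   volume_fraction: 0.0400, flow_fraction: 0.090, f_water: 0.76, f_neutral_lipid: 0.040,  f_phospholipid: 0.0100, f_protein: 0.150}
# portal organs drain through the liver; the liver's own flow_fraction above
# is the hepatic-artery share, so total hepatic flow = 0.045 + 0.180 + 0.020
portal_organs: [gut, spleen]
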
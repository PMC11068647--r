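# Antihypertensive drug catalogue: per-drug target effects applied through
# the influence function F = 1 +/- E * d. Doses (mg) are identifiers only.
# Magnitudes E were calibrated once against the default high-ACE patient
# (cACE = 54.1 1/h) so that each monotherapy lowers SBP by about 5-15 mmHg.
aliskiren:
  dose: 300
  effects:
    - {target: renin_activity, sign: inhibition, E: 0.60}
enalapril:
  dose: 20
  effects:
    - {target: ace_activity, sign: inhibition, E: 0.75}
losartan:
  dose: 100
  effects:
    - {target: at1_receptor, sign: inhibition, E: 0.65}
bisoprolol:
  dose: 5
  effects:
    - {target: heart_rate, sign: inhibition, E: 0.12}
    - {target: contractility, sign: inhibition, E: 0.15}
    - {target: renin_secretion, sign: inhibition, E: 0.58}
    - {target: arterial_elastance, sign: inhibition, E: 0.10}
amlodipine:
  dose: 5
  effects:
    - {target: vascular_tone, sign: inhibition, E: 0.14}
    - {target: afferent_tone, sign: inhibition, E: 0.25}
    - {target: sodium_reabsorption, sign: inhibition, E: 0.0010}
hydrochlorothiazide:
  dose: 12.5
  effects:
    - {target: sodium_reabsorption, sign: inhibition, E: 0.0025}
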
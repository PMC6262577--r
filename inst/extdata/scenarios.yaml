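# Named study-condition presets for the synthetic generators.
# Permeabilities in cm/s, Ea in kcal/mol, IC50 in umol/L, pKa in pH units.
version: 1
stopped_flow:
  haqp7_ph74:
    pf: 4.38e-4
    pgly: 1.31e-5
  control:
    pf: 2.91e-4
    pgly: 1.2e-7
  haqp7_ph50:
    # acid-blocked channel: ~10% residual permeability, consistent with
    # the >90% reduction seen at pH 5.0
    pf: 0.44e-4
    pgly: 1.31e-6
  auphen_treated:
    # 34% Pf and 84% PGly inhibition applied to haqp7_ph74
    pf: 2.89e-4
    pgly: 2.10e-6
shock:
  tonicity: 1.25
  permeant_gradient: 0.35
  iso_osm: 1.4
  temperature_K: 296.15
geometry:
  radius_cm: 2.5e-4
  beta: 0.5
  vw: 18
gating:
  pka_water_wt: 5.88
  pka_glycerol_wt: 5.85
  pka_glycerol_h165a: 6.30
  ea_water_haqp7: 9.16
  ea_glycerol_haqp7: 10.55
  ea_water_control: 15.06
  ea_glycerol_control: 23.20
  ic50_auphen: 12.95
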
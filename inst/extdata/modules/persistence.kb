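# Persistence screening module.
# Thresholds are configuration defaults taken from the OECD 301
# ready-biodegradability pass levels (60% ThCO2 / ThOD, 70% DOC removal)
# and the REACH Annex XIII half-life criteria for water (P > 40 d,
# vP > 60 d). Edit the rule literals to override.
MODULE Persistence
QUESTIONS
  ThCO2 "Degradation after 28 d [% of theoretical CO2 evolution]" numeric unit=% explain="Ready biodegradability endpoint; the OECD pass level is 60%."
  ThOD "Degradation after 28 d [% of theoretical oxygen demand]" numeric unit=% explain="Ready biodegradability endpoint; the OECD pass level is 60%."
  DOC "Removal after 28 d [% dissolved organic carbon]" numeric unit=% explain="Ready biodegradability endpoint; the OECD pass level is 70%."
  dt50_water "Degradation half-life in fresh water" numeric unit=d explain="Half-life above 40 d fulfils P, above 60 d vP (water)."
DECISIONS
  nrb "Not readily biodegradable"
  P "P criterion fulfilled (persistent)"
    vP "vP criterion fulfilled (very persistent)"
RULES
  RULE r_nrb: IF OR(ThCO2 < 60, ThOD < 60, DOC < 70) THEN nrb P7
  RULE r_rb: IF AND(ThCO2 >= 60, ThOD >= 60, DOC >= 70) THEN nrb N7
  RULE r_p_halflife: IF dt50_water > 40 THEN P P7
  RULE r_p_screen: IF state(nrb) = established THEN P P3
  RULE r_vp: IF dt50_water > 60 THEN vP P7
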
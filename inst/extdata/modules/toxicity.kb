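# Toxicity module (aquatic long-term + CMR shortcut).
# T thresholds follow the REACH Annex XIII convention: chronic NOEC
# below 0.01 mg/L, or classification as carcinogenic.
MODULE Toxicity
QUESTIONS
  chronic_noec "Chronic NOEC, aquatic organisms" numeric unit=mg/L explain="Lowest reliable long-term no-observed-effect concentration."
  carcinogenic "Classified as carcinogenic (cat. 1A/1B)?" one_choice(yes, no, unknown)
DECISIONS
  T "T criterion fulfilled (toxic)"
RULES
  RULE r_t_noec: IF chronic_noec < 0.01 THEN T P7
  RULE r_t_carc: IF carcinogenic = yes THEN T P7
  RULE r_t_neg: IF AND(chronic_noec >= 0.01, carcinogenic = no) THEN T N7
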
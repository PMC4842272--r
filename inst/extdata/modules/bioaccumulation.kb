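# Bioaccumulation assessment as a diagnostic workflow: the B/vB decisions
# hinge on the value and source of the bioconcentration factor (BCF).
# BCF thresholds follow the REACH Annex XIII convention
# (B: BCF >= 2000 L/kg, vB: BCF >= 5000 L/kg); the log Kow screen
# (>= 4.5) only *suggests* B when no measured BCF exists.
MODULE Bioaccumulation
QUESTIONS
  bcf_available "Is a measured BCF available?" one_choice(yes, no) explain="A measured, reliable bioconcentration factor from a fish study."
  BCF "Bioconcentration factor" numeric unit=L/kg explain="Concentration ratio organism/water at steady state."
  log_kow "log Kow (octanol-water partition coefficient)" numeric explain="Screening surrogate for bioaccumulation potential."
DECISIONS
  B "B criterion fulfilled (bioaccumulative)"
    vB "vB criterion fulfilled (very bioaccumulative)"
FLOW bioaccumulation
  START s
  ASK a_avail bcf_available
  ASK a_bcf BCF
  ASK a_kow log_kow
  DECIDE d_vb vB established
  DECIDE d_vb_b B established
  DECIDE d_b B established
  DECIDE d_notb B excluded
  DECIDE d_b_sugg B suggested
  EXIT x
  EDGE s -> a_avail
  EDGE a_avail -> a_bcf IF bcf_available = yes
  EDGE a_avail -> a_kow IF bcf_available = no
  EDGE a_bcf -> d_vb IF BCF >= 5000
  EDGE a_bcf -> d_b IF AND(BCF >= 2000, BCF < 5000)
  EDGE a_bcf -> d_notb IF BCF < 2000
  EDGE d_vb -> d_vb_b
  EDGE d_vb_b -> x
  EDGE d_b -> x
  EDGE d_notb -> x
  EDGE a_kow -> d_b_sugg IF log_kow >= 4.5
  EDGE a_kow -> x IF log_kow < 4.5
  EDGE d_b_sugg -> x
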
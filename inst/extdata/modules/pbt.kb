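# Final PBT / vPvB assessment: reuses the decisions derived by the
# Persistence, Bioaccumulation and Toxicity modules.
MODULE PBT
DEPENDS Persistence, Bioaccumulation, Toxicity
DECISIONS
  PBT "PBT (persistent, bioaccumulative, toxic)"
  vPvB "vPvB (very persistent, very bioaccumulative)"
RULES
  RULE r_pbt: IF AND(state(P) = established, state(B) = established, state(T) = established) THEN PBT P7
  RULE r_vpvb: IF AND(state(vP) = established, state(vB) = established) THEN vPvB P7
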
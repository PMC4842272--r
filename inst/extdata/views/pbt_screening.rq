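# Substances currently screened as PBT: driven by the mirrored formal
# decision state, not by the static property assertions — this list follows
# every retraction or new derivation.
PREFIX ks: <http://example.org/knowsub/ks#>
SELECT ?label ?ec ?cas WHERE {
  ?s ks:hasDecision ?d .
  ?d ks:decisionId "PBT" .
  ?d ks:decisionState "established" .
  ?s ks:hasLabel ?label .
  OPTIONAL { ?s ks:hasEC ?ec . }
  OPTIONAL { ?s ks:hasCAS ?cas . }
}
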
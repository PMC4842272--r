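# Overview list: every substance with identifiers and any mirrored
# decision (columns: label, EC, CAS, decision, state).
PREFIX ks: <http://example.org/knowsub/ks#>
SELECT ?label ?ec ?cas ?decision ?state WHERE {
  ?s a ks:Substance .
  ?s ks:hasLabel ?label .
  OPTIONAL { ?s ks:hasEC ?ec . }
  OPTIONAL { ?s ks:hasCAS ?cas . }
  OPTIONAL {
    ?s ks:hasDecision ?d .
    ?d ks:decisionId ?decision .
    ?d ks:decisionState ?state .
  }
}
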
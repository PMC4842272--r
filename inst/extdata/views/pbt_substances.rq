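# All PBT substances and their labels: substances carrying the persistent,
# bioaccumulative and toxic chemical properties (the PBT class pattern).
PREFIX ks: <http://example.org/knowsub/ks#>
SELECT ?label WHERE {
  ?s a ks:Substance .
  ?s ks:hasChemProperty ks:persistent .
  ?s ks:hasChemProperty ks:bioaccumulative .
  ?s ks:hasChemProperty ks:toxic .
  ?s ks:hasLabel ?label .
}
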
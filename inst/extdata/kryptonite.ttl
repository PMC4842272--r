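# Worked example: the fantasy substance Kryptonite.
# The CAS and EC values are SYNTHETIC (reserved high-number style), chosen
# to be clearly fictional yet checksum-valid so identifier QC passes:
#   CAS 9999999-99-5  (weighted sum 405, 405 mod 10 = 5)
#   EC  999-999-2     (weighted sum 189, 189 mod 11 = 2)
@prefix ks: <http://example.org/knowsub/ks#> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .

ks:Substance a rdfs:Class .
ks:ChemProperty a rdfs:Class .

ks:persistent a ks:ChemProperty ;
    ks:hasLabel "persistent" .
ks:bioaccumulative a ks:ChemProperty ;
    ks:hasLabel "bioaccumulative" .
ks:toxic a ks:ChemProperty ;
    ks:hasLabel "toxic" .

ks:Kryptonite a ks:Substance ;
    ks:hasLabel "Kryptonite" ;
    ks:hasCAS "9999999-99-5" ;
    ks:hasEC "999-999-2" ;
    ks:hasMemo "Fictional reference substance used for demonstrations." ;
    ks:hasChemProperty ks:persistent , ks:bioaccumulative , ks:toxic .
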
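@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix obo: <http://www.geneontology.org/formats/oboInOwl#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix : <http://example.org/ddo-mini#> .

:C0001 a owl:Class ;
    rdfs:label "oral hypoglycemic" ;
    obo:hasExactSynonym "oral antidiabetic" ;
    rdfs:comment "not a term source" .

:C0002 a owl:Class ;
    rdfs:label "blood sugar"@en ;
    obo:hasRelatedSynonym "blood glucose" .

:C0003 a owl:Class ;
    rdfs:label "metformin" .
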
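<?xml version="1.0"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#"
         xmlns:oboInOwl="http://www.geneontology.org/formats/oboInOwl#">
  <owl:Ontology rdf:about="http://example.org/ddo-mini"/>
  <owl:Class rdf:about="http://example.org/ddo-mini#C0001">
    <rdfs:label>oral hypoglycemic</rdfs:label>
    <oboInOwl:hasExactSynonym>oral antidiabetic</oboInOwl:hasExactSynonym>
    <rdfs:comment>not a term source</rdfs:comment>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/ddo-mini#C0002">
    <rdfs:label>blood sugar</rdfs:label>
    <oboInOwl:hasRelatedSynonym>blood glucose</oboInOwl:hasRelatedSynonym>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/ddo-mini#C0003">
    <rdfs:label>metformin</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://example.org/ddo-mini#C0001"/>
  </owl:Class>
</rdf:RDF>
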
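<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic BioPAX Level 3 document for examples and tests: a
     six-enzyme leucine-biosynthesis-like pathway. Not derived from any
     database export. -->
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:owl="http://www.w3.org/2002/07/owl#"
         xmlns:xsd="http://www.w3.org/2001/XMLSchema#"
         xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#"
         xml:base="http://example.org/synthetic#">
  <owl:Ontology rdf:about="">
    <owl:imports rdf:resource="http://www.biopax.org/release/biopax-level3.owl#"/>
  </owl:Ontology>
  <bp:Pathway rdf:about="SYN-LEU-PWY">
    <bp:displayName rdf:datatype="http://www.w3.org/2001/XMLSchema#string">synthetic leucine biosynthesis</bp:displayName>
    <bp:pathwayComponent rdf:resource="rxn1"/>
  </bp:Pathway>
  <bp:ProteinReference rdf:about="protRefId1">
    <bp:displayName rdf:datatype="http://www.w3.org/2001/XMLSchema#string">LeuA-like 2-isopropylmalate synthase</bp:displayName>
    <bp:sequence rdf:datatype="http://www.w3.org/2001/XMLSchema#string">MSKLVIFDTTLRDGEQA</bp:sequence>
  </bp:ProteinReference>
  <bp:ProteinReference rdf:about="protRefId2">
    <bp:displayName rdf:datatype="http://www.w3.org/2001/XMLSchema#string">LeuB-like 3-isopropylmalate dehydrogenase</bp:displayName>
  </bp:ProteinReference>
  <bp:ProteinReference rdf:about="protRefId3">
    <bp:displayName rdf:datatype="http://www.w3.org/2001/XMLSchema#string">LeuC-like isopropylmalate isomerase large subunit</bp:displayName>
  </bp:ProteinReference>
  <bp:ProteinReference rdf:about="protRefId4">
    <bp:displayName rdf:datatype="http://www.w3.org/2001/XMLSchema#string">LeuD-like isopropylmalate isomerase small subunit</bp:displayName>
  </bp:ProteinReference>
  <bp:ProteinReference rdf:about="protRefId5">
    <bp:displayName rdf:datatype="http://www.w3.org/2001/XMLSchema#string">TyrB-like aromatic aminotransferase</bp:displayName>
  </bp:ProteinReference>
  <bp:ProteinReference rdf:about="protRefId6">
    <bp:displayName rdf:datatype="http://www.w3.org/2001/XMLSchema#string">IlvE-like branched-chain aminotransferase</bp:displayName>
  </bp:ProteinReference>
</rdf:RDF>
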
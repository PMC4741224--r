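<?xml version="1.0" encoding="UTF-8"?>
<!-- Conservative subset of the Taxon Concept Transfer Schema (TCS) used by
     the botanical/fungal registration channel: a batch of TaxonName
     records with canonical name, authorship, rank, nomenclatural status
     phrase, basionym authorship for combinations, and the publication
     citation.  Responses carry an additional RegistryId per record. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">

  <xs:element name="DataSet">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="TaxonNames">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="TaxonName" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="Simple" type="xs:string"/>
                    <xs:element name="Rank" type="xs:string"/>
                    <xs:element name="CanonicalName">
                      <xs:complexType>
                        <xs:sequence>
                          <xs:element name="Simple" type="xs:string"/>
                        </xs:sequence>
                      </xs:complexType>
                    </xs:element>
                    <xs:element name="CanonicalAuthorship" type="xs:string"/>
                    <xs:element name="PublicationStatus" type="xs:string"/>
                    <xs:element name="Hybrid" type="xs:string" minOccurs="0"/>
                    <xs:element name="Basionym" type="xs:string" minOccurs="0"/>
                    <xs:element name="PublishedIn" type="xs:string"/>
                    <xs:element name="RegistryId" type="xs:string" minOccurs="0"/>
                  </xs:sequence>
                  <xs:attribute name="id" type="xs:string"/>
                  <xs:attribute name="nomenclaturalCode" type="xs:string"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="schema" type="xs:string"/>
    </xs:complexType>
  </xs:element>

</xs:schema>
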
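<?xml version="1.0" encoding="UTF-8"?>
<!-- The manuscript dialect supported by this package: a minimal
     TaxPub-conformant subset of JATS.  Treatment elements may appear with
     or without the tp: prefix in instance documents; this schema describes
     the namespace-stripped form (see validate_taxpub()). -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">

  <xs:element name="article">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="front" type="frontType"/>
        <xs:element name="body" type="bodyType"/>
      </xs:sequence>
      <xs:attribute name="dtd-version" type="xs:string"/>
    </xs:complexType>
  </xs:element>

  <xs:complexType name="frontType">
    <xs:sequence>
      <xs:element name="journal-meta" minOccurs="0">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="journal-title" type="xs:string" minOccurs="0"/>
            <xs:element name="issn" type="xs:string" minOccurs="0"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
      <xs:element name="article-meta">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="article-id" minOccurs="0" maxOccurs="unbounded">
              <xs:complexType>
                <xs:simpleContent>
                  <xs:extension base="xs:string">
                    <xs:attribute name="pub-id-type" type="xs:string"/>
                  </xs:extension>
                </xs:simpleContent>
              </xs:complexType>
            </xs:element>
            <xs:element name="title-group">
              <xs:complexType>
                <xs:sequence>
                  <xs:element name="article-title" type="xs:string"/>
                </xs:sequence>
              </xs:complexType>
            </xs:element>
            <xs:element name="contrib-group">
              <xs:complexType>
                <xs:sequence>
                  <xs:element name="contrib" maxOccurs="unbounded">
                    <xs:complexType>
                      <xs:sequence>
                        <xs:element name="name">
                          <xs:complexType>
                            <xs:sequence>
                              <xs:element name="surname" type="xs:string"/>
                              <xs:element name="given-names" type="xs:string" minOccurs="0"/>
                            </xs:sequence>
                          </xs:complexType>
                        </xs:element>
                      </xs:sequence>
                      <xs:attribute name="contrib-type" type="xs:string"/>
                    </xs:complexType>
                  </xs:element>
                </xs:sequence>
              </xs:complexType>
            </xs:element>
            <xs:element name="history" minOccurs="0">
              <xs:complexType>
                <xs:sequence>
                  <xs:element name="date" minOccurs="0" maxOccurs="unbounded">
                    <xs:complexType>
                      <xs:attribute name="date-type" type="xs:string"/>
                      <xs:attribute name="iso-8601-date" type="xs:string"/>
                    </xs:complexType>
                  </xs:element>
                </xs:sequence>
              </xs:complexType>
            </xs:element>
            <xs:element name="pub-date" minOccurs="0">
              <xs:complexType>
                <xs:attribute name="date-type" type="xs:string"/>
                <xs:attribute name="iso-8601-date" type="xs:string"/>
              </xs:complexType>
            </xs:element>
            <xs:element name="custom-meta-group" minOccurs="0">
              <xs:complexType>
                <xs:sequence>
                  <xs:element name="custom-meta" minOccurs="0" maxOccurs="unbounded">
                    <xs:complexType>
                      <xs:sequence>
                        <xs:element name="meta-name" type="xs:string"/>
                        <xs:element name="meta-value" type="xs:string"/>
                      </xs:sequence>
                    </xs:complexType>
                  </xs:element>
                </xs:sequence>
              </xs:complexType>
            </xs:element>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="bodyType">
    <xs:sequence>
      <xs:element name="taxon-treatment" minOccurs="0" maxOccurs="unbounded">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="nomenclature" maxOccurs="unbounded">
              <xs:complexType>
                <xs:sequence>
                  <xs:element name="object-id" minOccurs="0">
                    <xs:complexType>
                      <xs:simpleContent>
                        <xs:extension base="xs:string">
                          <xs:attribute name="content-type" type="xs:string"/>
                        </xs:extension>
                      </xs:simpleContent>
                    </xs:complexType>
                  </xs:element>
                  <xs:element name="taxon-name">
                    <xs:complexType>
                      <xs:sequence>
                        <xs:element name="taxon-name-part" maxOccurs="unbounded">
                          <xs:complexType>
                            <xs:simpleContent>
                              <xs:extension base="xs:string">
                                <xs:attribute name="taxon-name-part-type" type="xs:string"/>
                              </xs:extension>
                            </xs:simpleContent>
                          </xs:complexType>
                        </xs:element>
                      </xs:sequence>
                      <xs:attribute name="is-hybrid" type="xs:string"/>
                    </xs:complexType>
                  </xs:element>
                  <xs:element name="taxon-authority" type="xs:string" minOccurs="0"/>
                  <xs:element name="taxon-status" type="xs:string"/>
                </xs:sequence>
              </xs:complexType>
            </xs:element>
            <xs:element name="treatment-sec" minOccurs="0" maxOccurs="unbounded">
              <xs:complexType>
                <xs:sequence>
                  <xs:element name="p" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
                </xs:sequence>
                <xs:attribute name="sec-type" type="xs:string"/>
              </xs:complexType>
            </xs:element>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
    </xs:sequence>
  </xs:complexType>

</xs:schema>
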
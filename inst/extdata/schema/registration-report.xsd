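<?xml version="1.0" encoding="UTF-8"?>
<!-- Response-report document returned at the acceptance stage: one entry
     per act and per author, each carrying exactly one of a registry
     identifier, an error message, or a pending-disambiguation reference
     (a registered entry may add an advisory message). -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="unqualified">

  <xs:complexType name="outcomeType">
    <xs:sequence>
      <xs:element name="id" type="xs:string" minOccurs="0"/>
      <xs:element name="message" type="xs:string" minOccurs="0"/>
      <xs:element name="pending-ref" type="xs:string" minOccurs="0"/>
    </xs:sequence>
    <xs:attribute name="index" type="xs:integer" use="required"/>
    <xs:attribute name="status" use="required">
      <xs:simpleType>
        <xs:restriction base="xs:string">
          <xs:enumeration value="registered"/>
          <xs:enumeration value="error"/>
          <xs:enumeration value="pending"/>
        </xs:restriction>
      </xs:simpleType>
    </xs:attribute>
  </xs:complexType>

  <xs:element name="registration-report">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="acts">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="act" type="outcomeType" minOccurs="0" maxOccurs="unbounded"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
        <xs:element name="authors">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="author" type="outcomeType" minOccurs="0" maxOccurs="unbounded"/>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="article-id" type="xs:string" use="required"/>
      <xs:attribute name="registry" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>

</xs:schema>
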
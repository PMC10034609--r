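<?xml version="1.0" encoding="UTF-8"?>
<!-- Normative schema of the extract dialect: an entry-level subset of the
     EN/ISO 13606 extract structure. Elements carry their reference-model
     data value as typed attributes; which attributes are required depends
     on the kind, checked by the archetype-conformance validator on top of
     this structural schema. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           targetNamespace="urn:ehr2omop:extract:1"
           xmlns:e="urn:ehr2omop:extract:1"
           elementFormDefault="qualified">
  <xs:simpleType name="dvKind">
    <xs:restriction base="xs:string">
      <xs:enumeration value="CODED_TEXT"/>
      <xs:enumeration value="SIMPLE_TEXT"/>
      <xs:enumeration value="DATE_TIME"/>
      <xs:enumeration value="QUANTITY"/>
      <xs:enumeration value="IDENTIFIER"/>
      <xs:enumeration value="BOOLEAN"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="ehr_extract">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="entry" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="element" minOccurs="1" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="node_id" type="xs:string" use="required"/>
                  <xs:attribute name="kind" type="e:dvKind" use="required"/>
                  <xs:attribute name="value" type="xs:string"/>
                  <xs:attribute name="code" type="xs:string"/>
                  <xs:attribute name="code_system" type="xs:string"/>
                  <xs:attribute name="display" type="xs:string"/>
                  <xs:attribute name="magnitude" type="xs:decimal"/>
                  <xs:attribute name="units" type="xs:string"/>
                  <xs:attribute name="id" type="xs:string"/>
                  <xs:attribute name="scope" type="xs:string"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="extract_id" type="xs:string" use="required"/>
      <xs:attribute name="patient_id" type="xs:string" use="required"/>
      <xs:attribute name="archetype_id" type="xs:string" use="required"/>
      <xs:attribute name="source_name" type="xs:string" use="required"/>
      <xs:attribute name="extracted_at" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
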
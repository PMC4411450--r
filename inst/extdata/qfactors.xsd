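<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="qfactors">
    <xs:complexType>
      <xs:choice minOccurs="0" maxOccurs="unbounded">
        <xs:element name="qcategorical">
          <xs:complexType>
            <xs:attribute name="label" type="nonEmptyString" use="required"/>
            <xs:attribute name="value" type="nonEmptyString" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="qcontinuous">
          <xs:complexType>
            <xs:attribute name="label" type="nonEmptyString" use="required"/>
            <xs:attribute name="value" type="xs:decimal" use="required"/>
            <xs:attribute name="unit" type="nonEmptyString" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:choice>
    </xs:complexType>
  </xs:element>
  <xs:simpleType name="nonEmptyString">
    <xs:restriction base="xs:string">
      <xs:minLength value="1"/>
    </xs:restriction>
  </xs:simpleType>
</xs:schema>
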
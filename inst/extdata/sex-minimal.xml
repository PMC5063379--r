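<?xml version="1.0" encoding="UTF-8"?>
<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3" FileType="Snapshot" FileOID="sex-minimal" ODMVersion="1.3.2">
  <Study OID="S.1">
    <GlobalVariables>
      <StudyName>Minimal demographics study</StudyName>
      <StudyDescription>Minimal demographics study</StudyDescription>
      <ProtocolName>Minimal demographics study</ProtocolName>
    </GlobalVariables>
    <MetaDataVersion OID="MV.1" Name="v1">
      <StudyEventDef OID="SE.1" Name="Baseline" Repeating="No" Type="Scheduled">
        <FormRef FormOID="F.1" OrderNumber="1" Mandatory="No"/>
      </StudyEventDef>
      <FormDef OID="F.1" Name="Demographics" Repeating="No">
        <ItemGroupRef ItemGroupOID="IG.1" OrderNumber="1" Mandatory="No"/>
      </FormDef>
      <ItemGroupDef OID="IG.1" Name="Main" Repeating="No">
        <ItemRef ItemOID="I.1" OrderNumber="1" Mandatory="No"/>
      </ItemGroupDef>
      <ItemDef OID="I.1" Name="Sex" DataType="integer">
        <Question>
          <TranslatedText xml:lang="en">Sex</TranslatedText>
        </Question>
        <CodeListRef CodeListOID="CL.1"/>
        <Alias Context="UMLS" Name="C0150831"/>
      </ItemDef>
      <CodeList OID="CL.1" Name="Sex" DataType="integer">
        <CodeListItem CodedValue="1">
          <Decode>
            <TranslatedText xml:lang="en">male</TranslatedText>
          </Decode>
          <Alias Context="UMLS" Name="C0086582"/>
        </CodeListItem>
        <CodeListItem CodedValue="2">
          <Decode>
            <TranslatedText xml:lang="en">female</TranslatedText>
          </Decode>
          <Alias Context="UMLS" Name="C0086287"/>
        </CodeListItem>
      </CodeList>
    </MetaDataVersion>
  </Study>
</ODM>
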
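<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="model">
    <listOfCompartments>
      <compartment id="default" constant="true" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="C2" name="cdc2" compartment="default" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="CP" name="cdc2-P" compartment="default" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="pM" name="preMPF (P-cyclin-cdc2-P)" compartment="default" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M" name="active MPF (P-cyclin-cdc2)" compartment="default" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="Y" name="cyclin" compartment="default" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="YP" name="cyclin-P" compartment="default" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="EmptySet" name="EmptySet" compartment="default" hasOnlySubstanceUnits="false" boundaryCondition="true" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="Reaction1" name="R6: destruction of active MPF" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="M" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C2" stoichiometry="1" constant="true"/>
          <speciesReference species="YP" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Reaction2" name="R8: phosphorylation of cdc2" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="C2" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="CP" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Reaction3" name="R9: reversion of cdc2 phosphorylation" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="CP" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C2" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Reaction4" name="R3: cdc2-P + cyclin to preMPF" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="CP" stoichiometry="1" constant="true"/>
          <speciesReference species="Y" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="pM" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Reaction5" name="R5: opposition of MPF activation" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="M" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="pM" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Reaction6" name="R1: de novo synthesis of cyclin" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="EmptySet" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="Y" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Reaction7" name="R2: cyclin decay" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="Y" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="EmptySet" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Reaction8" name="R7: proteolysis of phosphorylated cyclin" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="YP" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="EmptySet" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="Reaction9" name="R4: dephosphorylation of cdc2 (MPF activation)" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="pM" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
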
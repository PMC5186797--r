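<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic toy model (hand-written fixture, not derived from any
     published reconstruction): linear uptake -> A -> B -> proliferation
     chain with one reversible interconversion and pathway notes. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_chain" fbc:strict="true">
    <listOfSpecies>
      <species id="A" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="B" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="C" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="EX_A" reversible="false" fast="false">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>pathway: uptake</p></body></notes>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_AB" reversible="false" fast="false">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>pathway: chain</p></body></notes>
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_BC" reversible="true" fast="false">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>pathway: chain</p></body></notes>
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="GROWTH" reversible="false" fast="false">
        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>pathway: biomass</p></body></notes>
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="GROWTH" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
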
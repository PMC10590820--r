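<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1"
      level="3" version="1" fbc:required="false" groups:required="false">
  <model id="toy_model" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_A_c" compartment="c" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"
               fbc:chemicalFormula="C3H6O3"/>
      <species id="M_B_c" compartment="c" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"
               fbc:chemicalFormula="C3H4O3"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_ex_a" value="-10" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_default" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_EX_A" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_ex_a" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_R1" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_g1"/>
            <fbc:or>
              <fbc:geneProductRef fbc:geneProduct="G_g2"/>
              <fbc:geneProductRef fbc:geneProduct="G_g3"/>
            </fbc:or>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_EX_B" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="M_B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <groups:listOfGroups>
      <groups:group groups:id="g_exchange" groups:name="Exchange/demand"
                    groups:kind="partonomy">
        <groups:listOfMembers>
          <groups:member groups:idRef="R_EX_A"/>
          <groups:member groups:idRef="R_EX_B"/>
        </groups:listOfMembers>
      </groups:group>
      <groups:group groups:id="g_core" groups:name="Core" groups:kind="partonomy">
        <groups:listOfMembers>
          <groups:member groups:idRef="R_R1"/>
        </groups:listOfMembers>
      </groups:group>
    </groups:listOfGroups>
  </model>
</sbml>
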
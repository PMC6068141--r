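<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic four-reaction toy model (glucose uptake, transport,
     lumped glycolysis with an isozyme OR rule, biomass sink).
     FBA optimum of BIOMASS is 10 = (10 glucose x 2 ATP) / 2. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_sbml" fbc:strict="true">
    <listOfCompartments>
      <compartment id="e" constant="true"/>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc_e" compartment="e" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
      <species id="glc_c" compartment="c" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
      <species id="atp_c" compartment="c" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_glc" value="-10" constant="true"/>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="ub_default" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g0" fbc:label="g0"/>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_glc" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_glc" fbc:upperFluxBound="zero">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1"
                            constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="GLCt" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1"
                            constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glc_c" stoichiometry="1"
                            constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="GLY" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="glc_c" stoichiometry="1"
                            constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="atp_c" stoichiometry="2"
                            constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_g2"/>
            <fbc:geneProductRef fbc:geneProduct="G_g3"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="BIOMASS" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="atp_c" stoichiometry="2"
                            constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
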
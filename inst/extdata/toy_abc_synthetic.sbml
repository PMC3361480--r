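<?xml version="1.0" encoding="UTF-8"?>
<!-- synthetic three-metabolite toy model, hand written for import tests -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="toy_abc">
    <listOfParameters>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_two" value="2" constant="true"/>
      <parameter id="ub_five" value="5" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="A" name="metabolite A" initialConcentration="1.5"/>
      <species id="B" name="metabolite B" initialConcentration="0.5"/>
      <species id="C" initialConcentration="0"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="r1" reversible="false" lowerFluxBound="lb_zero" upperFluxBound="ub_two">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="2"/>
        </listOfProducts>
      </reaction>
      <reaction id="r2" reversible="false" lowerFluxBound="lb_zero" upperFluxBound="ub_five">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
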
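<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner" level="2" version="4">
  <model id="demo_cftr_map" name="Synthetic CFTR demo map">
    <listOfCompartments>
      <compartment id="er" name="endoplasmic reticulum"/>
      <compartment id="pm" name="plasma membrane"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="sp_cftr_er" name="CFTR" compartment="er">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>PROTEIN</celldesigner:class>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="sp_cftr_pm" name="CFTR" compartment="pm">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>PROTEIN</celldesigner:class>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="sp_hsp90" name="HSP90AA1" compartment="er">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>PROTEIN</celldesigner:class>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="sp_nfkb1" name="NFKB1" compartment="pm">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>GENE</celldesigner:class>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="sp_atp" name="ATP" compartment="pm">
        <annotation>
          <celldesigner:extension>
            <celldesigner:speciesIdentity>
              <celldesigner:class>SIMPLE_MOLECULE</celldesigner:class>
            </celldesigner:speciesIdentity>
          </celldesigner:extension>
        </annotation>
      </species>
      <species id="sp_misc" name="UNANNOTATED_SPECIES" compartment="pm"/>
    </listOfSpecies>
  </model>
</sbml>
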
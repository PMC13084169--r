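# Hand-authored minimal SBML L3/FBC document, independent of write_sbml().
minimal_sbml <- function(level = "3", with_bounds = TRUE,
                         species_ok = TRUE) {
  bounds <- if (with_bounds)
    ' fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub"' else ""
  ref <- if (species_ok) "M_a" else "M_ghost"
  paste0('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="', level,
'" version="1" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" fbc:required="false">
  <model id="mini" fbc:strict="true">
    <listOfCompartments><compartment id="c" name="cytosol" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="M_a" name="A" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb0" value="0" constant="true"/>
      <parameter id="ub" value="10" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_1" fbc:label="ENSG00000010404"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_in" reversible="false" fast="false"', bounds, '>
        <listOfProducts><speciesReference species="M_a" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
      <reaction id="R_out" reversible="false" fast="false"', bounds, '>
        <listOfReactants><speciesReference species="', ref,
'" stoichiometry="1" constant="true"/></listOfReactants>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_1"/>
        </fbc:geneProductAssociation>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_out" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>')
}

test_that("a hand-written minimal FBC document parses correctly", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(minimal_sbml(), p)
  m <- read_sbml(p)
  expect_equal(nrow(m$reactions), 2L)
  expect_equal(nrow(m$metabolites), 1L)
  expect_identical(m$objective_id, "R_out")
  expect_identical(m$genes, "ENSG00000010404")
  expect_equal(m$stoichiometry$R_out, c(M_a = -1))
  expect_equal(m$reactions$upper_bound, c(10, 10))
  expect_equal(fba(m)$objective_value, 10)
  expect_identical(reactions_for_gene(m, "ENSG00000010404"), "R_out")
})

test_that("SBML write/read round-trips a structured model", {
  gen <- generate_synthetic_model(synthetic_spec(
    chain_length = 3, bypass = TRUE, n_decoys = 2, seed = 8))
  m <- gen$model
  p <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, p)
  m2 <- read_sbml(p)
  for (fld in c("metabolites", "reactions", "stoichiometry", "genes",
                "compartments", "objective_id"))
    expect_equal(m2[[fld]], m[[fld]], info = fld)
  # subsystems survive via the groups extension
  expect_identical(m2$reactions$subsystem, m$reactions$subsystem)
})

test_that("unsupported or defective SBML is rejected with a clear cause", {
  p2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(minimal_sbml(level = "2"), p2)
  expect_error(read_sbml(p2), "Level 3")

  pb <- withr::local_tempfile(fileext = ".xml")
  writeLines(minimal_sbml(with_bounds = FALSE), pb)
  expect_error(read_sbml(pb), "flux bound")

  pg <- withr::local_tempfile(fileext = ".xml")
  writeLines(minimal_sbml(species_ok = FALSE), pg)
  expect_error(read_sbml(pg), "unknown metabolite")
})
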
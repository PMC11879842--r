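minimal_model <- function() {
  stoichiometric_model(
    list(metabolite("a_e", "A", formula = "C1H2", charge = 0L,
                    compartment = "e")),
    list(reaction("EX_a_e", c(a_e = -1), -10, 1000, is_exchange = TRUE)),
    "EX_a_e")
}

expect_same_model <- function(m1, m2) {
  expect_setequal(names(m1$metabolites), names(m2$metabolites))
  expect_setequal(names(m1$reactions), names(m2$reactions))
  for (id in names(m1$reactions)) {
    r1 <- m1$reactions[[id]]; r2 <- m2$reactions[[id]]
    expect_equal(sort(names(r1$stoichiometry)), sort(names(r2$stoichiometry)),
                 info = id)
    expect_equal(r1$stoichiometry[sort(names(r1$stoichiometry))],
                 r2$stoichiometry[sort(names(r2$stoichiometry))], info = id)
    expect_equal(r1$lower_bound, r2$lower_bound, info = id)
    expect_equal(r1$upper_bound, r2$upper_bound, info = id)
  }
  for (id in names(m1$metabolites)) {
    expect_equal(m1$metabolites[[id]]$formula, m2$metabolites[[id]]$formula)
    expect_equal(m1$metabolites[[id]]$charge, m2$metabolites[[id]]$charge)
  }
}

test_that("write-then-read round trip preserves ids, stoichiometry and bounds", {
  p <- withr::local_tempfile(fileext = ".xml")
  m <- minimal_model()
  write_sbml(m, p)
  m2 <- load_sbml(p)
  expect_length(m2$metabolites, 1)
  expect_length(m2$reactions, 1)
  expect_same_model(m, m2)

  # the ~30-reaction core model round trips too, variant hooks included
  core <- core_for_tests()
  write_sbml(core, p)
  core2 <- load_sbml(p)
  expect_same_model(core, core2)
  expect_equal(core2$biomass_reaction_id, "BIOMASS")  # via fbc objective
})

test_that("rational coefficients survive the round trip as 12-digit decimals", {
  p <- withr::local_tempfile(fileext = ".xml")
  m <- stoichiometric_model(
    list(metabolite("a_c"), metabolite("b_c")),
    list(reaction("half", c(a_c = -0.5, b_c = 1), 0, 1000),
         reaction("third", c(a_c = -1 / 3, b_c = 1), 0, 1000),
         reaction("EX_b", c(b_c = -1), -1000, 1000, is_exchange = TRUE),
         reaction("EX_a", c(a_c = 1), -1000, 1000, is_exchange = TRUE)),
    "half")
  write_sbml(m, p)
  m2 <- load_sbml(p)
  expect_identical(m2$reactions[["half"]]$stoichiometry[["a_c"]], -0.5)
  expect_equal(m2$reactions[["third"]]$stoichiometry[["a_c"]], -1 / 3,
               tolerance = 1e-11)
})

test_that("an empty model writes a loadable SBML skeleton", {
  p <- withr::local_tempfile(fileext = ".xml")
  write_sbml(stoichiometric_model(list(), list(), NA_character_), p)
  m <- load_sbml(p)
  expect_length(m$metabolites, 0)
  expect_length(m$reactions, 0)
})

test_that("kinetic-law bound encodings and reversibility defaults are accepted", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="legacy"><listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies>',
    '<species id="a" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    '<species id="b" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="r_kl" reversible="true" fast="false">',
    '<listOfReactants><speciesReference species="a" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b" stoichiometry="1" constant="true"/></listOfProducts>',
    '<kineticLaw><math xmlns="http://www.w3.org/1998/Math/MathML"><ci>FLUX_VALUE</ci></math>',
    '<listOfLocalParameters>',
    '<localParameter id="LOWER_BOUND" value="-12.5"/>',
    '<localParameter id="UPPER_BOUND" value="800"/>',
    '</listOfLocalParameters></kineticLaw>',
    '</reaction>',
    '<reaction id="r_rev" reversible="true" fast="false">',
    '<listOfReactants><speciesReference species="b" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="a" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction>',
    '<reaction id="r_irrev" reversible="false" fast="false">',
    '<listOfReactants><speciesReference species="a" stoichiometry="2" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), p)
  m <- load_sbml(p, biomass_reaction_id = "r_rev")
  expect_equal(m$reactions[["r_kl"]]$lower_bound, -12.5)
  expect_equal(m$reactions[["r_kl"]]$upper_bound, 800)
  expect_equal(m$reactions[["r_rev"]]$lower_bound, -1000)   # reversible default
  expect_equal(m$reactions[["r_irrev"]]$lower_bound, 0)     # irreversible default
  expect_equal(m$reactions[["r_irrev"]]$upper_bound, 1000)
  expect_equal(m$reactions[["r_irrev"]]$stoichiometry[["a"]], -2)
})

test_that("malformed files and duplicate ids are rejected with clear errors", {
  p <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", p)
  expect_error(load_sbml(p), "parse error")

  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model><listOfSpecies>',
    '<species id="a" compartment="c"/><species id="a" compartment="c"/>',
    '</listOfSpecies></model></sbml>'), p)
  expect_error(load_sbml(p), "duplicated species")

  expect_error(load_sbml(file.path(tempdir(), "nope.xml")), "no such file")
})

test_that("variant edits commute with SBML round-tripping", {
  p <- withr::local_tempfile(fileext = ".xml")
  core <- core_for_tests()
  for (v in c("CBB", "RGLYP")) {
    spec <- variant_spec(v)
    edited_then_written <- apply_variant(core, spec)
    write_sbml(edited_then_written, p)
    a <- load_sbml(p)
    write_sbml(core, p)
    b <- apply_variant(load_sbml(p), spec)
    expect_same_model(a, b)
  }
})
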
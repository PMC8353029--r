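test_that("SBML round trip preserves ids, stoichiometry, bounds and objective", {
  m <- build_core_model()
  path <- tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_identical(names(m2$metabolites), names(m$metabolites))
  expect_identical(names(m2$reactions), names(m$reactions))
  for (id in names(m$reactions)) {
    a <- m$reactions[[id]]; b <- m2$reactions[[id]]
    ord <- sort(names(a$stoichiometry))
    expect_equal(b$stoichiometry[ord], a$stoichiometry[ord], info = id)
    expect_identical(b$lower_bound, a$lower_bound, info = id)
    expect_identical(b$upper_bound, a$upper_bound, info = id)
    expect_identical(b$gene_associated, a$gene_associated, info = id)
  }
  expect_equal(m2$objective, m$objective)
  for (id in names(m$metabolites)) {
    a <- m$metabolites[[id]]; b <- m2$metabolites[[id]]
    expect_identical(b$compartment, a$compartment, info = id)
    if (!is.null(a$formula)) {
      ord <- sort(names(a$formula))
      expect_equal(b$formula[ord], a$formula[ord], info = id)
    }
  }
})

test_that("a single-reaction model writes a valid document", {
  m <- stoichiometric_model(list(metabolite("X")),
                            list(reaction("DM_X", stoichiometry = c(X = -1),
                                          gene_associated = FALSE)))
  path <- tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_identical(names(m2$reactions), "DM_X")
  expect_equal(m2$reactions$DM_X$stoichiometry, c(X = -1))
})

test_that("writing an empty model errors", {
  m <- structure(list(metabolites = list(), reactions = list(),
                      objective = numeric(0)), class = "phb_model")
  expect_error(write_sbml(m, tempfile()), "empty model")
})

test_that("an undeclared species reference is a parse error naming the reaction", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="bad"><listOfSpecies>',
    '<species id="A" compartment="c" constant="false"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="r1" reversible="false">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="GHOST" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), path)
  expect_error(suppressWarnings(read_sbml(path)), "GHOST")
})

test_that("malformed XML is rejected", {
  path <- tempfile(fileext = ".xml")
  writeLines("<sbml><model><unclosed", path)
  expect_error(read_sbml(path), "malformed|Premature|error")
  expect_error(read_sbml(tempfile()), "not found")
})

test_that("Level 2 kinetic-law bounds are honoured", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="l2"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies><species id="A" compartment="c"/><species id="B" compartment="c"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="v1" reversible="true">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-5"/><parameter id="UPPER_BOUND" value="10"/>',
    '</listOfParameters></kineticLaw>',
    '</reaction></listOfReactions></model></sbml>'), path)
  m <- read_sbml(path)
  expect_identical(m$reactions$v1$lower_bound, -5)
  expect_identical(m$reactions$v1$upper_bound, 10)
})

test_that("missing bounds fall back to defaults with a warning", {
  path <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="nb"><listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="A" compartment="c" constant="false"/>',
    '<species id="B" compartment="c" constant="false"/></listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="fwd" reversible="false">',
    '<listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction>',
    '<reaction id="rev" reversible="true">',
    '<listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions></model></sbml>'), path)
  expect_warning(m <- read_sbml(path), "no declared bounds")
  expect_identical(m$reactions$fwd$lower_bound, 0)
  expect_identical(m$reactions$rev$lower_bound, -1000)
  expect_identical(m$reactions$rev$upper_bound, 1000)
})

test_that("FBA after an SBML round trip matches FBA on the original", {
  m <- build_core_model()
  path <- tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  s1 <- solve_fba(m, c(EX_succ = 1), "max", phase1_constraints())
  s2 <- solve_fba(m2, c(EX_succ = 1), "max", phase1_constraints())
  expect_equal(s2$objective_value, s1$objective_value, tolerance = 1e-10)
})
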
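# Hand-written CellDesigner-dialect SBML used as a parsing contract.
cd_sbml <- function() {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
    '<model id="mini">\n',
    '<listOfCompartments>\n',
    '<compartment id="c1" name="cytoplasm"/>\n',
    '<compartment id="c2" name="nucleus"/>\n',
    '</listOfCompartments>\n',
    '<listOfSpecies>\n',
    '<species id="s1" name="TGFB" compartment="c1">\n',
    '<annotation><celldesigner:extension xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner">\n',
    '<celldesigner:speciesIdentity><celldesigner:class>PROTEIN</celldesigner:class></celldesigner:speciesIdentity>\n',
    '</celldesigner:extension></annotation></species>\n',
    '<species id="s2" name="SNAIL_gene" compartment="c2">\n',
    '<annotation><celldesigner:extension xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner">\n',
    '<celldesigner:speciesIdentity><celldesigner:class>GENE</celldesigner:class></celldesigner:speciesIdentity>\n',
    '</celldesigner:extension></annotation></species>\n',
    '<species id="s3" name="miR34" compartment="c1">\n',
    '<annotation><celldesigner:extension xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner">\n',
    '<celldesigner:speciesIdentity><celldesigner:class>RNA</celldesigner:class></celldesigner:speciesIdentity>\n',
    '</celldesigner:extension></annotation></species>\n',
    '</listOfSpecies>\n',
    '<listOfReactions>\n',
    '<reaction id="r1">\n',
    '<annotation><celldesigner:extension xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner">\n',
    '<celldesigner:reactionType>STATE_TRANSITION</celldesigner:reactionType>\n',
    '<celldesigner:listOfModification>\n',
    '<celldesigner:modification type="INHIBITION" modifiers="s3"/>\n',
    '</celldesigner:listOfModification>\n',
    '</celldesigner:extension></annotation>\n',
    '<listOfReactants><speciesReference species="s1"/></listOfReactants>\n',
    '<listOfProducts><speciesReference species="s2"/></listOfProducts>\n',
    '<listOfModifiers><modifierSpeciesReference species="s3"/></listOfModifiers>\n',
    '</reaction>\n',
    '</listOfReactions>\n',
    '</model>\n</sbml>\n')
}

test_that("CellDesigner SBML parses species classes, reactions and modifiers", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(cd_sbml(), path)
  map <- read_celldesigner_sbml(path)
  expect_equal(n_species(map), 3)
  # one reactant->product interaction plus one signed modifier arc
  expect_equal(n_interactions(map), 2)
  expect_equal(map$species$kind[match(c("s1", "s2", "s3"), map$species$id)],
               c("protein", "gene", "rna"))
  expect_equal(map$species$compartment[map$species$id == "s2"], "nucleus")
  edges <- interaction_edges(map)
  expect_equal(edges$sign[edges$source == "s1"], "activation")
  expect_equal(edges$sign[edges$source == "s3"], "inhibition")
  expect_equal(edges$target, c("s2", "s2"))
  expect_equal(nrow(validate_map(map)), 0)
})

test_that("minimal plain SBML yields a map with unknown kinds", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    '<?xml version="1.0"?><sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfSpecies>',
    '<species id="a" name="A"/><species id="b" name="B"/>',
    '</listOfSpecies><listOfReactions><reaction id="r1">',
    '<listOfReactants><speciesReference species="a"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), path)
  map <- read_celldesigner_sbml(path)
  expect_equal(n_species(map), 2)
  expect_equal(n_interactions(map), 1)
  expect_true(all(map$species$kind == "unknown"))
})

test_that("truncated or species-free SBML is rejected without a partial map", {
  path <- withr::local_tempfile(fileext = ".xml")
  full <- cd_sbml()
  writeLines(substr(full, 1, nchar(full) %/% 2), path)
  expect_error(read_celldesigner_sbml(path), class = "emtmap_parse_error")

  writeLines(paste0('<?xml version="1.0"?>',
                    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4">',
                    '<model id="m"/></sbml>'), path)
  expect_error(read_celldesigner_sbml(path), class = "emtmap_format_error")
})

test_that("SBML-qual round trips are truth-table exact rule by rule", {
  models <- c(lapply(c(3, 17, 23), function(s) infer_rules(random_test_map(s))),
              list(infer_rules(emt_core_fixture())))
  for (model in models) {
    path <- withr::local_tempfile(fileext = ".sbml")
    write_sbml_qual(model, path)
    back <- read_sbml_qual(path)
    expect_setequal(back$node_order, model$node_order)
    expect_setequal(back$inputs, model$inputs)
    for (t in model$node_order) {
      k <- length(expr_literals(model$rules[[t]]$expr))
      if (k > 6) next
      expect_equal(truth_table(back$rules[[t]]),
                   truth_table(model$rules[[t]]),
                   info = sprintf("node %s", t))
    }
  }
})

test_that("a qual file declares one qualitative species per model node", {
  model <- infer_rules(emt_core_fixture())
  path <- withr::local_tempfile(fileext = ".sbml")
  write_sbml_qual(model, path)
  doc <- xml2::read_xml(path)
  qs <- xml2::xml_find_all(doc,
                           ".//*[local-name()='qualitativeSpecies']")
  expect_length(qs, length(model$node_order))
})

test_that("multilevel and dangling-reference qual files are rejected", {
  model <- infer_rules(edges_map(data.frame(source = "A",
                                            sign = "activation",
                                            target = "B")))
  path <- withr::local_tempfile(fileext = ".sbml")
  write_sbml_qual(model, path)
  txt <- readLines(path)
  writeLines(gsub('qual:maxLevel="1"', 'qual:maxLevel="3"', txt), path)
  expect_error(read_sbml_qual(path), class = "emtmap_multilevel_error")

  writeLines(gsub('<ci>A</ci>', '<ci>GHOST</ci>', txt), path)
  expect_error(read_sbml_qual(path), "GHOST",
               class = "emtmap_format_error")
})
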
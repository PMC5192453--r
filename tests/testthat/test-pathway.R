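toy_network_file <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("pathway\treaction\trole\tmetabolite", rows), f)
  f
}

test_that("TSV networks load with substrate/product structure", {
  f <- toy_network_file(c(
    "P1\tr1\tsubstrate\ta",
    "P1\tr1\tproduct\tb",
    "P2\tr2\tsubstrate\tb",
    "P2\tr2\tproduct\tc"))
  net <- load_network(f)
  expect_length(net$reactions, 2L)
  expect_equal(net$reactions$r1$substrates, "a")
  expect_equal(net$reactions$r2$products, "c")
  expect_setequal(net$metabolites, c("a", "b", "c"))

  empty <- toy_network_file(character(0))
  expect_length(load_network(empty)$pathways, 0L)

  dangling <- toy_network_file("P1\tr1\tsubstrate\ta")
  expect_error(load_network(dangling), "r1")
})

test_that("a minimal SBML level-3 model with groups loads", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"',
    ' xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1">',
    '<model id="toy"><listOfSpecies>',
    '<species id="m1" name="glucose"/><species id="m2" name="pyruvate"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="rx1"><listOfReactants><speciesReference species="m1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="m2"/></listOfProducts></reaction>',
    '</listOfReactions>',
    '<groups:listOfGroups><groups:group groups:id="g1" groups:name="Glycolysis">',
    '<groups:listOfMembers><groups:member groups:idRef="rx1"/></groups:listOfMembers>',
    '</groups:group></groups:listOfGroups>',
    '</model></sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  net <- load_network(f)
  expect_equal(net$reactions$rx1$substrates, "glucose")
  expect_equal(net$pathways$Glycolysis, "rx1")
})

test_that("the fixture network contains the expected pathways", {
  net <- load_network()
  expect_true("Glycolysis / TCA cycle" %in% names(net$pathways))
  expect_true("Starch and sucrose metabolism" %in% names(net$pathways))
  # every reaction has both sides (validated at load, asserted here on one)
  expect_setequal(net$reactions$succinate_dehydrogenase$substrates, "succinate")
})

test_that("pathway ranking counts discriminant metabolites first", {
  f <- toy_network_file(c(
    "A\tra1\tsubstrate\tm1", "A\tra1\tproduct\tm2",
    "B\trb1\tsubstrate\tm3", "B\trb1\tproduct\tm4",
    "B\trb2\tsubstrate\tm4", "B\trb2\tproduct\tm5"))
  net <- load_network(f)
  rep1 <- map_metabolites(net, detected = c("m1", "m2", "m3"),
                          discriminant = c("m1", "m2", "m3"))
  expect_equal(rep1$pathway[1], "A")                  # 2 of 2 beats 1 of 3
  expect_equal(rep1$n_discriminant, c(2L, 1L))
  # empty discriminant list: all counts zero
  rep0 <- map_metabolites(net, detected = "m1", discriminant = character(0))
  expect_true(all(rep0$n_discriminant == 0L))
  # input order never changes the report
  rep2 <- map_metabolites(net, detected = c("m3", "m1", "m2"),
                          discriminant = c("m3", "m2", "m1"))
  expect_identical(rep1[1:4], rep2[1:4])
  # unmatched names warn, not fail
  expect_warning(map_metabolites(net, "nothing_here", character(0)),
                 "not in network")
})

test_that("node states follow the published coloring convention", {
  net <- load_network()
  rep <- suppressWarnings(
    map_metabolites(net, detected = c("glucose", "lactate"),
                    discriminant = "glucose"))
  st <- attr(rep, "node_states")
  expect_equal(unname(st[["glucose"]]), "discriminant")
  expect_equal(unname(st[["lactate"]]), "detected_only")
  expect_equal(unname(st[["citrate"]]), "absent")
  dot <- network_to_dot(net, st)
  expect_match(dot, "\"glucose\" \\[shape=ellipse style=filled fillcolor=red\\]")
})

test_that("subnetwork extraction is closed, monotone and order-safe", {
  net <- load_network()
  sub1 <- extract_subnetwork(net, "succinate")
  expect_setequal(names(sub1$reactions),
                  c("succinyl-CoA_synthetase", "succinate_dehydrogenase"))
  expect_true("fumarate" %in% sub1$metabolites)       # immediate partners kept

  sub2 <- extract_subnetwork(net, c("glucose", "succinate"))
  expect_true("hexokinase" %in% names(sub2$reactions))
  expect_true("maltase" %in% names(sub2$reactions))
  expect_true(all(names(sub1$reactions) %in% names(sub2$reactions)))  # monotone

  expect_warning(e <- extract_subnetwork(net, "unobtainium"), "empty")
  expect_length(e$reactions, 0L)
})
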
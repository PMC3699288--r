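test_that("Hill-notation formulas parse, including pseudo-species", {
  p <- parse_formula(c("C6H12O6", "C10H12N5O6P", "", NA, "C3.68N1O1.9S0.03"))
  expect_equal(p[[1]][["C"]], 6)
  expect_equal(p[[2]][["P"]], 1)
  expect_length(p[[3]], 0)   # element-free pseudo-species
  expect_null(p[[4]])        # unknown composition
  expect_equal(p[[5]][["C"]], 3.68)
  expect_equal(element_count("CHO3", "O"), 3)
})

test_that("SBML round-trip preserves ids, stoichiometry, bounds, categories", {
  m <- example_toy_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_equal(m2$reactions$category, m$reactions$category)
  expect_equal(m2$reactions$gene_association, m$reactions$gene_association)
  o <- function(mm) dplyr::arrange(mm$stoichiometry, reaction, metabolite)
  expect_equal(o(m2), o(m))
  expect_equal(m2$metabolites$formula, m$metabolites$formula)
  expect_equal(model_summary(m2), model_summary(m))
})

test_that("the synthetic core model round-trips through SBML", {
  m <- core_default()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_equal(model_summary(m2), model_summary(m))
  expect_equal(sort(m2$metabolites$id), sort(m$metabolites$id))
  # unset formula/charge stay absent
  m3 <- example_toy_model()
  m3$metabolites$formula[2] <- NA
  m3$metabolites$charge[3] <- NA
  write_sbml(m3, path)
  m4 <- read_sbml(path)
  expect_true(is.na(m4$metabolites$formula[2]))
  expect_true(is.na(m4$metabolites$charge[3]))
})

test_that("an empty model writes valid SBML", {
  comp <- tibble::tibble(id = "c", name = "c")
  m <- metabolic_model(comp,
                       tibble::tibble(id = character(), name = character(),
                                      compartment = character()),
                       tibble::tibble(id = character()),
                       tibble::tibble(reaction = character(),
                                      metabolite = character(),
                                      coefficient = numeric()),
                       objective_id = NA_character_)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_equal(nrow(m2$reactions), 0)
  s <- model_summary(m2)
  expect_true(all(s[, c("n_genes", "n_metabolites",
                        "n_metabolic_reactions")] == 0))
})

test_that("dangling metabolite references raise an integrity error", {
  path <- withr::local_tempfile(fileext = ".xml")
  m <- example_toy_model()
  write_sbml(m, path)
  txt <- readLines(path)
  txt <- sub('species="A" stoichiometry="1"', 'species="GHOST" stoichiometry="1"', txt)
  writeLines(txt, path)
  expect_error(read_sbml(path), "GHOST")
  expect_error(read_sbml(withr::local_tempfile(fileext = ".xml")), "no such file")
})

test_that("malformed XML errors name the problem", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c("<sbml><model><unclosed>"), path)
  expect_error(read_sbml(path))
})

test_that("stoichiometric matrix has declared order and signed coefficients", {
  m <- example_toy_model()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(nrow(m$metabolites), nrow(m$reactions)))
  expect_equal(S["A", "R1"], -1)
  expect_equal(S["B", "R1"], 1)
  # a 2A -> B column
  comp <- tibble::tibble(id = "c", name = "c")
  met <- tibble::tibble(id = c("A", "B"), compartment = "c")
  rxn <- tibble::tibble(id = "R", lower_bound = 0, upper_bound = 10)
  sto <- tibble::tibble(reaction = "R", metabolite = c("A", "B"),
                        coefficient = c(-2, 1))
  m2 <- metabolic_model(comp, met, rxn, sto, "R")
  expect_equal(as.numeric(stoichiometric_matrix(m2)[, "R"]), c(-2, 1))
})

test_that("balance checking finds seeded elemental and charge imbalances", {
  comp <- tibble::tibble(id = "c", name = "c")
  met <- tibble::tibble(id = c("glc", "o2", "co2", "h2o", "Aminus", "B0"),
                        compartment = "c",
                        formula = c("C6H12O6", "O2", "CO2", "H2O", "C", "C"),
                        charge = c(0L, 0L, 0L, 0L, -1L, 0L))
  rxn <- tibble::tibble(id = c("resp", "chg"), lower_bound = 0,
                        upper_bound = 10, category = "metabolic")
  sto <- tibble::tibble(
    reaction = c(rep("resp", 4), "chg", "chg"),
    metabolite = c("glc", "o2", "co2", "h2o", "Aminus", "B0"),
    coefficient = c(-1, -6, 6, 6, -1, 1))
  m <- metabolic_model(comp, met, rxn, sto, "resp")
  res <- check_balance(m)
  expect_equal(res$quantity[res$reaction == "chg"], "charge")
  expect_equal(res$imbalance[res$reaction == "chg"], 1)
  expect_false("resp" %in% res$reaction[res$quantity %in% c("C", "O")])
  # delete one water: H -2 (flagged as proton convention) and O -1
  m$stoichiometry$coefficient[m$stoichiometry$metabolite == "h2o"] <- 5
  res2 <- check_balance(m, elements = c("C", "H", "O"))
  rr <- res2[res2$reaction == "resp", ]
  expect_equal(rr$imbalance[rr$quantity == "O"], -1)
  expect_equal(rr$imbalance[rr$quantity == "H"], -2)
  expect_equal(rr$flag[rr$quantity == "H"], "proton_convention")
  # unknown composition is a finding, not an error
  m$metabolites$formula[1] <- NA
  res3 <- check_balance(m)
  expect_true("unknown composition" %in%
                res3$quantity[res3$reaction == "resp"])
})

test_that("the core model is balanced for C, N, O, P, S and charge", {
  expect_equal(nrow(check_balance(core_default())), 0)
  expect_equal(nrow(check_balance(core_all())), 0)
  expect_equal(nrow(check_balance(core_shunt())), 0)
})

test_that("summary counts are additive and match the generator manifest", {
  m <- core_default()
  s <- model_summary(m)
  manifest <- attr(m, "manifest")
  expect_equal(s$n_metabolic_reactions, unname(manifest[["metabolic"]]))
  expect_equal(s$n_transport, unname(manifest[["transport"]]))
  expect_equal(s$n_spontaneous, unname(manifest[["spontaneous"]]))
  expect_equal(s$n_metabolites, nrow(m$metabolites))
  expect_equal(s$n_compartments, 2)
  # categories partition the reaction set
  expect_equal(sum(manifest), nrow(m$reactions))
  # enzymes: distinct gene associations over metabolic + transport reactions
  scope <- m$reactions$category %in% c("metabolic", "transport")
  expect_equal(s$n_enzymes,
               length(unique(m$reactions$gene_association[
                 scope & m$reactions$gene_association != ""])))
})

test_that("category inference classifies exchange, transport, metabolic", {
  m <- example_toy_model()
  m2 <- infer_categories(m, spontaneous_ids = "R7")
  expect_equal(m2$reactions$category[m2$reactions$id == "EX_A"], "exchange")
  expect_equal(m2$reactions$category[m2$reactions$id == "T_A"], "transport")
  expect_equal(m2$reactions$category[m2$reactions$id == "R1"], "metabolic")
  expect_equal(m2$reactions$category[m2$reactions$id == "R7"], "spontaneous")
})

test_that("model validation names the offending reaction", {
  m <- example_toy_model()
  m$stoichiometry$metabolite[5] <- "GHOST"
  expect_error(validate_model(m), "GHOST")
  m2 <- example_toy_model()
  m2$reactions$lower_bound[3] <- 2000
  expect_error(validate_model(m2), "lower bound")
})
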
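test_that("TSV loader parses minimal files and preserves coefficients", {
  net <- tsv_net("r1, A[c] -> B[e], irrev, 0, 1000")
  expect_equal(nrow(net$metabolites), 2L)
  expect_equal(nrow(net$reactions), 1L)
  expect_equal(unname(net$S[, "r1"]), c(-1, 1))

  net2 <- tsv_net("r1\t2 A[c] + B[c] -> 0.5 C[e]\tirrev\t0\t10")
  expect_equal(reaction_stoich(net2, "r1"),
               c("A[c]" = -2, "B[c]" = -1, "C[e]" = 0.5))
  expect_equal(net2$reactions$ub, 10)
})

test_that("loader reports malformed input with context", {
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(c("r1\tA[c] -> B[e]\tirrev\t0\t10", "r2\tA[c] + -> B[e]"), tf)
  expect_error(load_network(tf), "line 2")
  writeLines("r1\tA[q] -> B[e]", tf)
  expect_error(load_network(tf), "compartment")
  writeLines(c("r1\tA[c] -> B[e]", "r1\tB[e] -> A[c]"), tf)
  expect_error(load_network(tf), "duplicate")
})

test_that("write-then-load round trips reproduce S exactly (TSV and SBML)", {
  suite <- toy_network_suite()
  for (nm in names(suite)) {
    net <- suite[[nm]]$network
    tf <- tempfile(fileext = ".tsv")
    write_network_tsv(net, tf)
    back <- load_network(tf, format = "tsv")
    expect_equal(back$S[rownames(net$S), colnames(net$S)], net$S, tolerance = 0)
    expect_equal(back$reactions$reversible, net$reactions$reversible)
    unlink(tf)

    xf <- tempfile(fileext = ".xml")
    write_network_sbml(net, xf)
    back2 <- load_network(xf, format = "sbml")
    expect_equal(back2$S[rownames(net$S), colnames(net$S)], net$S)
    expect_equal(back2$reactions$lb, net$reactions$lb)
    expect_equal(back2$reactions$ub, net$reactions$ub)
    unlink(xf)
  }
})

test_that("packaged reduced network has the documented dimensions", {
  net <- fixture_network()
  expect_equal(nrow(net$reactions), 63L)
  expect_equal(sum(net$metabolites$compartment == "c"), 36L)
  expect_equal(sum(net$metabolites$compartment == "e"), 16L)
  expect_equal(nrow(stoichiometric_matrix(net, "extracellular")), 16L)
  expect_equal(net$objective, "biomass_lumped")
})

test_that("stoichiometric matrix rows partition into Si and Se", {
  net <- tsv_net("r1\tA[c] -> B[e]")
  expect_equal(unname(stoichiometric_matrix(net, "all")), matrix(c(-1, 1), 2))
  expect_equal(unname(stoichiometric_matrix(net, "intracellular")), matrix(-1, 1))
  expect_equal(unname(stoichiometric_matrix(net, "extracellular")), matrix(1, 1))
  for (nm in names(toy_network_suite())) {
    n2 <- toy_network_suite()[[nm]]$network
    S <- stoichiometric_matrix(n2, "all")
    Si <- stoichiometric_matrix(n2, "intracellular")
    Se <- stoichiometric_matrix(n2, "extracellular")
    expect_setequal(c(rownames(Si), rownames(Se)), rownames(S))
    expect_length(intersect(rownames(Si), rownames(Se)), 0)
    expect_equal(rbind(Si, Se)[rownames(S), ], S)
  }
})

test_that("split_reversible decouples reactions and is reversible", {
  net <- tsv_net(c("upt\tA[e] -> A[c]",
                   "r\tA[c] <=> B[c]\trev\t-5\t8",
                   "sec\tB[c] -> B[e]"))
  sp <- split_reversible(net)
  expect_equal(nrow(sp$reactions), 4L) # 2 irreversible + 2 x 1 reversible
  expect_true(all(!sp$reactions$reversible))
  expect_true(all(sp$reactions$lb >= 0))
  expect_equal(sp$S[, "r_f"], -sp$S[, "r_b"])
  expect_equal(sp$reactions$ub[sp$reactions$id == "r_f"], 8)
  expect_equal(sp$reactions$ub[sp$reactions$id == "r_b"], 5)

  merged <- merge_split_reactions(sp)
  expect_equal(nrow(merged$reactions), nrow(net$reactions))
  expect_equal(merged$S[rownames(net$S), colnames(net$S)], net$S)

  irr <- tsv_net("r1\tA[c] -> B[e]")
  expect_equal(split_reversible(irr)$S, irr$S)
})

test_that("elemental imbalance detects forced arithmetic and missing formulas", {
  net <- tsv_net("r1\tA[c] -> B[e]")
  net$metabolites$formula <- c("C6H12O6", "C6H12O6")
  bal <- elemental_imbalance(net, "r1")
  expect_true(all(abs(bal) < 1e-12))

  net$metabolites$formula <- c("C6H12O6", "C5H12O6")
  expect_equal(elemental_imbalance(net, "r1", elements = "C"), c(C = -1))

  net$metabolites$formula <- c("C6H12O6", NA)
  expect_error(elemental_imbalance(net, "r1"), "B\\[e\\]")
  expect_equal(elemental_imbalance(net, "r1", ignore = "B[e]", elements = "C"),
               c(C = -6))
})

test_that("the packaged network is carbon balanced (pseudo-species exempt)", {
  net <- fixture_network()
  exempt <- "salts[e]"
  for (id in net$reactions$id) {
    imb <- elemental_imbalance(net, id, ignore = exempt, elements = c("C", "N"))
    expect_lt(abs(imb[["C"]]), 1e-9)
  }
})

test_that("molar mass per carbon matches hand sums and the biomass composition", {
  expect_equal(molar_mass_per_carbon("C"), 12.011)
  expect_equal(molar_mass_per_carbon("CH2O"), 12.011 + 2 * 1.008 + 15.999)
  expect_equal(molar_mass_per_carbon(biomass_formula), 26.401, tolerance = 0.005)
  expect_error(molar_mass_per_carbon("H2O"), "carbon")
  expect_error(molar_mass(NULL), "formula")
})

test_that("formula parsing handles fractional subscripts and pseudo-species", {
  f <- parse_formula("C3.69H6.76O2.66N0.25S0.010")
  expect_equal(f[["C"]], 3.69)
  expect_equal(f[["S"]], 0.010)
  expect_null(parse_formula(NA))
  expect_null(parse_formula(""))
  expect_equal(carbon_count("H2O"), 0)
  expect_error(parse_formula("C6H12O6!"), "parse")
})
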
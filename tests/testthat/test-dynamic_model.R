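# carbon-closed toy macro reactions derived from the branched fermentation
# network (hexose substrate, biomass in C-mol)
ferment_macros <- function() {
  tc <- toy_network_suite()$ferment
  net <- tc$network
  efms <- enumerate_efms(net, substrate_id = tc$substrate_id)
  kept <- filter_efms(efms, net, tc$substrate_id, tc$biomass_id)
  all3 <- efms
  macros <- lapply(seq_len(n_efms(all3)), function(i) {
    m <- macroscopic_reaction(all3, net, tc$substrate_id, index = i,
                              id = paste0("m", i))
    # rename species to canonical names for the model builder
    names(m$coef) <- c("S[e]" = "substrate", "Ac[e]" = "acetate",
                       "Fo[e]" = "formate", "Su[e]" = "succinate",
                       "N[e]" = "ammonium", "X[e]" = "biomass")[names(m$coef)]
    m$substrate_id <- "substrate"
    # X is a C1 biomass unit: convert mol/mol to g/mmol with 26.401 g/C-mol
    if ("biomass" %in% names(m$coef)) {
      m$biomass_id <- "biomass"
      m$coef[["biomass"]] <- m$coef[["biomass"]] * biomass_g_per_mol_c / 1000
    }
    m
  })
  names(macros) <- vapply(macros, function(m) m$id, "")
  macros
}

test_that("macroscopic reactions equal the extracellular image of a mode", {
  tc <- toy_network_suite()$ferment
  net <- tc$network
  efms <- enumerate_efms(net, substrate_id = tc$substrate_id)
  # hand product: acetate route converts 1 hexose into 2 acetate + 2 formate
  i_ac <- which(drop(stoichiometric_matrix(net, "extracellular")["Ac[e]", ] %*%
                       efms$modes) > 1e-9)
  m <- macroscopic_reaction(efms, net, tc$substrate_id, index = i_ac)
  expect_equal(m$coef[["S[e]"]], -1)
  expect_equal(m$coef[["Ac[e]"]], 2)
  expect_equal(m$coef[["Fo[e]"]], 2)

  # a mode not using the substrate has no macroscopic reaction
  storage <- tsv_net(c("upt\tA[e] -> A[c]", "sec\tA[c] -> B[e]",
                       "other\tC[e] -> D[e]"))
  ef2 <- enumerate_efms(storage)
  other_idx <- which(ef2$modes["other", ] > 1e-9)
  expect_error(macroscopic_reaction(ef2, storage, "A[e]", index = other_idx),
               "does not use")
})

test_that("packaged macro table round trips and reproduces the e5 column", {
  macros <- glucose_macro_reactions()
  expect_length(macros, 9L)
  e5 <- macros$e5
  expect_equal(e5$coef[["substrate"]], -1)
  expect_equal(e5$coef[["succinate"]], 1.562)
  expect_equal(e5$coef[["biomass"]], 0.012)
  expect_equal(e5$coef[["ammonium"]], -0.087)
  tf <- tempfile(fileext = ".csv"); on.exit(unlink(tf))
  write_macro_table(macros, tf)
  back <- read_macro_table(tf, substrate_id = "glucose")
  for (id in names(macros)) {
    expect_equal(back[[id]]$coef[names(macros[[id]]$coef)], macros[[id]]$coef)
  }
})

test_that("macro table validation rejects sign violations", {
  tf <- tempfile(fileext = ".csv"); on.exit(unlink(tf))
  writeLines(c("species,e1", "substrate,-2", "acetate,1"), tf)
  expect_error(read_macro_table(tf), "must be -1")
  writeLines(c("species,e1", "substrate,-1", "acetate,-0.5"), tf)
  expect_error(read_macro_table(tf), "negative coefficient")
  writeLines(c("species,e1", "substrate,-1", "atp,0.5"), tf)
  expect_error(read_macro_table(tf), "positive coefficient")
})

test_that("Monod kinetics: half saturation, saturation limit, hand value", {
  expect_equal(monod_rate(9e-3, 1e-3, 0.31, 9e-3), 0.31 * 1e-3 / 2)
  expect_equal(monod_rate(9e-3, 1e-3, 0.31, 9e-3), 1.55e-4)
  expect_equal(monod_rate(1e6, 2, 0.5, 9e-3), 0.5 * 2, tolerance = 1e-6)
  expect_equal(monod_rate(0, 1, 0.5, 9e-3), 0)
  expect_error(monod_rate(-1, 1, 0.5, 9e-3), "negative")
})

test_that("Contois kinetics: biomass-scaled saturation and Monod limit", {
  expect_equal(contois_rate(0.02, 0.01, 0.4, 2), 0.4 * 0.01 / 2) # s = Kc B
  # rate vanishes linearly in B as B -> 0
  r1 <- contois_rate(0.01, 1e-6, 0.4, 2)
  r2 <- contois_rate(0.01, 2e-6, 0.4, 2)
  expect_equal(r2 / r1, 2, tolerance = 1e-3)
  # Kc -> 0 recovers mu_max * B
  expect_equal(contois_rate(0.01, 0.5, 0.4, 0), 0.4 * 0.5)
  expect_error(contois_rate(1, 1, -0.1, 1), "negative")
})

test_that("Contois rate per biomass falls with B while Monod stays flat", {
  B <- c(0.001, 0.01, 0.1)
  per_b_monod <- vapply(B, function(b) monod_rate(0.01, b, 0.3, 9e-3) / b, 0)
  per_b_contois <- vapply(B, function(b) contois_rate(0.01, b, 0.3, 2) / b, 0)
  expect_lt(diff(range(per_b_monod)), 1e-12)
  expect_true(all(diff(per_b_contois) < 0))
})

test_that("carbon is conserved along trajectories of carbon-closed models", {
  macros <- ferment_macros()
  params <- kinetic_params(mu_max = c(0.05, 0.08, 0.2), K = 9e-3, kd = 0,
                           alpha = 6.15e-4)
  model <- build_dmm(macros, params, substrate_carbon = 6)
  expect_lt(max(abs(macro_carbon_balance(model))), 1e-9)
  init <- c(substrate = 0.0166, biomass = 3e-5, ammonium = 0.03)
  traj <- simulate_dmm(model, init, seq(0, 24, by = 0.5))
  tot <- trajectory_carbon(traj, model)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  expect_true(all(as.matrix(traj[, model$states]) >= 0))
})

test_that("a model with B(0) = 0 stays constant", {
  model <- glucose_reference_model()
  traj <- simulate_dmm(model, c(substrate = 0.0166, biomass = 0, ammonium = 0.03),
                       c(0, 10, 24))
  expect_equal(traj$substrate, rep(0.0166, 3))
  expect_equal(traj$biomass, rep(0, 3))
})

test_that("with s = 0 biomass decays with the closed-form death kinetics", {
  model <- glucose_reference_model()
  B0 <- 0.01
  tt <- c(0, 6, 12, 24)
  traj <- simulate_dmm(model, c(substrate = 0, biomass = B0, ammonium = 0.03), tt)
  expect_equal(traj$biomass, B0 * exp(-model$params$kd * tt), tolerance = 1e-7)
})

test_that("refining the output grid does not move shared states", {
  model <- glucose_reference_model()
  init <- c(substrate = 0.0166, biomass = 3e-5, ammonium = 0.03)
  coarse <- simulate_dmm(model, init, seq(0, 24, by = 2))
  fine <- simulate_dmm(model, init, seq(0, 24, by = 1))
  shared <- fine[fine$time %in% coarse$time, model$states]
  expect_equal(unname(as.matrix(shared)), unname(as.matrix(coarse[, model$states])),
               tolerance = 1e-6)
})

test_that("substrate consumption is monotone in mu_max", {
  macros <- ferment_macros()
  left <- vapply(c(0.02, 0.05, 0.1, 0.3), function(mu) {
    params <- kinetic_params(mu_max = rep(mu, 3), K = 9e-3, kd = 0)
    model <- build_dmm(macros, params, substrate_carbon = 6)
    traj <- simulate_dmm(model, c(substrate = 0.0166, biomass = 3e-5,
                                  ammonium = 0.03), c(0, 12))
    traj$substrate[2]
  }, 0)
  expect_true(all(diff(left) < 0))
})

test_that("deSolve trajectories agree with an independent RK4 integrator", {
  model <- glucose_reference_model()
  init <- c(substrate = 0.0166, biomass = 3e-5, ammonium = 0.03)
  tt <- c(0, 4, 8, 12)
  traj <- simulate_dmm(model, init, tt)
  y0 <- stats::setNames(numeric(nrow(model$stoich)), rownames(model$stoich))
  y0[names(init)] <- init
  rhs <- function(y) {
    rho <- gem2dmm:::reaction_rates(y[["substrate"]], y[["biomass"]], model$params)
    dy <- drop(model$stoich %*% rho)
    dy["biomass"] <- dy["biomass"] - model$params$kd * max(y[["biomass"]], 0)
    dy
  }
  ref <- rk4_integrate(rhs, y0, tt, n_sub = 2000L)
  for (sp in c("substrate", "biomass", "acetate", "succinate")) {
    expect_equal(traj[[sp]], unname(ref[, sp]), tolerance = 1e-5)
  }
})

test_that("kinetic parameter validation enforces one saturation constant", {
  expect_error(kinetic_params(0.1), "exactly one")
  expect_error(kinetic_params(0.1, K = 9e-3, Kc = 2), "exactly one")
  expect_error(kinetic_params(-0.1, K = 9e-3), "non-negative")
  p <- kinetic_params(c(0.1, 0.2), Kc = 2)
  expect_equal(p$kinetics, "contois")
  expect_error(build_dmm(glucose_macro_reactions()[1:3], p), "one mu_max per")
})
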
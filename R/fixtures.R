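#' Packaged synthetic reduced network
#'
#' Loads the synthetic reduced fermentation network shipped with the
#' package: a constructed stand-in mirroring the structure of a reduced
#' genome-derived model of a cellulolytic, succinate-producing anaerobe —
#' 63 reactions over 36 intracellular and 16 extracellular species,
#' with EMP glycolysis on a PPi-dependent phosphofructokinase, the PEP
#' carboxykinase route to succinate, pyruvate-formate lyase and acetate
#' kinase, a six-glucose glycogen cycle with the five-glucose glucan
#' balance reaction, cellobiose/cellodextrin phosphorolysis and a lumped
#' biomass reaction with the C3.69H6.76O2.66N0.25S0.010 composition.
#' Carbon (and nitrogen, where closed) balance exactly; water and charge
#' are implicit.
#'
#' @return A `metabolic_network`.
#' @export
example_reduced_network <- function() {
  load_network(system.file("extdata", "reduced_network_synthetic.tsv",
                           package = "gem2dmm", mustWork = TRUE),
               format = "tsv",
               metabolite_file = system.file(
                 "extdata", "reduced_network_synthetic_metabolites.csv",
                 package = "gem2dmm", mustWork = TRUE))
}

#' Packaged macroscopic reactions for glucose fermentation
#'
#' The stoichiometry of the nine yield-space polygon modes (e1-e9) of
#' glucose fermentation by *Fibrobacter succinogenes* S85, in the canonical
#' table format: substrate -1, biomass in g per mmol glucose, all other
#' species in mol per mol glucose; glycogen in six-glucose storage units.
#'
#' @return Named list of `macro_reaction`s.
#' @export
glucose_macro_reactions <- function() {
  read_macro_table(system.file("extdata", "macro_reactions_glucose.csv",
                               package = "gem2dmm", mustWork = TRUE),
                   substrate_id = "glucose")
}

#' Reference dynamic model of glucose fermentation
#'
#' The four-reaction Monod model of glucose fermentation by
#' *F. succinogenes* S85: macroscopic reactions e2, e5, e6 and e9 with
#' rate constants 0.037, 0.031, 0.31 and 0.004 /h, Monod constant
#' 9e-3 M, death rate 8.33e-4 /h and OD conversion 6.15e-4 M/OD.
#'
#' @return A `dynamic_model`.
#' @export
glucose_reference_model <- function() {
  macros <- glucose_macro_reactions()[c("e2", "e5", "e6", "e9")]
  build_dmm(macros,
            kinetic_params(mu_max = c(0.037, 0.031, 0.31, 0.004),
                           K = 9e-3, kd = 8.33e-4, alpha = 6.15e-4),
            substrate_carbon = 6)
}
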
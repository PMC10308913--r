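# canonical species vocabulary of macroscopic reactions (the row format of
# the packaged macro-reaction tables); bookkeeping species are balanced by
# the medium / the reduction and are not tracked as concentrations
MACRO_SPECIES <- c("substrate", "salts", "atp", "co2", "co_a", "ammonium",
                   "biomass", "acetate", "succinate", "formate",
                   "proton_c", "proton_e", "glycogen", "ppi")
BOOKKEEPING_SPECIES <- c("salts", "atp", "co_a", "proton_c", "proton_e", "ppi")

# carbon content per canonical unit: hexose substrate basis; glycogen is a
# six-glucose storage unit (36 C per table unit); biomass is handled in
# C-mol separately
CARBON_PER_UNIT <- c(substrate = 6, co2 = 1, acetate = 2, succinate = 4,
                     formate = 1, glycogen = 36, ammonium = 0, salts = 0,
                     atp = 10, co_a = 21, ppi = 0, proton_c = 0, proton_e = 0,
                     biomass = NA)

#' Macroscopic reaction of one elementary flux mode
#'
#' The extracellular net conversion `Se e` of a mode, rescaled so the
#' substrate coefficient is exactly -1. The biomass entry is converted to
#' grams per mmol of substrate via the biomass molar mass (26.401 g/C-mol
#' for a formula-less C-mol bookkeeping species).
#'
#' @param e One EFM: a named flux vector, or an `efm_set` together with
#'   `index`.
#' @param net The network.
#' @param substrate_id Extracellular substrate id.
#' @param biomass_id Extracellular biomass species id (optional).
#' @param index Column to take when `e` is an `efm_set`.
#' @param id Identifier for the macro reaction.
#' @return A `macro_reaction`: list with `id`, `substrate_id`, `coef`
#'   (named extracellular coefficients, substrate -1, biomass in g/mmol).
#' @export
macroscopic_reaction <- function(e, net, substrate_id, biomass_id = NULL,
                                 index = 1L, id = NULL) {
  v <- if (inherits(e, "efm_set")) e$modes[, index] else e
  Se <- stoichiometric_matrix(net, "extracellular")
  conv <- drop(Se %*% v[colnames(Se)])
  ws <- resolve_exchange(net, substrate_id)
  upt <- abs(sum(ws * v[names(ws)]))
  if (upt < 1e-12) stop("mode does not use the substrate; no macroscopic reaction")
  conv <- conv / upt
  if (max(abs(conv)) < 1e-12) stop("mode has an empty extracellular image")
  sub_row <- if (substrate_id %in% rownames(Se)) substrate_id else NULL
  if (!is.null(sub_row)) conv[sub_row] <- -1
  if (!is.null(biomass_id) && biomass_id %in% names(conv)) {
    i <- match(biomass_id, net$metabolites$id)
    f <- net$metabolites$formula[i]
    gpm <- if (!is.na(f) && nzchar(f)) molar_mass(f) else biomass_g_per_mol_c
    conv[biomass_id] <- conv[biomass_id] * gpm / 1000
  }
  coef <- conv[abs(conv) > 1e-12]
  structure(list(id = if (is.null(id)) "macro" else id,
                 substrate_id = substrate_id, biomass_id = biomass_id,
                 coef = coef),
            class = "macro_reaction")
}

#' @export
print.macro_reaction <- function(x, ...) {
  cat(sprintf("macro_reaction %s (substrate %s):\n", x$id, x$substrate_id))
  print(round(x$coef, 4))
  invisible(x)
}

#' Read a macroscopic-reaction table
#'
#' CSV with one row per canonical species (`species` column using the
#' vocabulary substrate/salts/atp/co2/co_a/ammonium/biomass/acetate/
#' succinate/formate/proton_c/proton_e/glycogen/ppi) and one column per
#' macroscopic reaction. The substrate row must be -1 in every column;
#' biomass is in g per mmol substrate, all other species mol per mol.
#'
#' @param path CSV file.
#' @param substrate_id Name of the carbon substrate the table refers to.
#' @return Named list of `macro_reaction`s.
#' @export
read_macro_table <- function(path, substrate_id = "glucose") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species" %in% names(df)) stop("macro table needs a 'species' column")
  sp <- df$species
  unknown <- setdiff(sp, MACRO_SPECIES)
  if (length(unknown)) stop(sprintf("unknown macro species row(s): %s",
                                    paste(unknown, collapse = ", ")))
  cols <- setdiff(names(df), "species")
  out <- list()
  for (cn in cols) {
    coef <- stats::setNames(as.numeric(df[[cn]]), sp)
    if (abs(coef[["substrate"]] + 1) > 1e-9) {
      stop(sprintf("macro reaction '%s': substrate coefficient must be -1", cn))
    }
    if (!is.na(coef["biomass"]) && coef[["biomass"]] < 0) {
      stop(sprintf("macro reaction '%s': negative biomass yield", cn))
    }
    prod_rows <- intersect(c("acetate", "succinate", "formate", "glycogen"), sp)
    cons_rows <- intersect(c("salts", "atp", "co_a", "ammonium"), sp)
    if (any(coef[prod_rows] < -1e-12, na.rm = TRUE)) {
      stop(sprintf("macro reaction '%s': fermentation product with negative coefficient", cn))
    }
    if (any(coef[cons_rows] > 1e-12, na.rm = TRUE)) {
      stop(sprintf("macro reaction '%s': consumed currency species with positive coefficient", cn))
    }
    coef <- coef[!is.na(coef) & abs(coef) > 0 | names(coef) %in% c("substrate", "biomass")]
    out[[cn]] <- structure(list(id = cn, substrate_id = substrate_id,
                                biomass_id = "biomass", coef = coef),
                           class = "macro_reaction")
  }
  out
}

#' Write macro reactions in the table format read by [read_macro_table()]
#' @param macros Named list of `macro_reaction`s.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_macro_table <- function(macros, path) {
  species <- Reduce(union, lapply(macros, function(m) names(m$coef)))
  species <- c(intersect(MACRO_SPECIES, species), setdiff(species, MACRO_SPECIES))
  df <- data.frame(species = species, stringsAsFactors = FALSE)
  for (m in macros) {
    col <- stats::setNames(numeric(length(species)), species)
    col[names(m$coef)] <- m$coef
    df[[m$id]] <- col
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a macroscopic network from macro reactions
#'
#' Builds a small `metabolic_network` whose reactions are the macroscopic
#' reactions on a hexose-equivalent basis plus uptake reactions for the
#' carbon sources (cellobiose counts as 2 and cellulose as 4 glucose
#' equivalents). Useful for LP yield analysis of the macroscopic model —
#' maximum yields over this network equal the maxima over the generating
#' modes.
#'
#' @param macros Named list of `macro_reaction`s (hexose basis, substrate -1).
#' @param substrates Named numeric vector substrate -> hexose equivalents.
#' @return A `metabolic_network` with one internal species `hexose[c]`.
#' @export
macro_network <- function(macros,
                          substrates = c(glucose = 1, cellobiose = 2, cellulose = 4)) {
  species <- Reduce(union, lapply(macros, function(m) setdiff(names(m$coef), "substrate")))
  met_ids <- c("hexose[c]", paste0(names(substrates), "[e]"),
               paste0(species, "[e]"))
  mets <- data.frame(id = met_ids,
                     name = sub("\\[[ce]\\]$", "", met_ids),
                     compartment = c("c", rep("e", length(met_ids) - 1L)),
                     formula = NA_character_, stringsAsFactors = FALSE)
  rids <- c(paste0("uptake_", names(substrates)),
            vapply(macros, function(m) m$id, ""))
  S <- matrix(0, length(met_ids), length(rids), dimnames = list(met_ids, rids))
  for (k in seq_along(substrates)) {
    S[paste0(names(substrates)[k], "[e]"), k] <- -1
    S["hexose[c]", k] <- substrates[[k]]
  }
  for (m in macros) {
    j <- match(m$id, rids)
    S["hexose[c]", j] <- -1
    for (sp in setdiff(names(m$coef), "substrate")) {
      S[paste0(sp, "[e]"), j] <- m$coef[[sp]]
    }
  }
  metabolic_network(mets,
                    data.frame(id = rids, reversible = FALSE, lb = 0, ub = 1000,
                               stringsAsFactors = FALSE),
                    S)
}
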
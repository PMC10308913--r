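#' Design of a simulated batch-culture experiment
#'
#' Defaults mirror anaerobic batch cultures on 3 g/L carbohydrate sampled
#' at 0, 5, 9, 13, 17, 20 and 24 h in triplicate, with ~5% proportional
#' measurement noise on six observed variables. Optical density is not
#' observed on cellulose (particulate substrate).
#'
#' @param substrate `"glucose"`, `"cellobiose"` or `"cellulose"`.
#' @param initial_substrate_gL Initial carbohydrate (g/L), default 3.
#' @param times Sampling times (h).
#' @param replicates Number of replicate cultures, default 3.
#' @param noise_cv Coefficient of variation of measurement noise, default 0.05.
#' @param seed RNG seed.
#' @param observe_od Measure OD? Default: not for cellulose.
#' @return An `experiment_design`.
#' @export
experiment_design <- function(substrate = c("glucose", "cellobiose", "cellulose"),
                              initial_substrate_gL = 3,
                              times = c(0, 5, 9, 13, 17, 20, 24),
                              replicates = 3, noise_cv = 0.05, seed = 1,
                              observe_od = substrate != "cellulose") {
  substrate <- match.arg(substrate)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (replicates < 1) stop("replicates >= 1 required")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(substrate = substrate,
                 initial_substrate_gL = initial_substrate_gL,
                 times = times, replicates = replicates,
                 noise_cv = noise_cv, seed = seed, observe_od = observe_od),
            class = "experiment_design")
}

#' Molar masses of the carbon substrates (g/mol)
#'
#' Glucose 180.16, cellobiose 342.30; cellulose is handled as a
#' four-anhydroglucose unit (4 x 162.14 = 648.56 g/mol).
#' @export
substrate_molar_mass <- c(glucose = 180.16, cellobiose = 342.30,
                          cellulose = 648.56)

#' Initial substrate concentration for a design (mol/L)
#' @param design An `experiment_design`.
#' @return mol/L of the native substrate unit.
#' @export
initial_substrate_molar <- function(design) {
  design$initial_substrate_gL / substrate_molar_mass[[design$substrate]]
}

# default initial ammonia pool of the defined medium (M); generous enough
# that nitrogen never limits growth on 3 g/L carbohydrate
INITIAL_AMMONIUM_M <- 0.03

# absolute detection floors per variable (sd is never below these)
DETECTION_FLOOR <- c(substrate = 1e-4, acetate = 1e-4, succinate = 1e-4,
                     formate = 1e-4, ammonia = 1e-4, od = 0.01)

#' Generate a simulated batch-culture dataset
#'
#' Simulates the true model, samples it at the design's time points and
#' adds independent Gaussian noise with standard deviation
#' `noise_cv * |signal|`, floored at a per-variable detection limit and
#' clipped at zero. Deterministic given the design seed.
#'
#' @param true_model A `dynamic_model` whose kinetics match the substrate
#'   (Monod for soluble, Contois for cellulose).
#' @param design An `experiment_design`.
#' @param init Named initial state; default: substrate from the design,
#'   biomass from an inoculum of OD 0.05 (`alpha * 0.05`).
#' @return A `time_series_data` with attribute `truth` (the noise-free
#'   sampled trajectory).
#' @export
generate_experiment <- function(true_model, design, init = NULL) {
  if (design$substrate == "cellulose" && true_model$params$kinetics != "contois") {
    stop("cellulose is particulate: the true model must use Contois kinetics")
  }
  if (design$substrate != "cellulose" && true_model$params$kinetics != "monod") {
    stop("soluble substrates use Monod kinetics")
  }
  if (is.null(init)) init <- default_initial_state(design, true_model)
  times <- design$times
  sim_times <- if (times[1] > 0) c(0, times) else times
  traj <- simulate_dmm(true_model, init, sim_times)
  traj <- traj[match(times, traj$time), , drop = FALSE]
  vars <- c("substrate", "acetate", "succinate", "formate", "ammonia",
            if (design$observe_od) "od")
  vars <- vars[vapply(vars, function(v)
    !is.null(tryCatch(variable_prediction(traj, v), error = function(e) NULL)), TRUE)]
  set.seed(design$seed)
  obs <- list()
  for (v in vars) {
    signal <- variable_prediction(traj, v)
    sdv <- pmax(design$noise_cv * abs(signal), DETECTION_FLOOR[[v]] * design$noise_cv)
    m <- matrix(NA_real_, design$replicates, length(times))
    for (r in seq_len(design$replicates)) {
      m[r, ] <- pmax(signal + stats::rnorm(length(signal), 0, sdv), 0)
    }
    obs[[v]] <- m
  }
  out <- time_series_data(times, obs, substrate = design$substrate)
  attr(out, "truth") <- traj
  out
}

#' Default initial state of a batch culture
#'
#' Substrate from the design's g/L value, biomass from an inoculum of
#' OD 0.05 (`alpha * 0.05` C-mol/L), and a 30 mM ammonia pool (nitrogen in
#' the defined medium is non-limiting for 3 g/L carbohydrate). All other
#' states start at zero.
#'
#' @param design An `experiment_design`.
#' @param model The `dynamic_model` (supplies `alpha`).
#' @return Named initial-state vector.
#' @export
default_initial_state <- function(design, model) {
  c(substrate = initial_substrate_molar(design),
    biomass = model$params$alpha * 0.05,
    ammonium = INITIAL_AMMONIUM_M)
}

#' Write/read the batch-culture CSV schema
#'
#' Long format: columns `time`, `variable`, `replicate`, `value`.
#' @param data A `time_series_data`.
#' @param path CSV file.
#' @return `path` (write) or a `time_series_data` (read).
#' @export
write_timeseries_csv <- function(data, path) {
  rows <- do.call(rbind, lapply(names(data$observations), function(v) {
    m <- data$observations[[v]]
    data.frame(time = rep(data$times, each = nrow(m)),
               variable = v,
               replicate = rep(seq_len(nrow(m)), length(data$times)),
               value = as.numeric(m))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @param substrate Substrate label for the container.
#' @export
read_timeseries_csv <- function(path, substrate = "glucose") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  times <- sort(unique(df$time))
  obs <- list()
  for (v in unique(df$variable)) {
    sub <- df[df$variable == v, ]
    reps <- sort(unique(sub$replicate))
    m <- matrix(NA_real_, length(reps), length(times))
    for (k in seq_len(nrow(sub))) {
      m[match(sub$replicate[k], reps), match(sub$time[k], times)] <- sub$value[k]
    }
    obs[[v]] <- m
  }
  time_series_data(times, obs, substrate = substrate)
}

#' Hand-constructed toy networks with verified expectations
#'
#' Five small networks exercising every stage of the pipeline, each with
#' its exact elementary-flux-mode count and maximum product yields
#' (obtained by hand and confirmed against brute-force enumeration in the
#' test suite): a linear chain, a diamond of parallel routes, a branched
#' fermentation with two products plus biomass, a chain with a futile
#' reversible two-cycle, and a storage (glycogen-like) branch.
#'
#' @return Named list; each element has `network`, `n_efms` (after futile
#'   two-cycle removal), `max_yields` (named, mol per mol substrate),
#'   `substrate_id`, and optionally `biomass_id`, `glycogen_id`.
#' @export
toy_network_suite <- function() {
  net_from_lines <- function(lines) {
    tf <- tempfile(fileext = ".tsv")
    on.exit(unlink(tf))
    writeLines(lines, tf)
    load_network(tf, format = "tsv")
  }
  chain <- net_from_lines(c(
    "upt\tglc[e] -> G[c]\tirrev\t0\t10",
    "conv\tG[c] -> P[c]\tirrev\t0\t1000",
    "sec\tP[c] -> P[e]\tirrev\t0\t1000"))
  diamond <- net_from_lines(c(
    "upt\tA[e] -> A[c]\tirrev\t0\t10",
    "b1\tA[c] -> B[c]\tirrev\t0\t1000",
    "b2\tA[c] -> C[c]\tirrev\t0\t1000",
    "j1\tB[c] -> D[c]\tirrev\t0\t1000",
    "j2\tC[c] -> D[c]\tirrev\t0\t1000",
    "sec\tD[c] -> D[e]\tirrev\t0\t1000"))
  # branched fermentation of a hexose: acetate+formate, succinate, biomass
  ferment <- net_from_lines(c(
    "upt\tS[e] -> G[c]\tirrev\t0\t10",
    "ac_path\tG[c] -> 2 Ac[c] + 2 Fo[c]\tirrev\t0\t1000",
    "su_path\tG[c] -> 1.5 Su[c]\tirrev\t0\t1000",
    "bio_path\tG[c] + 0.6 N[c] -> 6 X[c]\tirrev\t0\t1000",
    "n_upt\tN[e] -> N[c]\tirrev\t0\t1000",
    "ac_sec\tAc[c] -> Ac[e]\tirrev\t0\t1000",
    "fo_sec\tFo[c] -> Fo[e]\tirrev\t0\t1000",
    "su_sec\tSu[c] -> Su[e]\tirrev\t0\t1000",
    "x_sec\tX[c] -> X[e]\tirrev\t0\t1000"))
  futile <- net_from_lines(c(
    "upt\tA[e] -> A[c]\tirrev\t0\t10",
    "r\tA[c] <=> B[c]\trev\t-1000\t1000",
    "sec\tB[c] -> B[e]\tirrev\t0\t1000"))
  storage <- net_from_lines(c(
    "upt\tS[e] -> G[c]\tirrev\t0\t10",
    "product\tG[c] -> P[c]\tirrev\t0\t1000",
    "store\t6 G[c] -> Y[c]\tirrev\t0\t1000",
    "p_sec\tP[c] -> P[e]\tirrev\t0\t1000",
    "y_sec\tY[c] -> Y[e]\tirrev\t0\t1000"))
  list(
    chain = list(network = chain, n_efms = 1L,
                 max_yields = c("P[e]" = 1), substrate_id = "glc[e]"),
    diamond = list(network = diamond, n_efms = 2L,
                   max_yields = c("D[e]" = 1), substrate_id = "A[e]"),
    ferment = list(network = ferment, n_efms = 3L,
                   max_yields = c("Ac[e]" = 2, "Fo[e]" = 2, "Su[e]" = 1.5,
                                  "X[e]" = 6),
                   substrate_id = "S[e]", biomass_id = "X[e]"),
    futile = list(network = futile, n_efms = 1L,
                  max_yields = c("B[e]" = 1), substrate_id = "A[e]"),
    storage = list(network = storage, n_efms = 2L,
                   max_yields = c("P[e]" = 1, "Y[e]" = 1 / 6),
                   substrate_id = "S[e]", glycogen_id = "Y[e]"))
}
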
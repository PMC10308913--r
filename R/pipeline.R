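PIPELINE_KEYS <- c("network", "metabolite_file", "id_map", "outdir", "seed",
                   "stages", "fba", "reduce", "efm", "select", "simulate",
                   "calibrate", "synth")

#' Validate a pipeline configuration
#'
#' Schema-checks a configuration (YAML file or list) before any stage runs:
#' unknown top-level keys are rejected, stage toggles default to off, and a
#' global seed funnels all randomness.
#'
#' @param config Path to a YAML file or a named list.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  config$stages <- config$stages %||% character()
  allowed <- c("fba", "reduce", "efm", "select", "simulate", "calibrate", "synth")
  bad <- setdiff(config$stages, allowed)
  if (length(bad)) stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  config$seed <- config$seed %||% 1L
  config$outdir <- config$outdir %||% tempfile("gem2dmm_run_")
  structure(config, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the staged analysis pipeline
#'
#' Executes the requested stages in order (load -> fba -> reduce -> efm ->
#' select -> simulate -> calibrate -> synth), writing each stage's outputs
#' under the configured artifact directory together with a JSON manifest
#' recording input hashes, parameters, package version and the failure
#' point if any. Deterministic stages are byte-identical on rerun with the
#' same configuration; the manifest is always written, even on failure.
#'
#' @param config A [pipeline_config()] (or list/path coercible to one).
#' @return List with `status` (0 ok), `outdir`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    version = as.character(utils::packageVersion("gem2dmm")),
    seed = cfg$seed,
    stages = as.list(cfg$stages),
    inputs = list(),
    outputs = list(),
    failed_at = NULL)
  if (!is.null(cfg$network)) {
    manifest$inputs$network <- list(path = cfg$network,
                                    md5 = unname(tools::md5sum(cfg$network)))
  }
  status <- 0L
  state <- new.env(parent = emptyenv())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  run_stage <- function(name, fun) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed_at <<- list(stage = name, message = conditionMessage(res))
      status <<- 1L
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(res)),
           call. = FALSE)
    }
    invisible(res)
  }
  on.exit(write_manifest(), add = TRUE)
  tryCatch({
    if (length(cfg$stages)) {
      if (is.null(cfg$network)) stop("config needs a 'network' for the requested stages")
      state$net <- load_network(cfg$network, metabolite_file = cfg$metabolite_file,
                                id_map = cfg$id_map)
    }
    run_stage("fba", function() {
      opts <- cfg$fba %||% list()
      fv <- fba(state$net, objective = opts$objective %||% state$net$objective,
                bounds_override = opts$bounds)
      out <- file.path(cfg$outdir, "fba_fluxes.tsv")
      utils::write.table(data.frame(reaction = names(fv$values), flux = fv$values),
                         out, sep = "\t", row.names = FALSE, quote = FALSE)
      manifest$outputs$fba <<- list(path = out, status = fv$status,
                                    objective_value = fv$objective_value)
      state$flux <- fv
    })
    run_stage("reduce", function() {
      opts <- cfg$reduce %||% list()
      if (is.null(opts$protected)) stop("reduce stage needs 'protected' metabolites")
      fvs <- if (!is.null(state$flux)) list(state$flux)
             else stop("reduce stage needs the fba stage")
      red <- reduce_network(state$net, reduction_spec(opts$protected, fvs,
                                                      opts$blocked %||% character()))
      out <- file.path(cfg$outdir, "reduced_network.tsv")
      write_network_tsv(red$network, out)
      mp <- file.path(cfg$outdir, "reduction_mapping.json")
      jsonlite::write_json(red$mapping, mp, auto_unbox = FALSE, pretty = TRUE)
      manifest$outputs$reduce <<- list(network = out, mapping = mp,
                                       n_reactions = nrow(red$network$reactions))
      state$reduced <- red
    })
    run_stage("efm", function() {
      opts <- cfg$efm %||% list()
      net <- split_reversible(state$net)
      efms <- enumerate_efms(net, max_efms = opts$max_efms %||% 5e6,
                             substrate_id = opts$substrate)
      if (!is.null(opts$substrate) && !is.null(opts$biomass)) {
        efms <- filter_efms(efms, net, opts$substrate, opts$biomass, opts$glycogen)
      }
      out <- file.path(cfg$outdir, "efms.csv")
      utils::write.csv(t(efms$modes), out, quote = FALSE)
      manifest$outputs$efm <<- list(path = out, n_efms = n_efms(efms))
      state$efm_net <- net
      state$efms <- efms
    })
    run_stage("select", function() {
      opts <- cfg$select %||% list()
      if (is.null(state$efms)) stop("select stage needs the efm stage")
      yt <- efm_yields(state$efms, state$efm_net, opts$substrate %||% cfg$efm$substrate,
                       biomass_id = opts$biomass %||% cfg$efm$biomass)
      sel <- select_vertex_efms(yt, efms = state$efms)
      out <- file.path(cfg$outdir, "selection.json")
      jsonlite::write_json(list(selected = sel$selected_indices,
                                polygons = sel$polygon_vertices),
                           out, auto_unbox = FALSE, pretty = TRUE)
      macros <- lapply(sel$selected_indices, function(i) {
        macroscopic_reaction(state$efms, state$efm_net,
                             opts$substrate %||% cfg$efm$substrate,
                             biomass_id = opts$biomass %||% cfg$efm$biomass,
                             index = i, id = paste0("e", i))
      })
      mt <- file.path(cfg$outdir, "selected_macros.csv")
      write_macro_table(macros, mt)
      manifest$outputs$select <<- list(selection = out, macros = mt,
                                       n_selected = length(sel$selected_indices))
      state$selection <- sel
    })
    run_stage("simulate", function() {
      opts <- cfg$simulate %||% list()
      macros <- read_macro_table(opts$macros, substrate_id = opts$substrate %||% "glucose")
      params <- kinetic_params(mu_max = as.numeric(opts$mu_max),
                               K = opts$K, Kc = opts$Kc,
                               kd = opts$kd %||% 8.33e-4,
                               alpha = opts$alpha %||% 6.15e-4)
      model <- build_dmm(macros, params,
                         substrate_carbon = opts$substrate_carbon %||% 6)
      times <- opts$times %||% seq(0, 24, by = 0.5)
      traj <- simulate_dmm(model, unlist(opts$init), times)
      out <- file.path(cfg$outdir, "trajectory.csv")
      utils::write.csv(traj, out, row.names = FALSE, quote = FALSE)
      manifest$outputs$simulate <<- list(path = out, n_times = length(times))
      state$model <- model
    })
    run_stage("calibrate", function() {
      opts <- cfg$calibrate %||% list()
      data <- read_timeseries_csv(opts$data, substrate = opts$substrate %||% "glucose")
      if (is.null(state$model)) stop("calibrate stage needs the simulate stage (model template)")
      res <- calibrate(state$model, data, unlist(opts$init),
                       lambda = opts$lambda %||% 0,
                       n_starts = opts$n_starts %||% 20,
                       seed = cfg$seed)
      out <- file.path(cfg$outdir, "calibration.json")
      jsonlite::write_json(list(mu_max = res$estimates$mu_max,
                                alpha = res$estimates$alpha,
                                B0 = res$estimates$B0,
                                cost = res$cost, cvrmse = as.list(res$cvrmse),
                                active = res$active_efms,
                                converged = res$convergence),
                           out, auto_unbox = TRUE, pretty = TRUE, null = "null")
      manifest$outputs$calibrate <<- list(path = out, cost = res$cost)
    })
    run_stage("synth", function() {
      opts <- cfg$synth %||% list()
      if (is.null(state$model)) stop("synth stage needs the simulate stage (true model)")
      design <- experiment_design(substrate = opts$substrate %||% "glucose",
                                  replicates = opts$replicates %||% 3,
                                  noise_cv = opts$noise_cv %||% 0.05,
                                  seed = cfg$seed)
      data <- generate_experiment(state$model, design)
      out <- file.path(cfg$outdir, "synthetic_data.csv")
      write_timeseries_csv(data, out)
      manifest$outputs$synth <<- list(path = out)
    })
  }, error = function(e) {
    if (is.null(manifest$failed_at)) {
      manifest$failed_at <<- list(stage = "load", message = conditionMessage(e))
    }
    status <<- 1L
  })
  write_manifest()
  on.exit()
  list(status = status, outdir = cfg$outdir, manifest = manifest)
}
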
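#' Pipeline configuration
#'
#' Collects everything one reproducible run needs.  Two stage groups are
#' supported and either may be omitted: a geometry group (trajectory in,
#' observables / state labels / state statistics out) and a kinetics group
#' (simulate or load lifetimes, bin, fit, locate the peak).  All
#' stochastic stages derive from the single `seed`.
#'
#' @param trajectory_files character vector of trajectory paths (multi-
#'   model PDB, or coordinate tables with extension `.csv`/`.tsv`).
#' @param chain_a,chain_b chain identifiers of the two molecules.
#' @param preset_a,preset_b vector-definition preset names
#'   (`"pd1"`, `"pdl1"`, `"pdl2"`) for the two molecules, or `NULL` with
#'   explicit `def_a` / `def_b`.
#' @param def_a,def_b explicit [vector_definition()]s (override presets).
#' @param criteria an [interaction_criteria()].
#' @param pairs optional salt-bridge pair table (see
#'   [detect_salt_bridges()]).
#' @param low_center,high_center,hysteresis state-classification
#'   thresholds, degrees.
#' @param lifetime_file optional measured lifetime CSV; if absent and
#'   `simulate_model` is given, lifetimes are simulated.
#' @param simulate_model a [two_state_model()] used for simulation and as
#'   fit initialisation.
#' @param simulate_forces,simulate_n forces (pN) and draws per force for
#'   simulation.
#' @param bin_edges force bin edges, pN.
#' @param fit logical: fit the two-state model to the binned curve.
#' @param f_range force range for peak search, pN.
#' @param seed integer seed recorded in every output.
#' @param output_dir directory for outputs (created if needed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(trajectory_files = character(0),
                            chain_a = "A", chain_b = "B",
                            preset_a = NULL, preset_b = NULL,
                            def_a = NULL, def_b = NULL,
                            criteria = interaction_criteria(),
                            pairs = NULL,
                            low_center = 87, high_center = 157,
                            hysteresis = 10,
                            lifetime_file = NULL,
                            simulate_model = NULL,
                            simulate_forces = seq(1, 29, by = 2),
                            simulate_n = 100L,
                            bin_edges = seq(0, 30, by = 2.5),
                            fit = TRUE,
                            f_range = c(0, 30),
                            seed = 1L,
                            output_dir = ".") {
  for (f in c(trajectory_files, lifetime_file)) {
    if (!is.null(f) && !file.exists(f)) stop("input path missing: ", f)
  }
  if (is.null(def_a) && !is.null(preset_a)) {
    def_a <- vector_preset(preset_a, chain_a)
  }
  if (is.null(def_b) && !is.null(preset_b)) {
    def_b <- vector_preset(preset_b, chain_b)
  }
  structure(list(trajectory_files = trajectory_files,
                 chain_a = chain_a, chain_b = chain_b,
                 def_a = def_a, def_b = def_b, criteria = criteria,
                 pairs = pairs, low_center = low_center,
                 high_center = high_center, hysteresis = hysteresis,
                 lifetime_file = lifetime_file,
                 simulate_model = simulate_model,
                 simulate_forces = simulate_forces,
                 simulate_n = as.integer(simulate_n),
                 bin_edges = bin_edges, fit = fit, f_range = f_range,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the configured pipeline
#'
#' Executes the requested stage groups and writes all outputs plus a
#' manifest JSON (`manifest.json`) recording the seed, package version,
#' per-stage status and output paths.  A failing stage is recorded in the
#' manifest (status `"failed"`, with the error message) and later stages
#' of that group are skipped; the other group still runs.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(packageVersion("catchbond")),
                   stages = list())
  outfile <- function(name) file.path(config$output_dir, name)
  note <- function(stage, status, outputs = NULL, error = NULL) {
    manifest$stages[[stage]] <<- list(status = status, outputs = outputs,
                                      error = error)
  }

  # geometry group
  if (length(config$trajectory_files) > 0L) {
    res <- tryCatch({
      series_list <- list()
      for (i in seq_along(config$trajectory_files)) {
        f <- config$trajectory_files[i]
        traj <- if (grepl("\\.(csv|tsv)$", f, ignore.case = TRUE)) {
          read_coord_table(f, config$chain_a, config$chain_b)
        } else {
          read_trajectory(f, config$chain_a, config$chain_b)
        }
        obs <- extract_observables(traj, config$def_a, config$def_b,
                                   config$criteria, config$pairs)
        write_observables(obs, outfile(sprintf("observables_%02d.csv", i)))
        series_list[[i]] <- obs
      }
      note("observables", "complete",
           sprintf("observables_%02d.csv", seq_along(series_list)))
      state_list <- lapply(series_list, function(obs) {
        classify_frames(obs$angle_deg, config$low_center,
                        config$high_center, config$hysteresis)
      })
      for (i in seq_along(state_list)) {
        write.csv(as.data.frame(state_list[[i]]),
                  outfile(sprintf("states_%02d.csv", i)),
                  row.names = FALSE, quote = FALSE)
      }
      note("classify", "complete",
           sprintf("states_%02d.csv", seq_along(state_list)))
      stats <- state_statistics(series_list, state_list)
      jsonlite::write_json(stats, outfile("state_summary.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      note("stats", "complete", "state_summary.json")
      TRUE
    }, error = function(e) {
      note("geometry_group", "failed", error = conditionMessage(e))
      FALSE
    })
  }

  # kinetics group
  if (!is.null(config$lifetime_file) || !is.null(config$simulate_model)) {
    tryCatch({
      if (!is.null(config$lifetime_file)) {
        records <- read_lifetimes(config$lifetime_file)
        note("load_lifetimes", "complete", config$lifetime_file)
      } else {
        records <- simulate_lifetimes(config$simulate_model,
                                      config$simulate_forces,
                                      config$simulate_n, config$seed)
        write_lifetimes(records, outfile("lifetimes.csv"))
        note("simulate", "complete", "lifetimes.csv")
      }
      curve <- bin_lifetimes(records, config$bin_edges)
      write_curve(curve, outfile("curve.csv"))
      note("bin", "complete", "curve.csv")
      model <- config$simulate_model
      if (isTRUE(config$fit) && !is.null(model)) {
        fitres <- fit_two_state(curve, model)
        write_model_json(fitres$model, outfile("fitted_model.json"))
        note("fit", if (fitres$converged) "complete" else "not_converged",
             "fitted_model.json")
        model <- fitres$model
      }
      if (!is.null(model)) {
        pk <- peak_force(model, config$f_range)
        jsonlite::write_json(pk, outfile("peak.json"), auto_unbox = TRUE,
                             digits = NA)
        note("peak", "complete", "peak.json")
      }
    }, error = function(e) {
      note("kinetics_group", "failed", error = conditionMessage(e))
    })
  }

  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipeline_config()] arguments; `simulate_model` may be
#' given inline as four `k0`/`x` pairs (`k1`, `k2`, `k12`, `k21`) plus
#' optional `p0`, or as the string `"example_catch"` / `"example_slip"`.
#'
#' @param file YAML path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$simulate_model)) {
    sm <- y$simulate_model
    y$simulate_model <- if (identical(sm, "example_catch")) {
      example_catch_model()
    } else if (identical(sm, "example_slip")) {
      example_slip_model()
    } else {
      two_state_model(
        k1 = bell_rate(sm$k1$k0, sm$k1$x), k2 = bell_rate(sm$k2$k0, sm$k2$x),
        k12 = bell_rate(sm$k12$k0, sm$k12$x),
        k21 = bell_rate(sm$k21$k0, sm$k21$x),
        p0 = if (is.null(sm$p0)) c(1, 0) else unlist(sm$p0))
    }
  }
  if (!is.null(y$criteria)) y$criteria <- do.call(interaction_criteria, y$criteria)
  do.call(pipeline_config, y)
}
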
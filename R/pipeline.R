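#' Read a pipeline configuration (YAML or JSON)
#'
#' Pipeline commands accept a configuration as an R list or a YAML/JSON
#' file. Recognized blocks: `channel` (arguments of [channel_geometry()]),
#' `obstacle` ([obstacle_spec()]), `grid` (`xlim`, `ylim`, `box_size`),
#' `field` (`kind`: `"flow"` or a [canonical_field()] kind, plus `seed`),
#' `sim` (arguments of [sim_config()]), and a top-level `seed` from which
#' per-module seeds default.
#'
#' @param config A list, or a path to a `.yaml`/`.yml`/`.json` file.
#' @return The configuration list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config),
            class = "fiberflow_io_error")
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) {
    abort("config must be a list or a YAML/JSON file path",
          class = "fiberflow_usage_error")
  }
  config
}

config_flow_model <- function(config) {
  geom <- do.call(channel_geometry, config$channel %||% list())
  obst_args <- config$obstacle %||%
    abort("config is missing the obstacle block",
          class = "fiberflow_usage_error")
  obst <- do.call(obstacle_spec,
                  modifyList(obst_args,
                             list(center = as.numeric(obst_args$center %||%
                                                        c(0, 0)))))
  flow_model(geom, obst)
}

config_grid_spec <- function(config) {
  g <- config$grid %||% list()
  do.call(grid_spec, g[intersect(names(g), c("xlim", "ylim", "box_size"))])
}

write_run_manifest <- function(out_dir, command, config, inputs, outputs) {
  manifest <- list(
    command = command,
    package = "fiberflow",
    version = as.character(utils::packageVersion("fiberflow")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    inputs = inputs,
    outputs = outputs
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

write_table_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

#' Pipeline commands
#'
#' Deterministic end-to-end entry points over the package's functions, each
#' writing CSV artifacts plus a `manifest.json` recording the configuration
#' and seeds that produced them. `cmd_flow()` exports the velocity field
#' and tracer trajectories; `cmd_field()` the orientation grid (flow-derived
#' or canonical); `cmd_simulate()` the per-day cell positions;
#' `cmd_analyze()` either an orientation histogram + degree of alignment
#' (TIFF input) or per-day sector fronts (positions CSV input).
#'
#' @param config Configuration list or YAML/JSON path
#'   (see [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of written file paths.
#' @export
cmd_flow <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  model <- config_flow_model(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- config$flow_grid %||% list()
  field <- flow_field_table(model,
                            xlim = as.numeric(g$xlim %||% c(-500, 500)),
                            ylim = as.numeric(g$ylim %||% c(-500, 500)),
                            n = g$n %||% 41)
  tr <- tracer_trajectories(model, n = config$tracers %||% 12,
                            seed = config$seed %||% 1)
  out <- list(
    velocity_field = write_table_csv(field,
                                     file.path(out_dir, "velocity_field.csv")),
    tracers = write_table_csv(tr, file.path(out_dir, "tracers.csv"))
  )
  out$manifest <- write_run_manifest(out_dir, "flow", config, list(), out)
  invisible(out)
}

#' @rdname cmd_flow
#' @export
cmd_field <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fld <- config$field %||% list(kind = "flow")
  kind <- fld$kind %||% "flow"
  spec <- config_grid_spec(config)
  seed <- fld$seed %||% config$seed %||% 1
  grid <- if (identical(kind, "flow")) {
    synthesize_orientation_field(config_flow_model(config), spec, seed = seed)
  } else if (kind %in% c("uniform", "radial", "tangential", "isotropic")) {
    canonical_field(kind, spec,
                    center = as.numeric(fld$center %||% c(0, 0)),
                    angle = fld$angle %||% 90, seed = seed)
  } else {
    abort(paste0("unknown field kind: ", kind),
          class = "fiberflow_usage_error")
  }
  out <- list(grid = write_orientation_grid(
    grid, file.path(out_dir, "orientation_grid.csv")))
  out$manifest <- write_run_manifest(out_dir, "field", config, list(), out)
  invisible(out)
}

#' @rdname cmd_flow
#' @param grid_file Path to an orientation grid written by
#'   [write_orientation_grid()].
#' @export
cmd_simulate <- function(config, grid_file, out_dir) {
  config <- read_pipeline_config(config)
  if (!file.exists(grid_file)) {
    abort(paste0("grid file not found: ", grid_file),
          class = "fiberflow_io_error")
  }
  grid <- read_orientation_grid(grid_file)
  sim_args <- config$sim %||% list()
  if (!is.null(sim_args$center)) sim_args$center <- as.numeric(sim_args$center)
  if (is.null(sim_args$seed) && !is.null(config$seed)) {
    sim_args$seed <- config$seed
  }
  cfg <- do.call(sim_config, sim_args)
  sim <- simulate_invasion(grid, cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(
    positions = write_table_csv(sim$positions,
                                file.path(out_dir, "positions.csv")),
    fronts = write_table_csv(invasion_front_table(sim),
                             file.path(out_dir, "fronts.csv"))
  )
  out$manifest <- write_run_manifest(out_dir, "simulate", config,
                                     list(grid = grid_file), out)
  invisible(out)
}

#' @rdname cmd_flow
#' @param input Path to a grayscale TIFF (image analysis) or a positions
#'   CSV written by `cmd_simulate()` (front analysis).
#' @export
cmd_analyze <- function(input, config, out_dir) {
  config <- read_pipeline_config(config)
  if (!file.exists(input)) {
    abort(paste0("input not found: ", input), class = "fiberflow_io_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (grepl("\\.tiff?$", input, ignore.case = TRUE)) {
    img <- tryCatch(read_image_tiff(input), error = function(e) {
      abort(paste0("cannot read TIFF: ", input),
            class = "fiberflow_io_error", parent = e)
    })
    pre_args <- config$preprocess %||% list()
    pre <- do.call(preprocess_fiber_image, c(list(image = img), pre_args))
    hist <- orientation_histogram(pre)
    doa <- degree_of_alignment(hist)
    out <- list(
      histogram = write_table_csv(hist, file.path(out_dir, "histogram.csv")),
      alignment = write_table_csv(tibble(degree_of_alignment = doa),
                                  file.path(out_dir, "alignment.csv"))
    )
  } else {
    pos <- utils::read.csv(input)
    sim_args <- config$sim %||% list()
    center <- as.numeric(sim_args$center %||% c(0, 0))
    radius <- sim_args$radius %||% 150
    fronts <- as_tibble(pos) |>
      group_by(.data$day) |>
      dplyr::group_modify(~ sector_front_distance(.x, center, radius)) |>
      ungroup()
    out <- list(fronts = write_table_csv(fronts,
                                         file.path(out_dir, "fronts.csv")))
  }
  out$manifest <- write_run_manifest(out_dir, "analyze", config,
                                     list(input = input), out)
  invisible(out)
}
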
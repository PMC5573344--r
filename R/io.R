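#' Load a run configuration from JSON
#'
#' The file may hold any subset of the \code{\link{simulation_config}}
#' and \code{\link{grid_spec}} fields (names mirror those functions'
#' arguments exactly; grid fields are \code{sigma_values},
#' \code{density_values}, \code{detection_values}, \code{n_replicates},
#' \code{estimators}, \code{grid_seed}). Missing fields take the package
#' defaults — an empty file yields the full 588-cell, 5-replicate design.
#' Unknown keys are rejected, and every constraint of the two
#' constructors is enforced.
#'
#' @param path Path to a JSON file.
#' @return List with elements \code{sim} (a \code{simulation_config}) and
#'   \code{grid} (a \code{grid_spec}).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  sim_keys <- names(formals(simulation_config))
  grid_keys <- c("sigma_values", "density_values", "detection_values",
                 "n_replicates", "estimators", "grid_seed")
  unknown <- setdiff(names(raw), c(sim_keys, grid_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  sim <- do.call(simulation_config, raw[intersect(names(raw), sim_keys)])
  g <- raw[intersect(names(raw), grid_keys)]
  names(g)[names(g) == "grid_seed"] <- "seed"
  grid <- do.call(grid_spec, g)
  list(sim = sim, grid = grid)
}

#' Write a run configuration to JSON
#'
#' Inverse of \code{\link{load_config}}; round-trips losslessly.
#'
#' @param config List with \code{sim} and/or \code{grid} elements.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list()
  if (!is.null(config$sim)) out <- c(out, unclass(config$sim))
  if (!is.null(config$grid)) {
    g <- unclass(config$grid)
    names(g)[names(g) == "seed"] <- "grid_seed"
    out <- c(out, g)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a simulated dataset as plain CSV files
#'
#' Writes \code{detectors.csv} (id, x_km, y_km, type),
#' \code{encounters.csv} (individual_id, occasion, detector_id,
#' detector_type, removed_flag; occasions 0-based on the combined
#' camera-then-trap calendar), \code{effort.csv} (occasion,
#' n_traps_active), \code{population.csv} (the ground truth, for
#' evaluation only) and \code{config.json}. Coordinates are km with
#' 6-decimal precision.
#'
#' @param dataset A \code{sim_dataset}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  det <- data.frame(id = dataset$detectors$id,
                    x_km = sprintf("%.6f", dataset$detectors$x),
                    y_km = sprintf("%.6f", dataset$detectors$y),
                    type = dataset$detectors$type)
  utils::write.csv(det, file.path(dir, "detectors.csv"), row.names = FALSE)
  enc <- as.data.frame(combine_histories(dataset$camera_history,
                                         dataset$trap_history))
  utils::write.csv(enc, file.path(dir, "encounters.csv"), row.names = FALSE)
  utils::write.csv(dataset$effort, file.path(dir, "effort.csv"),
                   row.names = FALSE)
  pop <- data.frame(individual_id = dataset$population$individual_id,
                    x_km = sprintf("%.6f", dataset$population$x),
                    y_km = sprintf("%.6f", dataset$population$y))
  utils::write.csv(pop, file.path(dir, "population.csv"), row.names = FALSE)
  write_config(list(sim = dataset$config), file.path(dir, "config.json"))
  invisible(dir)
}

#' Read a dataset written by \code{\link{write_dataset}}
#'
#' @param dir Directory holding the CSV files.
#' @return A \code{sim_dataset} (population truth included when
#'   \code{population.csv} is present).
#' @export
read_dataset <- function(dir) {
  cfg <- load_config(file.path(dir, "config.json"))$sim
  det <- utils::read.csv(file.path(dir, "detectors.csv"),
                         stringsAsFactors = FALSE)
  detectors <- data.frame(id = det$id, x = as.numeric(det$x_km),
                          y = as.numeric(det$y_km), type = det$type,
                          stringsAsFactors = FALSE)
  class(detectors) <- c("detector_array", "data.frame")

  enc <- utils::read.csv(file.path(dir, "encounters.csv"),
                         stringsAsFactors = FALSE)
  n_cam <- cfg$n_camera_occasions
  cam <- enc[enc$detector_type == "camera", ]
  trap <- enc[enc$detector_type == "trap", ]
  trap$occasion <- trap$occasion - n_cam
  camera_history <- new_encounter_history(cam, "camera", n_cam)
  removals <- data.frame(individual_id = trap$individual_id,
                         removal_occasion = trap$occasion)
  trap_history <- new_encounter_history(trap, "trap",
                                        cfg$n_trap_occasions, removals)
  effort <- utils::read.csv(file.path(dir, "effort.csv"))

  population <- NULL
  pp <- file.path(dir, "population.csv")
  if (file.exists(pp)) {
    pop <- utils::read.csv(pp)
    population <- data.frame(individual_id = pop$individual_id,
                             x = as.numeric(pop$x_km),
                             y = as.numeric(pop$y_km))
    class(population) <- c("population", "data.frame")
  }
  out <- list(config = cfg, detectors = detectors, population = population,
              camera_history = camera_history, trap_history = trap_history,
              effort = effort)
  class(out) <- "sim_dataset"
  out
}
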
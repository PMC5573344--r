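#' Simulation configuration
#'
#' Collects every generative parameter of the encounter simulator: the
#' movement/availability model, detector-type detection rates, the
#' multinomial cap on detectors visited per night, the behavioural
#' (trap-happiness) effect, the clustered point process for home-range
#' centroids, and the occasion calendar.
#'
#' @param sigma Scale of movement in km: the standard deviation of the
#'   (truncated) Gaussian availability kernel.
#' @param g0_camera Baseline per-occasion detection probability at a camera
#'   for an animal whose home-range centroid coincides with it.
#' @param trap_g0_ratio Multiplier giving the corral-trap baseline as a
#'   fraction of the camera baseline. The default 0.25 encodes a trap
#'   baseline 75\% lower than the camera baseline at equal distance.
#' @param density True population density, animals per km^2.
#' @param n_camera_occasions Number of daily camera occasions (default 13).
#' @param n_trap_occasions Number of trap nights (default 14).
#' @param camera_trunc_mult,trap_trunc_mult Availability truncation radii in
#'   units of \code{sigma}; animals farther than this from a detector are
#'   never available to it. Trap radii exceed camera radii (traps, with
#'   bait scarcer on the landscape, draw animals from farther).
#' @param visit_probs Probability vector over visiting 1, 2 or 3 distinct
#'   cameras on a night given any detection occurred; must sum to 1.
#' @param behavior_mult Trap-happiness multiplier (>= 1) applied to g0 at a
#'   camera where the individual has previously been detected; the boosted
#'   g0 is capped at 1.
#' @param cluster_mean_size Mean offspring per parent of the Poisson cluster
#'   process generating home-range centroids.
#' @param cluster_radius_km Radius of the disc around each parent within
#'   which offspring centroids are placed.
#' @param landscape_margin_km Margin added around the detector bounding box
#'   to define the landscape; defaults to the trap truncation radius at the
#'   largest routinely simulated sigma (4 x 1.2 km) so that every animal
#'   that could ever be detected lies inside the landscape.
#' @param seed Integer master seed; all phase-level randomness is derived
#'   from it.
#'
#' @return An object of class \code{simulation_config} (a validated list).
#' @export
simulation_config <- function(sigma = 0.6,
                              g0_camera = 0.5,
                              trap_g0_ratio = 0.25,
                              density = 2.5,
                              n_camera_occasions = 13L,
                              n_trap_occasions = 14L,
                              camera_trunc_mult = 3,
                              trap_trunc_mult = 4,
                              visit_probs = c(0.82, 0.15, 0.03),
                              behavior_mult = 2,
                              cluster_mean_size = 4,
                              cluster_radius_km = 0.3,
                              landscape_margin_km = 4.8,
                              seed = 1L) {
  cfg <- list(
    sigma = sigma, g0_camera = g0_camera, trap_g0_ratio = trap_g0_ratio,
    density = density,
    n_camera_occasions = as.integer(n_camera_occasions),
    n_trap_occasions = as.integer(n_trap_occasions),
    camera_trunc_mult = camera_trunc_mult,
    trap_trunc_mult = trap_trunc_mult,
    visit_probs = as.numeric(visit_probs),
    behavior_mult = behavior_mult,
    cluster_mean_size = cluster_mean_size,
    cluster_radius_km = cluster_radius_km,
    landscape_margin_km = landscape_margin_km,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every invariant of \code{\link{simulation_config}}; errors name
#' the offending field.
#'
#' @param cfg A \code{simulation_config}.
#' @return The config, invisibly unchanged, if valid.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(is.numeric(cfg$sigma) && cfg$sigma > 0, "sigma must be > 0")
  chk(cfg$g0_camera > 0 && cfg$g0_camera <= 1,
      "g0_camera must be in (0, 1]")
  chk(cfg$trap_g0_ratio > 0 && cfg$trap_g0_ratio <= 1,
      "trap_g0_ratio must be in (0, 1]")
  chk(cfg$density > 0, "density must be > 0")
  chk(cfg$n_camera_occasions >= 1, "n_camera_occasions must be >= 1")
  chk(cfg$n_trap_occasions >= 1, "n_trap_occasions must be >= 1")
  chk(length(cfg$visit_probs) == 3,
      "visit_probs must have length 3")
  chk(all(cfg$visit_probs >= 0) &&
        abs(sum(cfg$visit_probs) - 1) <= 1e-12,
      "visit_probs must be non-negative and sum to 1 (within 1e-12)")
  chk(cfg$behavior_mult >= 1, "behavior_mult must be >= 1")
  chk(cfg$camera_trunc_mult > 0 &&
        cfg$trap_trunc_mult > cfg$camera_trunc_mult,
      "must have trap_trunc_mult > camera_trunc_mult > 0")
  chk(cfg$cluster_mean_size > 0, "cluster_mean_size must be > 0")
  chk(cfg$cluster_radius_km >= 0, "cluster_radius_km must be >= 0")
  chk(cfg$landscape_margin_km >= 0, "landscape_margin_km must be >= 0")
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed),
      "seed must be a single integer")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  sigma (scale of movement): %.3f km\n", x$sigma))
  cat(sprintf("  g0 camera: %.3f   trap ratio: %.2f\n",
              x$g0_camera, x$trap_g0_ratio))
  cat(sprintf("  density: %.3f animals/km^2\n", x$density))
  cat(sprintf("  occasions: %d camera days + %d trap nights\n",
              x$n_camera_occasions, x$n_trap_occasions))
  cat(sprintf("  truncation: %.1f sigma (camera), %.1f sigma (trap)\n",
              x$camera_trunc_mult, x$trap_trunc_mult))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Derive reproducible sub-seeds from a master seed. Substreams are indexed
# by counter so phases / replicates are independently reproducible.
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master) %% 2147483647L)
  sample.int(2147483646L, n)
}
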
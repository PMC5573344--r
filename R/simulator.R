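#' Truncated Gaussian availability kernel
#'
#' Probability that an animal is available for detection at a detector a
#' distance \code{d} from its home-range centroid within one day. The
#' kernel is the Gaussian density in distance, truncated to zero beyond
#' \code{trunc_radius} and clamped at 1 (for small \code{sigma} the raw
#' density exceeds 1; availability is a probability).
#'
#' @param d Distance(s) in km, non-negative.
#' @param sigma Scale of movement (km).
#' @param trunc_radius Truncation radius (km); availability is 0 beyond it.
#' @return Availability probabilities in [0, 1], same length as \code{d}.
#' @export
availability_prob <- function(d, sigma, trunc_radius) {
  stopifnot(sigma > 0, trunc_radius > 0)
  if (any(d < 0)) stop("distances must be non-negative")
  p <- pmin(1, stats::dnorm(d, 0, sigma))
  p[d > trunc_radius] <- 0
  p
}

#' Per-occasion detection probability
#'
#' Baseline detection given availability times the availability kernel: a
#' scaled truncated Gaussian in the centroid-to-detector distance.
#'
#' @param d Distance(s) in km.
#' @param sigma Scale of movement (km).
#' @param g0_effective Baseline detection probability in [0, 1] (already
#'   including any detector-type ratio or behavioural multiplier).
#' @param trunc_radius Truncation radius (km).
#' @return Detection probabilities in [0, 1].
#' @export
detection_prob <- function(d, sigma, g0_effective, trunc_radius) {
  stopifnot(all(g0_effective >= 0), all(g0_effective <= 1))
  g0_effective * availability_prob(d, sigma, trunc_radius)
}

#' Simulate clustered home-range centroids
#'
#' Centroids follow a partial Poisson cluster process: parent points
#' uniform on the landscape, Poisson-distributed offspring per parent
#' displaced isotropically within \code{cluster_radius_km}, emulating the
#' social grouping of the study species. The realised point count is
#' forced to \code{round(density x landscape area)} by thinning or
#' augmenting offspring, so true density is exact by construction.
#' Centroids are stationary for the whole simulated study.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param detectors Detector array defining the landscape (bounding box
#'   plus \code{landscape_margin_km}).
#' @param seed Seed; defaults to a substream of \code{config$seed}.
#' @return A \code{population}: data frame with \code{individual_id},
#'   \code{x}, \code{y} (km), with the landscape extent as an attribute.
#' @export
simulate_centroids <- function(config, detectors, seed = NULL) {
  validate_config(config)
  ext <- landscape_extent(detectors, config$landscape_margin_km)
  area <- (ext$xmax - ext$xmin) * (ext$ymax - ext$ymin)
  target <- round(config$density * area)
  if (target < 1)
    stop("landscape too small: target population size is 0")
  if (is.null(seed)) seed <- derive_seeds(config$seed, 4)[1]
  set.seed(as.integer(seed))

  n_parents <- max(1L, ceiling(target / config$cluster_mean_size))
  px <- stats::runif(n_parents, ext$xmin, ext$xmax)
  py <- stats::runif(n_parents, ext$ymin, ext$ymax)
  n_off <- stats::rpois(n_parents, config$cluster_mean_size)
  parent_of <- rep.int(seq_len(n_parents), n_off)
  m <- length(parent_of)
  if (m < target)   # augment from randomly chosen parents
    parent_of <- c(parent_of,
                   sample.int(n_parents, target - m, replace = TRUE))
  if (length(parent_of) > target)   # thin
    parent_of <- parent_of[sample.int(length(parent_of), target)]
  m <- length(parent_of)
  ang <- stats::runif(m, 0, 2 * pi)
  rad <- config$cluster_radius_km * sqrt(stats::runif(m))
  x <- pmin(pmax(px[parent_of] + rad * cos(ang), ext$xmin), ext$xmax)
  y <- pmin(pmax(py[parent_of] + rad * sin(ang), ext$ymin), ext$ymax)

  pop <- data.frame(individual_id = seq_len(m), x = x, y = y)
  class(pop) <- c("population", "data.frame")
  attr(pop, "landscape") <- ext
  pop
}

# distance matrix: individuals x detectors (km)
centroid_detector_distances <- function(population, detectors) {
  dx <- outer(population$x, detectors$x, "-")
  dy <- outer(population$y, detectors$y, "-")
  sqrt(dx * dx + dy * dy)
}

new_encounter_history <- function(records, phase, n_occasions, removals = NULL) {
  if (is.null(removals))
    removals <- data.frame(individual_id = integer(), removal_occasion = integer())
  rownames(records) <- NULL
  class(records) <- c("encounter_history", "data.frame")
  attr(records, "phase") <- phase
  attr(records, "n_occasions") <- as.integer(n_occasions)
  attr(records, "removals") <- removals
  records
}

empty_records <- function() {
  data.frame(individual_id = integer(), occasion = integer(),
             detector_id = character(), detector_type = character(),
             removed_flag = logical(), stringsAsFactors = FALSE)
}

#' Simulate the camera-trapping phase
#'
#' For each individual and daily occasion, per-camera detection
#' probabilities combine the availability kernel, the camera baseline g0,
#' and a site-specific trap-happiness boost (g0 multiplied by
#' \code{behavior_mult}, capped at 1, at cameras where that individual was
#' detected on an earlier occasion). If any detection occurs that day, the
#' number of distinct cameras visited is drawn from \code{visit_probs}
#' (capped at 3) and that many cameras are sampled without replacement
#' with weights proportional to the per-camera detection probabilities.
#' Any observation within one day is a single detection (daily scale).
#'
#' @param population A \code{population}.
#' @param detectors Detector array (cameras are used).
#' @param config A \code{\link{simulation_config}}.
#' @param seed Seed; defaults to a substream of \code{config$seed}.
#' @return An \code{encounter_history} with 0-based occasions.
#' @export
simulate_camera_phase <- function(population, detectors, config, seed = NULL) {
  cams <- detectors[detectors$type == "camera", ]
  if (nrow(cams) == 0) stop("no camera detectors")
  if (is.null(seed)) seed <- derive_seeds(config$seed, 4)[2]
  set.seed(as.integer(seed))

  n <- nrow(population)
  K <- nrow(cams)
  dmat <- centroid_detector_distances(population, cams)
  trunc_r <- config$camera_trunc_mult * config$sigma
  avail <- matrix(availability_prob(as.vector(dmat), config$sigma, trunc_r),
                  n, K)
  g0_boost <- min(1, config$g0_camera * config$behavior_mult)
  visited <- matrix(FALSE, n, K)

  out <- vector("list", config$n_camera_occasions)
  for (occ in seq_len(config$n_camera_occasions)) {
    g0 <- ifelse(visited, g0_boost, config$g0_camera)
    p <- g0 * avail
    log_surv <- rowSums(log1p(-p))
    p_any <- -expm1(log_surv)
    hit <- which(stats::runif(n) < p_any)
    if (length(hit)) {
      kk <- sample.int(3L, length(hit), replace = TRUE,
                       prob = config$visit_probs)
      recs <- lapply(seq_along(hit), function(j) {
        i <- hit[j]
        cand <- which(p[i, ] > 0)
        k <- min(kk[j], length(cand))
        sel <- cand[sample.int(length(cand), k, prob = p[i, cand])]
        cbind(i, sel)
      })
      recs <- do.call(rbind, recs)
      visited[recs] <- TRUE
      out[[occ]] <- data.frame(
        individual_id = population$individual_id[recs[, 1]],
        occasion = occ - 1L,
        detector_id = cams$id[recs[, 2]],
        detector_type = "camera",
        removed_flag = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  recs <- do.call(rbind, out)
  if (is.null(recs)) recs <- empty_records()
  new_encounter_history(recs, "camera", config$n_camera_occasions)
}

#' Simulate the corral-trapping (removal) phase
#'
#' Each night, every live individual is captured with probability one
#' minus the product over active traps of the per-trap non-detection
#' probabilities; the trap baseline is \code{g0_camera * trap_g0_ratio}
#' and the truncation radius \code{trap_trunc_mult * sigma}. A captured
#' individual is assigned to a single trap with probability proportional
#' to its per-trap detection probabilities, flagged removed, and excluded
#' from all later nights: an animal is detected at one trap ever.
#'
#' @param population A \code{population}.
#' @param detectors Detector array (traps are used).
#' @param config A \code{\link{simulation_config}}.
#' @param prior_history Camera-phase history preceding trapping on the
#'   calendar (the behavioural effect is camera-specific, so it does not
#'   alter trap detection; accepted for calendar completeness).
#' @param seed Seed; defaults to a substream of \code{config$seed}.
#' @param active Optional logical matrix (traps x nights) of trap
#'   activity; default all traps active every night.
#' @return List with \code{history} (an \code{encounter_history} with
#'   removal occasions) and \code{effort} (data frame \code{occasion},
#'   \code{n_traps_active}).
#' @export
simulate_trap_phase <- function(population, detectors, config,
                                prior_history = NULL, seed = NULL,
                                active = NULL) {
  traps <- detectors[detectors$type == "trap", ]
  if (nrow(traps) == 0) stop("no trap detectors")
  if (is.null(seed)) seed <- derive_seeds(config$seed, 4)[3]
  set.seed(as.integer(seed))

  n <- nrow(population)
  J <- nrow(traps)
  T_n <- config$n_trap_occasions
  if (is.null(active)) active <- matrix(TRUE, J, T_n)
  stopifnot(nrow(active) == J, ncol(active) == T_n)

  dmat <- centroid_detector_distances(population, traps)
  trunc_r <- config$trap_trunc_mult * config$sigma
  g0_trap <- config$g0_camera * config$trap_g0_ratio
  p <- matrix(detection_prob(as.vector(dmat), config$sigma, g0_trap, trunc_r),
              n, J)

  alive <- rep(TRUE, n)
  out <- vector("list", T_n)
  for (t in seq_len(T_n)) {
    act <- which(active[, t])
    ids <- which(alive)
    if (length(act) == 0 || length(ids) == 0) next
    pt <- p[ids, act, drop = FALSE]
    p_cap <- -expm1(rowSums(log1p(-pt)))
    caught <- ids[stats::runif(length(ids)) < p_cap]
    if (length(caught)) {
      trap_ix <- vapply(caught, function(i) {
        w <- p[i, act]
        act[sample.int(length(act), 1L, prob = w)]
      }, integer(1))
      alive[caught] <- FALSE
      out[[t]] <- data.frame(
        individual_id = population$individual_id[caught],
        occasion = t - 1L,
        detector_id = traps$id[trap_ix],
        detector_type = "trap",
        removed_flag = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  recs <- do.call(rbind, out)
  if (is.null(recs)) recs <- empty_records()
  removals <- data.frame(individual_id = recs$individual_id,
                         removal_occasion = recs$occasion)
  history <- new_encounter_history(recs, "trap", T_n, removals)
  effort <- data.frame(occasion = seq_len(T_n) - 1L,
                       n_traps_active = colSums(active))
  list(history = history, effort = effort)
}

#' Simulate a complete camera-then-trap dataset
#'
#' Composes detector layout, clustered centroids, the camera phase and the
#' subsequent removal-trapping phase into one linked dataset. The master
#' seed is split into per-phase substreams so each phase is independently
#' reproducible.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param detectors Optional detector array; the default is the 5 x 4
#'   camera grid at 750 m spacing with 10 embedded traps.
#' @return A \code{sim_dataset}: list with \code{config}, \code{detectors},
#'   \code{population}, \code{camera_history}, \code{trap_history},
#'   \code{effort}.
#' @export
simulate_dataset <- function(config, detectors = NULL) {
  validate_config(config)
  seeds <- derive_seeds(config$seed, 4)
  if (is.null(detectors))
    detectors <- build_detector_grid(5L, 4L, 0.75, 10L, seed = seeds[4])
  population <- simulate_centroids(config, detectors, seed = seeds[1])
  camera_history <- simulate_camera_phase(population, detectors, config,
                                          seed = seeds[2])
  tp <- simulate_trap_phase(population, detectors, config,
                            prior_history = camera_history, seed = seeds[3])
  out <- list(config = config, detectors = detectors,
              population = population,
              camera_history = camera_history,
              trap_history = tp$history,
              effort = tp$effort)
  class(out) <- "sim_dataset"
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated camera + removal-trap dataset\n")
  cat(sprintf("  population: %d individuals (density %.2f /km^2)\n",
              nrow(x$population), x$config$density))
  cat(sprintf("  detectors: %d cameras, %d traps\n",
              sum(x$detectors$type == "camera"),
              sum(x$detectors$type == "trap")))
  cat(sprintf("  camera records: %d (%d individuals)\n",
              nrow(x$camera_history),
              length(unique(x$camera_history$individual_id))))
  cat(sprintf("  removals: %d over %d trap-nights\n",
              nrow(x$trap_history), sum(x$effort$n_traps_active)))
  invisible(x)
}

#' Pool camera and trap histories on one occasion calendar
#'
#' Camera occasions keep their indices; trap occasions are shifted to
#' follow them, giving the combined binary proximity history used by the
#' trap (camera + corral) SECR analysis.
#'
#' @param camera_history,trap_history Phase histories from the simulator.
#' @return An \code{encounter_history} spanning both phases, with the
#'   removal occasions re-expressed on the combined calendar.
#' @export
combine_histories <- function(camera_history, trap_history) {
  off <- attr(camera_history, "n_occasions")
  th <- as.data.frame(trap_history)
  th$occasion <- th$occasion + off
  recs <- rbind(as.data.frame(camera_history), th)
  removals <- attr(trap_history, "removals")
  removals$removal_occasion <- removals$removal_occasion + off
  new_encounter_history(recs, "combined",
                        off + attr(trap_history, "n_occasions"), removals)
}
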
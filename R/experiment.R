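#' Factorial grid specification
#'
#' Defaults are the full simulation design: seven scales of movement,
#' twelve densities and seven detection probabilities (588 combinations),
#' five replicate datasets per combination.
#'
#' @param sigma_values Scales of movement (km).
#' @param density_values True densities (animals/km^2).
#' @param detection_values Camera baseline detection probabilities g0.
#' @param n_replicates Replicate datasets per combination.
#' @param estimators Estimator labels evaluated per replicate; any of
#'   "lpe_mmdm", "lpe_hmmdm", "secr_camera", "secr_trap", "removal_mmdm",
#'   "removal_naive".
#' @param seed Master seed; per-cell, per-replicate seeds are derived from
#'   it so cells are independently reproducible.
#' @return A \code{grid_spec}.
#' @export
grid_spec <- function(sigma_values = c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2),
                      density_values = c(0.25, 0.50, 0.75, 1.25, 2.00, 2.50,
                                         3.75, 5.00, 6.25, 7.50, 10.00, 15.00),
                      detection_values = c(0.1, 0.2, 0.3, 0.5, 0.7, 0.8, 0.9),
                      n_replicates = 5L,
                      estimators = c("lpe_mmdm", "secr_camera",
                                     "secr_trap", "removal_mmdm"),
                      seed = 1L) {
  stopifnot(length(sigma_values) >= 1, length(density_values) >= 1,
            length(detection_values) >= 1, n_replicates >= 1)
  known <- c("lpe_mmdm", "lpe_hmmdm", "secr_camera", "secr_trap",
             "removal_mmdm", "removal_naive")
  bad <- setdiff(estimators, known)
  if (length(bad)) stop("unknown estimator(s): ", paste(bad, collapse = ", "))
  out <- list(sigma_values = sigma_values, density_values = density_values,
              detection_values = detection_values,
              n_replicates = as.integer(n_replicates),
              estimators = estimators, seed = as.integer(seed))
  class(out) <- "grid_spec"
  out
}

#' Enumerate the parameter grid
#'
#' @param spec A \code{\link{grid_spec}}.
#' @return Data frame of all (sigma, density, g0) combinations in
#'   deterministic order (sigma varying fastest).
#' @export
enumerate_grid <- function(spec) {
  expand.grid(sigma = spec$sigma_values, density = spec$density_values,
              g0 = spec$detection_values, KEEP.OUT.ATTRS = FALSE)
}

#' Scaled bias of a density estimate
#'
#' (estimated density - true density) / true density.
#'
#' @param d_hat Estimated density.
#' @param d_true True density (> 0).
#' @return Unitless scaled bias.
#' @export
scaled_bias <- function(d_hat, d_true) {
  if (any(d_true <= 0)) stop("d_true must be > 0")
  (d_hat - d_true) / d_true
}

#' Coefficient of variation of a density estimate
#'
#' SE divided by the estimate; missing (NA) when the estimate is not
#' positive. For display the CV is conventionally capped at 2.0; the raw
#' value is what this function returns.
#'
#' @param d_hat Density estimate.
#' @param se Its standard error (>= 0).
#' @return Raw CV (se / d_hat), NA where d_hat <= 0.
#' @export
cv <- function(d_hat, se) {
  out <- ifelse(d_hat > 0, se / d_hat, NA_real_)
  out[se < 0] <- NA_real_
  out
}

# one replicate of one grid cell: simulate, run estimators, return rows
run_cell_replicate <- function(sigma, density, g0, replicate, seed,
                               estimators, sim_defaults, detectors,
                               mcmc_iter, mcmc_burn) {
  cfg <- sim_defaults
  cfg$sigma <- sigma; cfg$density <- density; cfg$g0_camera <- g0
  cfg$seed <- as.integer(seed)
  validate_config(cfg)
  ds <- simulate_dataset(cfg, detectors = detectors)
  combined <- combine_histories(ds$camera_history, ds$trap_history)

  w_mmdm <- tryCatch(mmdm(combined, ds$detectors), error = function(e) NA_real_)
  hull_all <- ds$detectors
  hull_trap <- ds$detectors[ds$detectors$type == "trap", ]

  row0 <- function(est) data.frame(
    sigma = sigma, density = density, g0 = g0, replicate = replicate,
    estimator = est, d_hat = NA_real_, se = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, scaled_bias = NA_real_,
    cv = NA_real_, status = "failed", reason = "",
    stringsAsFactors = FALSE)
  fill <- function(row, d) {
    row$d_hat <- d$d_hat; row$se <- sqrt(d$variance)
    row$ci_low <- d$ci_low; row$ci_high <- d$ci_high
    row$scaled_bias <- scaled_bias(d$d_hat, density)
    row$cv <- cv(d$d_hat, sqrt(d$variance))
    row$status <- "ok"; row
  }

  rows <- vector("list", length(estimators))
  names(rows) <- estimators

  # abundance-based estimators need a buffer width
  for (est in intersect(estimators,
                        c("lpe_mmdm", "lpe_hmmdm", "removal_mmdm",
                          "removal_naive"))) {
    row <- row0(est)
    w <- switch(est,
                lpe_mmdm = w_mmdm, removal_mmdm = w_mmdm,
                lpe_hmmdm = w_mmdm / 2,
                removal_naive = buffer_width("naive"))
    if (!is.finite(w)) {
      row$reason <- "MMDM undefined"
      rows[[est]] <- row
      next
    }
    if (startsWith(est, "lpe")) {
      cnt <- build_lpe_counts(ds$camera_history, ds$trap_history)
      A <- effective_area(hull_all, w)
      rows[[est]] <- fill(row, to_density(chapman_estimate(cnt), A, est))
    } else {
      rd <- removal_data_from_dataset(ds)
      fit <- fit_removal(rd, n_iter = mcmc_iter, burn_in = mcmc_burn,
                         seed = (seed + 7L) %% 2147483647L)
      if (!fit$estimable) {
        row$reason <- fit$reason
        rows[[est]] <- row
      } else {
        A <- effective_area(hull_trap, w)
        rows[[est]] <- fill(row, to_density(fit$estimate, A, est))
      }
    }
  }

  for (est in intersect(estimators, c("secr_camera", "secr_trap"))) {
    row <- row0(est)
    if (est == "secr_camera") {
      hist <- ds$camera_history
      dets <- ds$detectors[ds$detectors$type == "camera", ]
      usage <- NULL
    } else {
      hist <- combined
      dets <- ds$detectors
      usage <- make_usage(dets, cfg$n_camera_occasions, cfg$n_trap_occasions)
    }
    if (nrow(hist) == 0) {
      row$reason <- "no detections"
      rows[[est]] <- row
      next
    }
    s0 <- start_sigma(hist, dets)
    mask <- build_mask(dets, buffer_km = max(4 * s0, 1.5),
                       spacing_km = min(max(s0 / 2, 0.1), 0.5))
    fit <- fit_secr(hist, dets, mask, usage = usage)
    if (!fit$converged) {
      row$reason <- fit$reason
      rows[[est]] <- row
    } else {
      d <- list(d_hat = fit$D, variance = fit$se_D^2,
                ci_low = fit$ci_low, ci_high = fit$ci_high)
      rows[[est]] <- fill(row, d)
    }
  }
  do.call(rbind, rows[estimators])
}

#' Run the factorial simulation-estimation grid
#'
#' For every (sigma, density, g0) combination and replicate: simulate a
#' dataset, run each requested estimator, and record the density estimate,
#' SE, scaled bias and CV, or a failure record (failed fits are kept as
#' rows with status "failed", never dropped). Fully reproducible from the
#' master seed; per-cell seeds are pre-drawn so results are identical
#' regardless of execution order.
#'
#' @param spec A \code{\link{grid_spec}}.
#' @param sim_defaults A \code{\link{simulation_config}} supplying all
#'   non-grid simulation parameters.
#' @param mcmc_iter,mcmc_burn Removal-model chain length per fit (grid
#'   economy default 20000/5000; single fits use longer chains).
#' @param progress Print per-cell progress to stderr.
#' @return An evaluation table (long data frame): one row per cell x
#'   replicate x estimator.
#' @export
run_grid <- function(spec, sim_defaults = simulation_config(),
                     mcmc_iter = 20000L, mcmc_burn = 5000L,
                     progress = FALSE) {
  grid <- enumerate_grid(spec)
  n_cells <- nrow(grid)
  seeds <- matrix(derive_seeds(spec$seed, n_cells * spec$n_replicates),
                  n_cells, spec$n_replicates)
  detectors <- build_detector_grid(5L, 4L, 0.75, 10L,
                                   seed = derive_seeds(spec$seed + 1L, 1))

  out <- vector("list", n_cells * spec$n_replicates)
  for (ci in seq_len(n_cells)) {
    if (progress)
      message(sprintf("cell %d/%d: sigma=%.2f D=%.2f g0=%.2f",
                      ci, n_cells, grid$sigma[ci], grid$density[ci],
                      grid$g0[ci]))
    for (r in seq_len(spec$n_replicates)) {
      out[[(ci - 1) * spec$n_replicates + r]] <- run_cell_replicate(
        grid$sigma[ci], grid$density[ci], grid$g0[ci], r, seeds[ci, r],
        spec$estimators, sim_defaults, detectors, mcmc_iter, mcmc_burn)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate an evaluation table per grid cell
#'
#' Mean and median scaled bias and mean CV over successful replicates per
#' (sigma, density, g0, estimator) cell, with explicit success/failure
#' counts (successes + failures = replicates for every cell).
#'
#' @param results A \code{\link{run_grid}} evaluation table.
#' @param cv_cap Display cap applied to the aggregated CV (the raw values
#'   in \code{results} are untouched); default 2.
#' @return Data frame of per-cell aggregates.
#' @export
summarize_grid <- function(results, cv_cap = 2) {
  key <- interaction(results$sigma, results$density, results$g0,
                     results$estimator, drop = TRUE)
  agg <- lapply(split(results, key), function(d) {
    ok <- d[d$status == "ok", ]
    data.frame(
      sigma = d$sigma[1], density = d$density[1], g0 = d$g0[1],
      estimator = d$estimator[1],
      n_ok = nrow(ok), n_failed = nrow(d) - nrow(ok),
      mean_scaled_bias = if (nrow(ok)) mean(ok$scaled_bias) else NA_real_,
      median_scaled_bias = if (nrow(ok)) stats::median(ok$scaled_bias) else NA_real_,
      mean_cv = if (nrow(ok)) mean(ok$cv, na.rm = TRUE) else NA_real_,
      mean_cv_display = if (nrow(ok))
        min(mean(ok$cv, na.rm = TRUE), cv_cap) else NA_real_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  rownames(res) <- NULL
  res[order(res$estimator, res$sigma, res$density, res$g0), ]
}
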
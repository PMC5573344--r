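#' Two-sample counts for the Lincoln-Petersen estimator
#'
#' The marking sample is the set of individuals identified at cameras; the
#' recapture sample is the set of individuals caught at corral traps
#' (identity is exact in simulation, emulating perfect photo-ID).
#'
#' @param camera_history Camera-phase \code{encounter_history}.
#' @param trap_history Trap-phase \code{encounter_history}.
#' @return List of class \code{lpe_counts}: \code{n1} marked, \code{n2}
#'   recaptured-sample size, \code{m} in both.
#' @export
build_lpe_counts <- function(camera_history, trap_history) {
  s1 <- unique(camera_history$individual_id)
  s2 <- unique(trap_history$individual_id)
  out <- list(n1 = length(s1), n2 = length(s2),
              m = length(intersect(s1, s2)))
  class(out) <- "lpe_counts"
  out
}

#' Chapman-corrected Lincoln-Petersen abundance estimate
#'
#' N-hat = (n1+1)(n2+1)/(m+1) - 1 with the classical Chapman variance
#' (n1+1)(n2+1)(n1-m)(n2-m) / ((m+1)^2 (m+2)). Finite for all inputs
#' including m = 0.
#'
#' @param counts An \code{lpe_counts} (or list with n1, n2, m).
#' @param alpha CI level is 1 - alpha (default 95\%).
#' @param ci One of \code{"normal"} (normal approximation on N-hat) or
#'   \code{"lognormal"} (log-normal interval on N-hat). The lower limit is
#'   floored at the number of distinct individuals actually observed.
#' @return An \code{abundance_estimate}: list with \code{n_hat},
#'   \code{variance}, \code{ci_low}, \code{ci_high}, \code{method}.
#' @export
chapman_estimate <- function(counts, alpha = 0.05,
                             ci = c("normal", "lognormal")) {
  ci <- match.arg(ci)
  n1 <- counts$n1; n2 <- counts$n2; m <- counts$m
  stopifnot(n1 >= 0, n2 >= 0, m >= 0, m <= min(n1, n2))
  n_hat <- (n1 + 1) * (n2 + 1) / (m + 1) - 1
  v <- (n1 + 1) * (n2 + 1) * (n1 - m) * (n2 - m) / ((m + 1)^2 * (m + 2))
  z <- stats::qnorm(1 - alpha / 2)
  n_obs <- n1 + n2 - m
  if (ci == "normal" || n_hat <= 0 || v == 0) {
    lo <- n_hat - z * sqrt(v)
    hi <- n_hat + z * sqrt(v)
  } else {
    # log-normal interval on the estimate
    cv2 <- v / n_hat^2
    C <- exp(z * sqrt(log(1 + cv2)))
    lo <- n_hat / C
    hi <- n_hat * C
  }
  abundance_estimate(n_hat, v, max(lo, n_obs), max(hi, n_obs),
                     method = "chapman")
}

#' Construct an abundance estimate object
#'
#' @param n_hat Point estimate (animals).
#' @param variance Estimator variance (animals^2).
#' @param ci_low,ci_high Confidence limits.
#' @param method Method label.
#' @return An \code{abundance_estimate}.
#' @export
abundance_estimate <- function(n_hat, variance, ci_low, ci_high, method) {
  stopifnot(variance >= 0, ci_low <= ci_high)
  out <- list(n_hat = n_hat, variance = variance,
              ci_low = ci_low, ci_high = ci_high, method = method)
  class(out) <- "abundance_estimate"
  out
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("Abundance (%s): %.2f  SE %.2f  CI [%.2f, %.2f]\n",
              x$method, x$n_hat, sqrt(x$variance), x$ci_low, x$ci_high))
  invisible(x)
}
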
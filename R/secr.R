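#' Build a habitat mask
#'
#' Rectangular lattice of candidate activity-centre points covering the
#' detector bounding box plus a buffer, used to integrate the SECR
#' likelihood over space. Buffer widths of at least ~4 sigma are
#' recommended so that animals with non-negligible detection probability
#' are inside the mask.
#'
#' @param detectors Detector array.
#' @param buffer_km Buffer width around the detector bounding box (km).
#' @param spacing_km Lattice spacing (km); the cell area is spacing^2.
#' @return A \code{habitat_mask}: data frame of x, y with attributes
#'   \code{spacing}, \code{cell_area} and \code{area}.
#' @export
build_mask <- function(detectors, buffer_km, spacing_km) {
  stopifnot(buffer_km >= 0, spacing_km > 0)
  xs <- seq(min(detectors$x) - buffer_km, max(detectors$x) + buffer_km,
            by = spacing_km)
  ys <- seq(min(detectors$y) - buffer_km, max(detectors$y) + buffer_km,
            by = spacing_km)
  if (length(xs) == 0 || length(ys) == 0) stop("empty mask")
  m <- expand.grid(x = xs, y = ys)
  class(m) <- c("habitat_mask", "data.frame")
  attr(m, "spacing") <- spacing_km
  attr(m, "cell_area") <- spacing_km^2
  attr(m, "area") <- nrow(m) * spacing_km^2
  m
}

#' SECR model specification
#'
#' Flags select terms on the detection submodel: a site-specific
#' behavioural ("bk") effect on g0 (g0 changes at a detector after the
#' individual's first detection there), a detector-type (camera vs trap)
#' effect on g0, and optionally a type-specific sigma.
#'
#' @param behavior Site-specific behavioural response on g0.
#' @param type_effect Detector-type effect on g0.
#' @param sigma_by_type Type-specific scale parameter.
#' @return A \code{secr_model_spec}.
#' @export
secr_model_spec <- function(behavior = FALSE, type_effect = FALSE,
                            sigma_by_type = FALSE) {
  out <- list(behavior = behavior, type_effect = type_effect,
              sigma_by_type = sigma_by_type,
              K = 3L + behavior + type_effect + sigma_by_type)
  class(out) <- "secr_model_spec"
  out
}

model_spec_label <- function(spec) {
  terms <- c("null"[!(spec$behavior || spec$type_effect || spec$sigma_by_type)],
             "bk"[spec$behavior], "type"[spec$type_effect],
             "sigma~type"[spec$sigma_by_type])
  paste(terms, collapse = "+")
}

#' Detector usage matrix for the camera-then-trap calendar
#'
#' @param detectors Detector array.
#' @param n_camera_occasions,n_trap_occasions Phase lengths; cameras are
#'   active on the first block of occasions, traps on the second.
#' @return Logical matrix detectors x occasions.
#' @export
make_usage <- function(detectors, n_camera_occasions, n_trap_occasions) {
  K <- nrow(detectors)
  T_n <- n_camera_occasions + n_trap_occasions
  u <- matrix(FALSE, K, T_n)
  u[detectors$type == "camera", seq_len(n_camera_occasions)] <- TRUE
  u[detectors$type == "trap",
    n_camera_occasions + seq_len(n_trap_occasions)] <- TRUE
  u
}

# Sufficient statistics for the binary proximity likelihood with optional
# bk split: per individual x detector, detections and Bernoulli trials in
# the pre- and post-first-detection states, honouring removal truncation
# (occasions after an individual's removal contribute no terms).
prepare_secr_data <- function(history, detectors, usage = NULL) {
  ids <- sort(unique(history$individual_id))
  n <- length(ids)
  if (n == 0) stop("no detections")
  K <- nrow(detectors)
  T_n <- attr(history, "n_occasions")
  if (is.null(usage)) usage <- matrix(TRUE, K, T_n)
  stopifnot(ncol(usage) == T_n, nrow(usage) == K)

  i_ix <- match(history$individual_id, ids)
  k_ix <- match(history$detector_id, detectors$id)
  if (anyNA(k_ix)) stop("history references unknown detector ids")

  Y <- matrix(0, n, K)
  for (r in seq_along(i_ix))
    Y[i_ix[r], k_ix[r]] <- Y[i_ix[r], k_ix[r]] + 1

  # first detection occasion (0-based) per (i, k); Inf when never
  Fmat <- matrix(Inf, n, K)
  for (r in seq_along(i_ix)) {
    occ <- history$occasion[r]
    if (occ < Fmat[i_ix[r], k_ix[r]]) Fmat[i_ix[r], k_ix[r]] <- occ
  }

  removals <- attr(history, "removals")
  r_i <- rep(T_n - 1, n)   # last occasion each individual is at risk
  if (!is.null(removals) && nrow(removals)) {
    mi <- match(removals$individual_id, ids)
    r_i[mi[!is.na(mi)]] <- removals$removal_occasion[!is.na(mi)]
  }

  # cumulative active-occasion counts per detector
  T_pre <- matrix(0, n, K)
  T_tot_i <- matrix(0, n, K)
  for (k in seq_len(K)) {
    cum <- cumsum(usage[k, ])            # active occasions among 0..t-1
    cnt <- function(last0) ifelse(last0 < 0, 0, cum[pmin(last0, T_n - 1) + 1])
    T_tot_i[, k] <- cnt(r_i)
    T_pre[, k] <- cnt(pmin(Fmat[, k], r_i))
  }
  Y_pre <- (Y > 0) * 1
  Y_post <- Y - Y_pre
  T_post <- T_tot_i - T_pre
  if (any(Y_post > T_post) || any(Y_pre > T_pre))
    stop("history inconsistent with usage/removals")

  list(ids = ids, n = n, K = K, T_n = T_n, usage = usage,
       Y_pre = Y_pre, Y_post = Y_post, T_pre = T_pre, T_post = T_post,
       T_k_total = rowSums(usage),
       is_trap = detectors$type == "trap",
       n_spatial_recaptures = sum(rowSums(Y > 0) >= 2))
}

# link-scale parameter vector layout for a model spec
secr_par_names <- function(spec) {
  c("logD", "logit_g0", if (spec$behavior) "beta_bk",
    if (spec$type_effect) "beta_type", "log_sigma",
    if (spec$sigma_by_type) "alpha_sigma_type")
}

secr_unpack <- function(theta, spec) {
  nm <- secr_par_names(spec)
  names(theta) <- nm
  list(D = exp(theta[["logD"]]),
       b0 = theta[["logit_g0"]],
       b_bk = if (spec$behavior) theta[["beta_bk"]] else 0,
       b_type = if (spec$type_effect) theta[["beta_type"]] else 0,
       ls = theta[["log_sigma"]],
       a_type = if (spec$sigma_by_type) theta[["alpha_sigma_type"]] else 0)
}

invlogit <- function(x) 1 / (1 + exp(-x))

# core negative log-likelihood on the link scale
secr_nll <- function(theta, dat, spec, dist_km, cell_area) {
  p <- secr_unpack(theta, spec)
  if (!all(is.finite(unlist(p)))) return(1e10)
  sig <- exp(p$ls + p$a_type * dat$is_trap)         # per detector
  log_gauss <- -dist_km^2 / (2 * sig^2)             # K x M
  gauss <- exp(log_gauss)
  g0_pre <- invlogit(p$b0 + p$b_type * dat$is_trap)
  g0_post <- invlogit(p$b0 + p$b_bk + p$b_type * dat$is_trap)
  P_pre <- g0_pre * gauss
  log_P_pre <- log(g0_pre) + log_gauss              # finite even on underflow
  log_Q_pre <- log1p(-P_pre)

  if (spec$behavior) {
    P_post <- g0_post * gauss
    L <- dat$Y_pre %*% log_P_pre + (dat$T_pre - dat$Y_pre) %*% log_Q_pre +
      dat$Y_post %*% (log(g0_post) + log_gauss) +
      (dat$T_post - dat$Y_post) %*% log1p(-P_post)
  } else {
    Y <- dat$Y_pre + dat$Y_post
    Tt <- dat$T_pre + dat$T_post
    L <- Y %*% log_P_pre + (Tt - Y) %*% log_Q_pre
  }
  # log sum over mask per individual (log-sum-exp), times cell area
  mx <- apply(L, 1, max)
  a_i <- mx + log(rowSums(exp(L - mx))) + log(cell_area)

  log_q <- colSums(dat$T_k_total * log_Q_pre)       # never-detected prob
  Lambda <- p$D * cell_area * sum(-expm1(log_q))
  ll <- -Lambda + sum(log(p$D) + a_i) - lfactorial(dat$n)
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' SECR log-likelihood
#'
#' Full likelihood for binary proximity detectors: activity centres follow
#' a homogeneous Poisson process with density D, per-occasion detection at
#' a detector distance d from the centre is g0 exp(-d^2 / (2 sigma^2))
#' (half-normal), the number of detected individuals is Poisson, and each
#' observed history is integrated over the habitat mask. Occasions after
#' an individual's removal contribute no terms for that individual.
#'
#' @param history An \code{encounter_history}.
#' @param detectors Detector array.
#' @param mask A \code{\link{build_mask}} result.
#' @param params Named list with \code{D} (animals/km^2), \code{g0},
#'   \code{sigma} (km), and optionally \code{beta_bk}, \code{beta_type}
#'   (logit-scale offsets) and \code{alpha_sigma_type} (log-scale offset)
#'   for non-null model terms.
#' @param model_spec A \code{\link{secr_model_spec}} (default null model).
#' @param usage Optional detector x occasion activity matrix.
#' @return Log-likelihood value.
#' @export
secr_loglik <- function(history, detectors, mask, params,
                        model_spec = secr_model_spec(), usage = NULL) {
  dat <- prepare_secr_data(history, detectors, usage)
  theta <- c(log(params$D), stats::qlogis(params$g0),
             if (model_spec$behavior) params$beta_bk %||% 0,
             if (model_spec$type_effect) params$beta_type %||% 0,
             log(params$sigma),
             if (model_spec$sigma_by_type) params$alpha_sigma_type %||% 0)
  dist_km <- detector_mask_distances(detectors, mask)
  -secr_nll(theta, dat, model_spec, dist_km, attr(mask, "cell_area"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

detector_mask_distances <- function(detectors, mask) {
  dx <- outer(detectors$x, mask$x, "-")
  dy <- outer(detectors$y, mask$y, "-")
  sqrt(dx * dx + dy * dy)
}

#' Fit a SECR model by maximum likelihood
#'
#' Maximises the SECR likelihood over (log D, logit g0, log sigma) and any
#' model-spec terms by quasi-Newton search with multiple jittered starts.
#' Standard errors come from the numerical Hessian on the link scales;
#' the D confidence interval is Wald on the log scale. Structural failure
#' (no spatial recaptures, optimiser failure, or a non-positive-definite
#' Hessian) is reported through the \code{converged} flag rather than an
#' error, so that simulation grids keep running over sparse cells.
#'
#' @param history An \code{encounter_history} with at least one detected
#'   individual.
#' @param detectors Detector array.
#' @param mask Habitat mask.
#' @param model_spec A \code{\link{secr_model_spec}}.
#' @param start Optional link-scale start vector.
#' @param usage Optional detector x occasion activity matrix.
#' @param n_starts Number of jittered starts before declaring failure.
#' @param alpha 1 - confidence level.
#' @return A \code{secr_fit}: density and detection estimates with SEs,
#'   log-likelihood, parameter count K, AICc, and a convergence flag.
#' @export
fit_secr <- function(history, detectors, mask,
                     model_spec = secr_model_spec(), start = NULL,
                     usage = NULL, n_starts = 3L, alpha = 0.05) {
  dat <- prepare_secr_data(history, detectors, usage)
  dist_km <- detector_mask_distances(detectors, mask)
  cell_area <- attr(mask, "cell_area")

  failed <- function(reason) {
    out <- list(converged = FALSE, reason = reason, n = dat$n,
                K = model_spec$K, model = model_spec_label(model_spec),
                D = NA_real_, se_D = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, g0 = NA_real_, sigma = NA_real_,
                loglik = NA_real_, aicc = NA_real_, estimates = NULL)
    class(out) <- "secr_fit"
    out
  }
  if (dat$n_spatial_recaptures == 0)
    return(failed("no spatial recaptures: sigma not identifiable"))

  if (is.null(start)) {
    sig0 <- start_sigma(history, detectors)
    g0_0 <- 0.15
    D0 <- dat$n / attr(mask, "area")
    start <- c(log(D0), stats::qlogis(g0_0),
               if (model_spec$behavior) 0,
               if (model_spec$type_effect) 0,
               log(sig0),
               if (model_spec$sigma_by_type) 0)
  }
  ls_pos <- match("log_sigma", secr_par_names(model_spec))
  make_jit <- function(a) {
    j <- numeric(model_spec$K)
    j[1] <- a; j[2] <- a; j[ls_pos] <- -0.8 * a
    j
  }
  jit <- list(make_jit(0), make_jit(0.5), make_jit(-0.5))
  best <- NULL
  for (s in seq_len(min(n_starts, 3L))) {
    st <- start + jit[[s]]
    fit <- tryCatch(
      stats::optim(st, secr_nll, dat = dat, spec = model_spec,
                   dist_km = dist_km, cell_area = cell_area,
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$convergence == 0 && fit$value < 1e9 &&
        (is.null(best) || fit$value < best$value - 1e-8)) best <- fit
    if (!is.null(best) && s == 1) break   # first start converged; done
  }
  if (is.null(best)) return(failed("optimizer failed"))

  H <- tryCatch(stats::optimHess(best$par, secr_nll, dat = dat,
                                 spec = model_spec, dist_km = dist_km,
                                 cell_area = cell_area),
                error = function(e) NULL)
  vcov <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vcov) || any(!is.finite(diag(vcov))) || any(diag(vcov) <= 0))
    return(failed("Hessian not positive definite"))

  theta <- best$par
  se <- sqrt(diag(vcov))
  names(theta) <- names(se) <- secr_par_names(model_spec)
  p <- secr_unpack(theta, model_spec)
  z <- stats::qnorm(1 - alpha / 2)
  D <- p$D
  se_logD <- se[["logD"]]
  ll <- -best$value
  K <- model_spec$K
  aicc <- if (dat$n > K + 1)
    -2 * ll + 2 * K + 2 * K * (K + 1) / (dat$n - K - 1) else NA_real_

  est <- data.frame(
    parameter = secr_par_names(model_spec),
    link_estimate = unname(theta),
    link_se = unname(se))
  out <- list(converged = TRUE, reason = "ok", n = dat$n, K = K,
              model = model_spec_label(model_spec),
              D = D, se_D = D * se_logD,
              ci_low = exp(log(D) - z * se_logD),
              ci_high = exp(log(D) + z * se_logD),
              g0 = invlogit(p$b0),
              g0_trap = invlogit(p$b0 + p$b_type),
              sigma = exp(p$ls),
              sigma_trap = exp(p$ls + p$a_type),
              loglik = ll, aicc = aicc, estimates = est,
              n_spatial_recaptures = dat$n_spatial_recaptures)
  class(out) <- "secr_fit"
  out
}

# half the mean maximum recapture distance, bounded away from degeneracy
start_sigma <- function(history, detectors) {
  s <- tryCatch(mmdm(history, detectors) / 2, error = function(e) NA_real_)
  if (!is.finite(s) || s <= 0) s <- 0.5
  max(s, 0.05)
}

#' @export
print.secr_fit <- function(x, ...) {
  cat(sprintf("SECR fit [%s]: %s\n", x$model,
              if (x$converged) "converged" else paste("FAILED -", x$reason)))
  if (x$converged) {
    cat(sprintf("  D = %.3f /km^2 (SE %.3f, CI %.3f-%.3f)\n",
                x$D, x$se_D, x$ci_low, x$ci_high))
    cat(sprintf("  g0 = %.3f  sigma = %.3f km  logLik = %.2f  AICc = %.2f\n",
                x$g0, x$sigma, x$loglik, x$aicc))
  }
  invisible(x)
}

#' AICc comparison table for SECR fits
#'
#' AICc = -2 lnL + 2K + 2K(K+1)/(n-K-1) with n the number of detected
#' individuals; Akaike weights are normalised over the supplied converged
#' fits. When several models fall within Delta-AICc < 2, the reported
#' density is their weight-averaged estimate.
#'
#' @param fits List of \code{secr_fit} objects.
#' @param n_individuals Sample size n used in the correction term.
#' @return Data frame ranked by AICc with columns model, K, loglik, aicc,
#'   delta_aicc, weight; the selected (possibly model-averaged) density is
#'   attached as attributes \code{D_best} and \code{averaged}.
#' @export
aicc_table <- function(fits, n_individuals) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) stop("no converged fit")
  Kv <- vapply(conv, `[[`, numeric(1), "K")
  if (any(n_individuals <= Kv + 1))
    stop("sample size n must exceed K + 1 for AICc")
  ll <- vapply(conv, `[[`, numeric(1), "loglik")
  aicc <- -2 * ll + 2 * Kv + 2 * Kv * (Kv + 1) / (n_individuals - Kv - 1)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  ord <- order(aicc)
  tab <- data.frame(
    model = vapply(conv, `[[`, character(1), "model"),
    K = Kv, loglik = ll, aicc = aicc, delta_aicc = delta,
    weight = w)[ord, ]
  rownames(tab) <- NULL
  Dv <- vapply(conv, `[[`, numeric(1), "D")[ord]
  in_set <- tab$delta_aicc < 2
  D_best <- if (sum(in_set) > 1)
    sum(Dv[in_set] * tab$weight[in_set]) / sum(tab$weight[in_set])
  else Dv[1]
  attr(tab, "D_best") <- D_best
  attr(tab, "averaged") <- sum(in_set) > 1
  tab
}

#' Simulate directly from the half-normal SECR observation model
#'
#' Activity centres are a homogeneous Poisson process over the detector
#' bounding box plus a buffer; detections are independent Bernoulli per
#' individual, detector and occasion with probability
#' g0 exp(-d^2/(2 sigma^2)). This is the fitted model's own generative
#' process (no availability clamp, visit cap or behavioural effect), used
#' for parameter-recovery validation.
#'
#' @param D Density (animals/km^2).
#' @param g0,sigma Detection parameters.
#' @param detectors Detector array (all rows are used as proximity
#'   detectors).
#' @param n_occasions Number of occasions.
#' @param buffer_km Buffer defining the simulated region.
#' @param seed Integer seed.
#' @return An \code{encounter_history} (only detected individuals appear).
#' @export
simulate_secr_history <- function(D, g0, sigma, detectors, n_occasions,
                                  buffer_km, seed) {
  set.seed(as.integer(seed))
  ext <- landscape_extent(detectors, buffer_km)
  A <- (ext$xmax - ext$xmin) * (ext$ymax - ext$ymin)
  N <- stats::rpois(1, D * A)
  x <- stats::runif(N, ext$xmin, ext$xmax)
  y <- stats::runif(N, ext$ymin, ext$ymax)
  dx <- outer(x, detectors$x, "-")
  dy <- outer(y, detectors$y, "-")
  p <- g0 * exp(-(dx^2 + dy^2) / (2 * sigma^2))
  recs <- vector("list", n_occasions)
  for (t in seq_len(n_occasions)) {
    hit <- which(matrix(stats::runif(length(p)), nrow(p)) < p,
                 arr.ind = TRUE)
    if (nrow(hit))
      recs[[t]] <- data.frame(individual_id = hit[, 1], occasion = t - 1L,
                              detector_id = detectors$id[hit[, 2]],
                              detector_type = detectors$type[hit[, 2]],
                              removed_flag = FALSE,
                              stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs)) recs <- empty_records()
  new_encounter_history(recs, "camera", n_occasions)
}
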
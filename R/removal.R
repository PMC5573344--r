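#' Removal (depletion) data
#'
#' Nightly removal counts with trapping effort: \code{catches[t]} animals
#' removed on night t with \code{effort[t]} active trap-nights.
#'
#' @param catches Non-negative integer vector of nightly removals.
#' @param effort Non-negative vector of active trap-nights per night.
#' @return A \code{removal_data} list.
#' @export
removal_data <- function(catches, effort) {
  stopifnot(length(catches) == length(effort),
            all(catches >= 0), all(catches == round(catches)),
            all(effort >= 0))
  out <- list(catches = as.integer(catches), effort = as.numeric(effort),
              n_nights = length(catches))
  class(out) <- "removal_data"
  out
}

#' Removal model log-likelihood
#'
#' Sequential binomial depletion: with N_t = N0 - sum of earlier catches,
#' y_t ~ Binomial(N_t, p_t) where p_t = 1 - (1 - theta)^{E_t} links the
#' per-trap-night capture rate theta to nightly effort E_t (alternative
#' link: p_t = 1 - exp(-theta E_t)). Closure is assumed: all change in N
#' is due to removals.
#'
#' @param data A \code{\link{removal_data}}.
#' @param N0 Initial abundance; -Inf is returned when N0 is below the
#'   cumulative catch.
#' @param theta Per-trap-night capture rate in (0, 1).
#' @param link Effort link, "geometric" (default) or "exponential".
#' @return Log-likelihood.
#' @export
removal_loglik <- function(data, N0, theta, link = c("geometric", "exponential")) {
  link <- match.arg(link)
  y <- data$catches
  if (N0 < sum(y) || N0 != round(N0)) return(-Inf)
  if (theta <= 0 || theta >= 1) return(-Inf)
  N_t <- N0 - c(0, cumsum(y))[seq_along(y)]
  p_t <- switch(link,
                geometric = -expm1(data$effort * log1p(-theta)),
                exponential = -expm1(-theta * data$effort))
  sum(stats::dbinom(y, N_t, p_t, log = TRUE))
}

#' Fit the Bayesian removal model by MCMC
#'
#' Metropolis-within-Gibbs sampler: a discrete random-walk proposal on N0
#' (support bounded below by the total catch and above by \code{n_max})
#' and a logit-scale random walk on theta. Priors: N0 discrete-uniform on
#' its support, theta ~ Beta(1, 1). Posterior summaries use the median
#' and the 2.5/97.5 percentiles.
#'
#' @param data A \code{\link{removal_data}}.
#' @param n_max Upper prior bound for N0; default 20 x total catch.
#' @param n_iter,burn_in Chain length and discarded burn-in.
#' @param seed Integer seed (chains are reproducible).
#' @param link Effort link passed to \code{\link{removal_loglik}}.
#' @param step_N0 Half-width of the discrete N0 proposal.
#' @param step_theta SD of the logit-theta proposal.
#' @return A \code{removal_posterior}: matrices of samples, acceptance
#'   rates, effective sample sizes, and an \code{abundance_estimate}
#'   summary (\code{$estimate}) with the posterior median and 95\%
#'   credible interval. Zero total catch is flagged non-estimable.
#' @export
fit_removal <- function(data, n_max = NULL, n_iter = 50000L,
                        burn_in = 10000L, seed = 1L,
                        link = c("geometric", "exponential"),
                        step_N0 = 5L, step_theta = 0.3) {
  link <- match.arg(link)
  total <- sum(data$catches)
  if (total == 0) {
    out <- list(estimable = FALSE, reason = "zero total catch",
                samples = NULL, estimate = NULL)
    class(out) <- "removal_posterior"
    return(out)
  }
  if (is.null(n_max)) n_max <- 20L * total
  n_max <- max(n_max, total)
  set.seed(as.integer(seed))

  N0 <- max(total, round(total * 1.5))
  N0 <- min(N0, n_max)
  theta <- 0.05
  lth <- stats::qlogis(theta)
  ll <- removal_loglik(data, N0, theta, link)
  if (!is.finite(ll)) ll <- -1e300

  keep_N <- integer(n_iter - burn_in)
  keep_th <- numeric(n_iter - burn_in)
  acc <- c(N0 = 0L, theta = 0L)
  steps_N <- seq.int(-step_N0, step_N0)
  steps_N <- steps_N[steps_N != 0]

  for (it in seq_len(n_iter)) {
    # discrete random walk on N0 (symmetric proposal, uniform prior)
    N_prop <- N0 + sample(steps_N, 1L)
    if (N_prop >= total && N_prop <= n_max) {
      ll_prop <- removal_loglik(data, N_prop, theta, link)
      if (is.finite(ll_prop) && log(stats::runif(1)) < ll_prop - ll) {
        N0 <- N_prop; ll <- ll_prop; acc[1] <- acc[1] + 1L
      }
    }
    # logit random walk on theta; Beta(1,1) prior with Jacobian term
    lth_prop <- lth + stats::rnorm(1, 0, step_theta)
    th_prop <- stats::plogis(lth_prop)
    ll_prop <- removal_loglik(data, N0, th_prop, link)
    lpost_diff <- (ll_prop + log(th_prop) + log1p(-th_prop)) -
      (ll + log(theta) + log1p(-theta))
    if (is.finite(ll_prop) && log(stats::runif(1)) < lpost_diff) {
      theta <- th_prop; lth <- lth_prop; ll <- ll_prop
      acc[2] <- acc[2] + 1L
    }
    if (it > burn_in) {
      keep_N[it - burn_in] <- N0
      keep_th[it - burn_in] <- theta
    }
  }

  qs <- stats::quantile(keep_N, c(0.025, 0.5, 0.975), names = FALSE)
  est <- abundance_estimate(qs[2], stats::var(keep_N), qs[1], qs[3],
                            method = "removal")
  out <- list(
    estimable = TRUE, reason = "ok",
    samples = data.frame(N0 = keep_N, theta = keep_th),
    acceptance = acc / n_iter,
    ess = c(N0 = ess(keep_N), theta = ess(keep_th)),
    n_max = n_max, link = link,
    estimate = est)
  class(out) <- "removal_posterior"
  out
}

# effective sample size from the autocorrelation function (initial
# positive sequence truncation)
ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE)$acf[-1]
  pos <- which(rho < 0.05)
  m <- if (length(pos)) pos[1] - 1 else length(rho)
  n / (1 + 2 * sum(rho[seq_len(m)]))
}

#' @export
print.removal_posterior <- function(x, ...) {
  if (!x$estimable) {
    cat("Removal model: non-estimable (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "Removal posterior: N0 median %.0f (95%% CrI %.0f-%.0f), theta median %.4f\n",
    x$estimate$n_hat, x$estimate$ci_low, x$estimate$ci_high,
    stats::median(x$samples$theta)))
  cat(sprintf("  acceptance: N0 %.2f, theta %.2f;  ESS: N0 %.0f, theta %.0f\n",
              x$acceptance[1], x$acceptance[2], x$ess[1], x$ess[2]))
  invisible(x)
}

#' Extract removal data from a simulated dataset
#'
#' @param dataset A \code{sim_dataset}.
#' @return A \code{\link{removal_data}} of nightly catches and effort.
#' @export
removal_data_from_dataset <- function(dataset) {
  T_n <- attr(dataset$trap_history, "n_occasions")
  y <- tabulate(dataset$trap_history$occasion + 1L, nbins = T_n)
  removal_data(y, dataset$effort$n_traps_active)
}
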
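# shared fixtures, built in code

small_config <- function(...) {
  args <- list(...)
  defaults <- list(sigma = 0.6, g0_camera = 0.5, density = 2.5,
                   landscape_margin_km = 2.4, seed = 1L)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# hand-built encounter history from a record table
make_history <- function(ind, occ, det_id, type = "camera",
                         n_occasions = max(occ) + 1L, removals = NULL) {
  recs <- data.frame(individual_id = ind, occasion = as.integer(occ),
                     detector_id = det_id,
                     detector_type = rep_len(type, length(ind)),
                     removed_flag = rep_len(FALSE, length(ind)),
                     stringsAsFactors = FALSE)
  h <- structure(recs, class = c("encounter_history", "data.frame"))
  attr(h, "phase") <- type[1]
  attr(h, "n_occasions") <- as.integer(n_occasions)
  attr(h, "removals") <- removals %||%
    data.frame(individual_id = integer(), removal_occasion = integer())
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force SECR log-likelihood: plain loops over mask
# points, individuals, detectors and occasions; supports removal
# truncation, a usage matrix, and the site-specific behavioural effect
brute_secr_loglik <- function(history, detectors, mask, D, g0, sigma,
                              usage = NULL, g0_post = g0) {
  ids <- sort(unique(history$individual_id))
  n <- length(ids)
  K <- nrow(detectors)
  T_n <- attr(history, "n_occasions")
  if (is.null(usage)) usage <- matrix(TRUE, K, T_n)
  removals <- attr(history, "removals")
  ca <- attr(mask, "cell_area")
  M <- nrow(mask)

  halfnorm <- function(s, k, g) {
    d2 <- (detectors$x[k] - mask$x[s])^2 + (detectors$y[k] - mask$y[s])^2
    g * exp(-d2 / (2 * sigma^2))
  }
  sum_pr <- numeric(n)
  for (ii in seq_len(n)) {
    id <- ids[ii]
    h <- history[history$individual_id == id, ]
    r_i <- T_n - 1
    if (nrow(removals)) {
      w <- removals$individual_id == id
      if (any(w)) r_i <- removals$removal_occasion[w]
    }
    acc <- 0
    for (s in seq_len(M)) {
      pr <- 1
      for (k in seq_len(K)) {
        for (t in 0:r_i) {
          if (!usage[k, t + 1]) next
          post <- any(h$detector_id == detectors$id[k] & h$occasion < t)
          p <- halfnorm(s, k, if (post) g0_post else g0)
          y <- any(h$detector_id == detectors$id[k] & h$occasion == t)
          pr <- pr * if (y) p else (1 - p)
        }
      }
      acc <- acc + pr
    }
    sum_pr[ii] <- acc * ca
  }
  pdot <- numeric(M)
  for (s in seq_len(M)) {
    q <- 1
    for (k in seq_len(K))
      for (t in seq_len(T_n))
        if (usage[k, t]) q <- q * (1 - halfnorm(s, k, g0))
    pdot[s] <- 1 - q
  }
  Lambda <- D * ca * sum(pdot)
  -Lambda + sum(log(D) + log(sum_pr)) - lfactorial(n)
}

# simulate two-sample homogeneous detection for LPE checks
sim_two_sample <- function(N, p1, p2) {
  s1 <- which(stats::runif(N) < p1)
  s2 <- which(stats::runif(N) < p2)
  list(n1 = length(s1), n2 = length(s2), m = length(intersect(s1, s2)))
}

# simulate depletion catches from the removal model itself
sim_removal_catches <- function(N0, theta, effort) {
  y <- integer(length(effort))
  N <- N0
  for (t in seq_along(effort)) {
    p <- 1 - (1 - theta)^effort[t]
    y[t] <- stats::rbinom(1, N, p)
    N <- N - y[t]
  }
  y
}
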
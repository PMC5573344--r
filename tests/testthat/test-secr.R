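test_that("mask covers the detectors and scales with spacing", {
  det <- build_detector_grid(5, 4, 0.75, 10, seed = 1)
  mask <- build_mask(det, buffer_km = 2, spacing_km = 0.25)
  expect_true(all(det$x >= min(mask$x) & det$x <= max(mask$x)))
  expect_true(all(det$y >= min(mask$y) & det$y <= max(mask$y)))
  expect_equal(attr(mask, "area"), nrow(mask) * 0.25^2)
  m2 <- build_mask(det, buffer_km = 2, spacing_km = 0.125)
  expect_gt(nrow(m2) / nrow(mask), 3.5)
  expect_lt(nrow(m2) / nrow(mask), 4.5)
  m0 <- build_mask(det, buffer_km = 0, spacing_km = 0.25)
  expect_equal(range(m0$x), range(det$x))
  expect_equal(range(m0$y), range(det$y))
})

test_that("likelihood matches brute-force quadrature on toy instances", {
  det <- build_detector_grid(2, 2, 0.75, 1, seed = 1)[1:4, ]  # 4 cameras
  mask <- build_mask(det, buffer_km = 0.75, spacing_km = 0.5)
  h <- make_history(c(1, 1, 2, 3, 3, 3),
                    c(0, 1, 0, 0, 1, 2),
                    c("C01", "C02", "C03", "C01", "C01", "C04"),
                    n_occasions = 3L)
  ll <- secr_loglik(h, det, mask, list(D = 1.5, g0 = 0.3, sigma = 0.5))
  ref <- brute_secr_loglik(h, det, mask, 1.5, 0.3, 0.5)
  expect_equal(ll, ref, tolerance = 1e-6)

  # removal truncation: individual 2 removed at occasion 0
  h2 <- make_history(c(1, 1, 2), c(0, 1, 0), c("C01", "C02", "C03"),
                     n_occasions = 3L,
                     removals = data.frame(individual_id = 2,
                                           removal_occasion = 0))
  ll2 <- secr_loglik(h2, det, mask, list(D = 2, g0 = 0.4, sigma = 0.4))
  ref2 <- brute_secr_loglik(h2, det, mask, 2, 0.4, 0.4)
  expect_equal(ll2, ref2, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(ll2,
    brute_secr_loglik(make_history(c(1, 1, 2), c(0, 1, 0),
                                   c("C01", "C02", "C03"), n_occasions = 3L),
                      det, mask, 2, 0.4, 0.4))))

  # behavioural (bk) effect and a usage matrix
  usage <- matrix(TRUE, 4, 3); usage[2, 3] <- FALSE
  spec <- secr_model_spec(behavior = TRUE)
  ll3 <- secr_loglik(h, det, mask,
                     list(D = 1.5, g0 = 0.3, sigma = 0.5, beta_bk = 0.8),
                     model_spec = spec, usage = usage)
  g0_post <- plogis(qlogis(0.3) + 0.8)
  ref3 <- brute_secr_loglik(h, det, mask, 1.5, 0.3, 0.5, usage = usage,
                            g0_post = g0_post)
  expect_equal(ll3, ref3, tolerance = 1e-6)
})

test_that("vanishing g0 makes any nonempty history impossible", {
  det <- build_detector_grid(2, 2, 0.75, 1, seed = 1)[1:4, ]
  mask <- build_mask(det, 0.75, 0.5)
  h <- make_history(1, 0, "C01", n_occasions = 2L)
  ll <- secr_loglik(h, det, mask, list(D = 1, g0 = 1e-10, sigma = 0.5))
  expect_lt(ll, -20)
  ll2 <- secr_loglik(h, det, mask, list(D = 1, g0 = 1e-14, sigma = 0.5))
  expect_lt(ll2, ll)
})

test_that("likelihood is stable under mask refinement", {
  det <- build_detector_grid(5, 4, 0.75, 10, seed = 1)
  cams <- det[det$type == "camera", ]
  h <- simulate_secr_history(2, 0.5, 0.6, cams, 5, 2.4, seed = 3)
  pars <- list(D = 2, g0 = 0.5, sigma = 0.6)
  ll_fine <- secr_loglik(h, cams, build_mask(cams, 2.4, 0.1), pars)
  ll_coarse <- secr_loglik(h, cams, build_mask(cams, 2.4, 0.2), pars)
  expect_lt(abs(ll_fine - ll_coarse), 0.1)
})

test_that("histories without spatial recaptures are flagged, not fitted", {
  det <- build_detector_grid(5, 4, 0.75, 10, seed = 1)
  cams <- det[det$type == "camera", ]
  mask <- build_mask(cams, 1.5, 0.25)
  h <- make_history(c(1, 2, 3), c(0, 0, 1), c("C01", "C05", "C09"),
                    n_occasions = 13L)
  fit <- fit_secr(h, cams, mask)
  expect_false(fit$converged)
  expect_match(fit$reason, "spatial recaptures")
  expect_error(fit_secr(make_history(integer(), integer(), character(),
                                     n_occasions = 2L), cams, mask),
               "no detections")
})

test_that("fit recovers generating parameters on one rich dataset", {
  det <- build_detector_grid(5, 4, 0.75, 10, seed = 1)
  cams <- det[det$type == "camera", ]
  h <- simulate_secr_history(2, 0.5, 0.6, cams, 13, 2.4, seed = 7)
  mask <- build_mask(cams, 2.4, 0.3)
  fit <- fit_secr(h, cams, mask)
  expect_true(fit$converged)
  expect_gt(fit$g0, 0.3); expect_lt(fit$g0, 0.7)
  expect_gt(fit$sigma, 0.45); expect_lt(fit$sigma, 0.8)
  expect_gt(fit$D, 1); expect_lt(fit$D, 4.5)
  expect_lt(fit$ci_low, fit$D); expect_gt(fit$ci_high, fit$D)
  # likelihood at the optimum beats the truth (it is the maximum)
  ll_true <- secr_loglik(h, cams, mask, list(D = 2, g0 = 0.5, sigma = 0.6))
  expect_gte(fit$loglik, ll_true - 1e-6)
})

test_that("pooling trap occasions does not hurt precision", {
  # trap SECR uses strictly more data than camera SECR
  cfg <- small_config(sigma = 0.8, g0_camera = 0.7, density = 2.5)
  wins <- 0L; total <- 0L
  for (s in 1:10) {
    cfg$seed <- s * 13L
    ds <- simulate_dataset(cfg)
    cams <- ds$detectors[ds$detectors$type == "camera", ]
    mask_c <- build_mask(cams, 2.5, 0.3)
    f_cam <- fit_secr(ds$camera_history, cams, mask_c)
    cmb <- combine_histories(ds$camera_history, ds$trap_history)
    usage <- make_usage(ds$detectors, cfg$n_camera_occasions,
                        cfg$n_trap_occasions)
    mask_t <- build_mask(ds$detectors, 2.5, 0.3)
    f_trap <- fit_secr(cmb, ds$detectors, mask_t, usage = usage)
    if (f_cam$converged && f_trap$converged) {
      total <- total + 1L
      if (f_trap$se_D <= f_cam$se_D) wins <- wins + 1L
    }
  }
  expect_gt(total, 5)
  expect_gt(wins / total, 0.5)
})

test_that("the detector-type model recovers the trap/camera g0 ratio", {
  cfg <- small_config(sigma = 0.8, g0_camera = 0.8, density = 2.5,
                      behavior_mult = 1)
  in_range <- 0L; total <- 0L
  for (s in 1:8) {
    cfg$seed <- 1000L + s
    ds <- simulate_dataset(cfg)
    cmb <- combine_histories(ds$camera_history, ds$trap_history)
    usage <- make_usage(ds$detectors, cfg$n_camera_occasions,
                        cfg$n_trap_occasions)
    mask <- build_mask(ds$detectors, 2.5, 0.3)
    fit <- fit_secr(cmb, ds$detectors, mask,
                    model_spec = secr_model_spec(type_effect = TRUE),
                    usage = usage)
    if (fit$converged) {
      total <- total + 1L
      ratio <- fit$g0_trap / fit$g0
      if (ratio > 0.1 && ratio < 0.5) in_range <- in_range + 1L
    }
  }
  expect_gt(total, 4)
  expect_gt(in_range / total, 0.5)
})

test_that("AICc table reproduces the formula and normalises weights", {
  f <- function(ll, K, model) {
    structure(list(converged = TRUE, loglik = ll, K = K, model = model,
                   D = 2), class = "secr_fit")
  }
  tab <- aicc_table(list(f(-100, 3, "null")), n_individuals = 20)
  expect_equal(tab$aicc, 207.5)
  expect_equal(tab$weight, 1.0)

  tab2 <- aicc_table(list(f(-100, 3, "null"), f(-99, 4, "bk"),
                          f(-98.5, 5, "type")), n_individuals = 40)
  expect_equal(sum(tab2$weight), 1, tolerance = 1e-12)
  expect_equal(tab2$delta_aicc[1], 0)
  expect_error(aicc_table(list(f(-100, 3, "null")), n_individuals = 4),
               "exceed")
})
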
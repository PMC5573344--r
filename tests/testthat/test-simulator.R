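test_that("detector grid reproduces the field layout geometry", {
  det <- build_detector_grid(5, 4, 0.75, 10, seed = 3)
  cams <- det[det$type == "camera", ]
  traps <- det[det$type == "trap", ]
  expect_equal(nrow(cams), 20)
  expect_equal(nrow(traps), 10)
  expect_equal(max(cams$x) - min(cams$x), 3.0)
  expect_equal(max(cams$y) - min(cams$y), 2.25)
  expect_true(all(traps$x >= min(cams$x) & traps$x <= max(cams$x)))
  expect_true(all(traps$y >= min(cams$y) & traps$y <= max(cams$y)))
  expect_false(anyDuplicated(det$id) > 0)
  # brute-force nearest-neighbour distance over the 20 lattice points
  dd <- as.matrix(dist(cams[, c("x", "y")]))
  diag(dd) <- Inf
  expect_equal(min(dd), 0.75)
})

test_that("degenerate grids and over-subscribed strata are handled", {
  det <- build_detector_grid(1, 1, 0.75, 1, seed = 1)
  expect_equal(nrow(det), 2)
  expect_equal(det$x[det$type == "camera"], 0)
  expect_error(build_detector_grid(5, 4, 0.75, 5, seed = 1, strata = c(2, 2)),
               "exceeds number of strata")
})

test_that("centroid count is forced to round(density x area)", {
  det <- build_detector_grid(1, 1, 0.75, 1, seed = 1)
  cfg <- small_config(density = 2.0, landscape_margin_km = 2.5)
  expect_equal(landscape_area(det, 2.5), 25)
  pop <- simulate_centroids(cfg, det)
  expect_equal(nrow(pop), 50)
  cfg2 <- small_config(density = 7.5, landscape_margin_km = 2.5, seed = 9)
  expect_equal(nrow(simulate_centroids(cfg2, det)), round(7.5 * 25))
})

test_that("zero cluster radius collapses offspring onto parents", {
  det <- build_detector_grid(1, 1, 0.75, 1, seed = 1)
  cfg <- small_config(density = 4, landscape_margin_km = 2.5,
                      cluster_radius_km = 0, cluster_mean_size = 5)
  pop <- simulate_centroids(cfg, det)
  n_parents <- ceiling(nrow(pop) / 5)
  expect_lte(nrow(unique(pop[, c("x", "y")])), n_parents)
})

test_that("larger clusters shrink nearest-neighbour distances", {
  det <- build_detector_grid(1, 1, 0.75, 1, seed = 1)
  mean_nn <- function(mean_size, seed) {
    cfg <- small_config(density = 2, landscape_margin_km = 2.5,
                        cluster_mean_size = mean_size, seed = seed)
    pop <- simulate_centroids(cfg, det)
    dd <- as.matrix(dist(pop[, c("x", "y")]))
    diag(dd) <- Inf
    mean(apply(dd, 1, min))
  }
  nn5 <- vapply(1:60, function(s) mean_nn(5, s), numeric(1))
  nn1 <- vapply(61:120, function(s) mean_nn(1, s), numeric(1))
  expect_lt(mean(nn5), mean(nn1))
})

test_that("availability kernel matches the truncated Gaussian with clamp", {
  expect_equal(availability_prob(0, 1.0, 3), 1 / sqrt(2 * pi),
               tolerance = 1e-10)
  expect_equal(round(availability_prob(0, 1.0, 3), 5), 0.39894)
  expect_equal(availability_prob(3.1, 1.0, 3), 0)
  expect_equal(availability_prob(0, 0.1, 0.3), 1)   # raw 3.989 clamped
  d <- seq(0, 4, by = 0.01)
  p <- availability_prob(d, 0.7, 2.1)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p <= 1))
  raw <- dnorm(d, 0, 0.7)
  expect_equal(p[raw <= 1 & d <= 2.1], raw[raw <= 1 & d <= 2.1])
  expect_error(availability_prob(-0.1, 1, 3), "non-negative")
})

test_that("detection probability scales availability by g0", {
  expect_equal(round(detection_prob(0, 1.0, 0.5, 3), 5), 0.19947)
  expect_equal(detection_prob(c(0, 1, 2), 1, 0, 3), c(0, 0, 0))
  # corral-trap baseline is one quarter of the camera baseline at equal d
  d <- c(0, 0.4, 1.1)
  expect_equal(detection_prob(d, 0.6, 0.8 * 0.25, 2.4),
               0.25 * detection_prob(d, 0.6, 0.8, 2.4))
})

test_that("camera phase is seed-reproducible and respects the visit cap", {
  cfg <- small_config(seed = 11)
  det <- build_detector_grid(5, 4, 0.75, 10, seed = 2)
  pop <- simulate_centroids(cfg, det)
  h1 <- simulate_camera_phase(pop, det, cfg)
  h2 <- simulate_camera_phase(pop, det, cfg)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  # daily scale: no duplicate (individual, occasion, detector)
  key <- paste(h1$individual_id, h1$occasion, h1$detector_id)
  expect_false(anyDuplicated(key) > 0)
  # at most 3 distinct cameras per individual-night
  per_night <- table(paste(h1$individual_id, h1$occasion))
  expect_lte(max(per_night), 3)
})

test_that("single-camera detection rate matches the analytic expectation", {
  det <- build_detector_grid(1, 1, 0.75, 1, seed = 1)
  cam <- det[det$type == "camera", ]
  cfg <- small_config(sigma = 1.2, g0_camera = 0.9, behavior_mult = 1,
                      n_camera_occasions = 1000, landscape_margin_km = 1,
                      seed = 4)
  pop <- data.frame(individual_id = 1L, x = cam$x, y = cam$y)
  class(pop) <- c("population", "data.frame")
  h <- simulate_camera_phase(pop, det, cfg)
  p_true <- 0.9 * dnorm(0, 0, 1.2)
  se <- sqrt(p_true * (1 - p_true) / 1000)
  expect_lt(abs(nrow(h) / 1000 - p_true), 3 * se)
})

test_that("visit counts given detection follow the multinomial weights", {
  # one individual centred in the grid with every camera in reach
  det <- build_detector_grid(5, 4, 0.75, 10, seed = 2)
  cams <- det[det$type == "camera", ]
  cfg <- small_config(sigma = 1.2, g0_camera = 0.9, behavior_mult = 1,
                      n_camera_occasions = 3000, seed = 8)
  pop <- data.frame(individual_id = 1L, x = mean(cams$x), y = mean(cams$y))
  class(pop) <- c("population", "data.frame")
  h <- simulate_camera_phase(pop, det, cfg)
  k_per_night <- table(factor(table(h$occasion), levels = 1:3))
  expect_gt(chisq.test(as.vector(k_per_night),
                       p = c(0.82, 0.15, 0.03))$p.value, 0.001)
})

test_that("trap-happiness raises return rates at previously visited cameras", {
  det <- build_detector_grid(1, 1, 0.75, 1, seed = 1)
  cam <- det[det$type == "camera", ]
  rate <- function(mult, seed) {
    cfg <- small_config(sigma = 0.6, g0_camera = 0.3, behavior_mult = mult,
                        n_camera_occasions = 400, landscape_margin_km = 1,
                        seed = seed)
    pop <- data.frame(individual_id = 1L, x = cam$x + 0.3, y = cam$y)
    class(pop) <- c("population", "data.frame")
    h <- simulate_camera_phase(pop, det, cfg)
    # rate after the first detection
    if (nrow(h) < 2) return(NA_real_)
    (nrow(h) - 1) / (400 - min(h$occasion) - 1)
  }
  r2 <- mean(vapply(1:20, function(s) rate(2, s), numeric(1)), na.rm = TRUE)
  r1 <- mean(vapply(21:40, function(s) rate(1, s), numeric(1)), na.rm = TRUE)
  expect_gt(r2, r1)
})

test_that("trap phase logs effort, removes on first capture, conserves N", {
  cfg <- small_config(seed = 21)
  ds <- simulate_dataset(cfg)
  expect_equal(sum(ds$effort$n_traps_active), 140)
  expect_equal(nrow(ds$effort), 14)
  th <- ds$trap_history
  # one trap record per removed individual, none after removal
  expect_false(anyDuplicated(th$individual_id) > 0)
  expect_true(all(th$removed_flag))
  # conservation: removals + survivors = initial N
  expect_equal(nrow(th) + (nrow(ds$population) - nrow(th)),
               nrow(ds$population))
  expect_true(all(th$individual_id %in% ds$population$individual_id))
})

test_that("perfect detection at trap sites depletes the population", {
  det <- build_detector_grid(2, 2, 0.75, 2, seed = 1)
  traps <- det[det$type == "trap", ]
  cfg <- small_config(sigma = 0.2, g0_camera = 1, trap_g0_ratio = 1,
                      n_trap_occasions = 14, seed = 5)
  pop <- data.frame(individual_id = 1:6,
                    x = rep(traps$x, 3), y = rep(traps$y, 3))
  class(pop) <- c("population", "data.frame")
  tp <- simulate_trap_phase(pop, det, cfg)
  expect_equal(nrow(tp$history), 6)               # everyone removed
  expect_equal(sort(unique(tp$history$occasion)), 0)  # first night
})

test_that("full datasets are reproducible and sparse cells often yield zero catch", {
  cfg <- small_config(seed = 31)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.data.frame(d1$camera_history),
                   as.data.frame(d2$camera_history))
  expect_identical(as.data.frame(d1$trap_history),
                   as.data.frame(d2$trap_history))
  expect_identical(d1$population, d2$population)
  zero <- vapply(1:50, function(s) {
    cfg <- simulation_config(sigma = 0.1, g0_camera = 0.1, density = 0.25,
                             seed = s)
    nrow(simulate_dataset(cfg)$trap_history) == 0
  }, logical(1))
  expect_gt(mean(zero), 0.2)
})
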
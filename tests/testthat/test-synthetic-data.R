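test_that("order sampling respects the requested distribution", {
  expect_true(all(sample_orders(c(1, 0, 0, 0, 0), 100, seed = 1) == 1))
  expect_true(all(sample_orders(c(0, 1, 0, 0, 0), 50, seed = 1) == 2))
  n <- 1e5
  orders <- sample_orders(c(0.5, 0.5, 0, 0, 0), n, seed = 2)
  se <- 0.5 / sqrt(n)
  expect_lt(abs(mean(orders) - 1.5), 3 * se)
  expect_error(sample_orders(c(0.5, 0.6), 10), "sum to 1")
  expect_error(sample_orders(c(-0.5, 1.5), 10), "non-negative")
  expect_identical(sample_orders(c(0.3, 0.7, 0, 0, 0), 20, seed = 5),
                   sample_orders(c(0.3, 0.7, 0, 0, 0), 20, seed = 5))
})

test_that("labeling is conditionally binomial in the subunit count", {
  expect_true(all(apply_labeling(rep(2, 100), 1.0, seed = 1) == 2))
  n <- 1e5
  lab2 <- apply_labeling(rep(2, n), 0.8, seed = 3)
  se2 <- sqrt(0.64 * 0.36 / n)
  expect_lt(abs(mean(lab2 == 2) - 0.64), 3 * se2)
  lab3 <- apply_labeling(rep(3, n), 0.8, seed = 4)
  se1 <- sqrt(0.096 * (1 - 0.096) / n)
  expect_lt(abs(mean(lab3 == 1) - 0.096), 3 * se1)
  # chi-square goodness of fit against Binomial(i, 0.8) for each order
  for (i in 2:4) {
    lab <- apply_labeling(rep(i, n), 0.8, seed = 10 + i)
    obs <- tabulate(lab + 1L, nbins = i + 1)
    p_exp <- dbinom(0:i, i, 0.8)
    gof <- suppressWarnings(chisq.test(obs, p = p_exp))
    expect_gt(gof$p.value, 0.001)
  }
  expect_error(apply_labeling(c(1, 2), 0), "probability")
})

test_that("traces have the exact staircase structure without noise", {
  cfg <- noiseless_cfg(n_frames = 200)
  tr0 <- simulate_trace(0, cfg, seed = 1)
  expect_true(all(tr0$intensity == cfg$background_level))

  tr2 <- simulate_trace(2, cfg, seed = 2, bleach_frames = c(50, 120))
  expect_equal(nrow(tr2), 200)
  lv <- rle(tr2$intensity)$values
  expect_equal(lv, cfg$background_level + c(2, 1, 0) * cfg$unit_intensity)
  expect_equal(which(diff(tr2$intensity) != 0), c(50, 120))
})

test_that("first bleach of k fluorophores is the minimum of k exponentials", {
  cfg <- noiseless_cfg(n_frames = 1, mean_bleach_time = 100)
  n <- 1e4
  set.seed(6)
  first <- replicate(n, min(photobleachr:::sample_bleach_frames(3, cfg)))
  se <- (100 / 3) / sqrt(n)
  # ceiling() of the continuous time adds ~0.5 on average
  expect_lt(abs(mean(first) - (100 / 3 + 0.5)), 4 * se)
})

test_that("pre-acquisition segment is scaled and followed by an upstroke", {
  cfg <- noiseless_cfg(n_frames = 100, preacq_frames = 20, preacq_scale = 0.1,
                       mean_bleach_time = 1e6)
  tr <- simulate_trace(1, cfg, seed = 1)
  expect_equal(tr$intensity[1:20],
               rep(0.1 * cfg$unit_intensity + cfg$background_level, 20))
  expect_gt(tr$intensity[21] - tr$intensity[20], 0.8 * cfg$unit_intensity)
})

test_that("rendered movies match ground truth geometry and photometry", {
  empty <- simulate_movie(noiseless_cfg(n_particles = 0), seed = 1)
  expect_equal(nrow(empty$truth), 0)
  expect_true(all(empty$movie$data == 100))

  cfg <- noiseless_cfg(n_particles = 1, true_fractions = c(1, 0, 0, 0, 0),
                       labeling_efficiency = 1, n_frames = 60,
                       mean_bleach_time = 20)
  sim <- simulate_movie(cfg, seed = 8)
  truth <- sim$truth
  expect_equal(truth$labeled_count, 1L)
  f1 <- get_frame(sim$movie, 1)
  peak <- which(f1 == max(f1), arr.ind = TRUE)
  expect_lt(abs(peak[1, 1] - truth$row), 1)
  expect_lt(abs(peak[1, 2] - truth$col), 1)
  bf <- as.integer(truth$bleach_frames)
  if (bf < 60) {
    expect_true(all(get_frame(sim$movie, bf + 1) == cfg$background_level))
  }

  # integrated intensity of an interior live spot = labeled_count * unit *
  # 2 pi sigma^2 within 1% discretization error
  cfg2 <- noiseless_cfg(n_particles = 6, true_fractions = c(0, 1, 0, 0, 0),
                        labeling_efficiency = 1, n_frames = 3,
                        mean_bleach_time = 1e6, image_shape = c(96, 96),
                        min_separation = 20)
  sim2 <- simulate_movie(cfg2, seed = 9)
  f1 <- get_frame(sim2$movie, 1) - cfg2$background_level
  interior <- interior_only(sim2$truth, c(96, 96), margin = 10)
  expect_gt(nrow(interior), 0)
  for (i in seq_len(nrow(interior))) {
    r0 <- round(interior$row[i]); c0 <- round(interior$col[i])
    tot <- sum(f1[(r0 - 8):(r0 + 8), (c0 - 8):(c0 + 8)])
    expected <- 2 * cfg2$unit_intensity * 2 * pi * cfg2$psf_sigma^2
    expect_lt(abs(tot - expected) / expected, 0.01)
  }
})

test_that("Poisson placement realizes the requested density", {
  cfg <- sim_config(particle_density = 0.22, image_shape = c(512, 512),
                    pixel_size = 0.107, n_frames = 1, shot_noise = FALSE,
                    read_noise_sd = 0)
  sim <- simulate_movie(cfg, seed = 123)
  expect_lt(abs(sim$realized_density - 0.22) / 0.22, 0.10)
  expect_true(all(sim$truth$row >= 0.5 & sim$truth$row <= 512.5))
  expect_true(all(sim$truth$col >= 0.5 & sim$truth$col <= 512.5))
})

test_that("hard-core placement enforces the minimum separation", {
  cfg <- noiseless_cfg(n_particles = 40, image_shape = c(96, 96),
                       n_frames = 1, min_separation = 6)
  sim <- simulate_movie(cfg, seed = 3)
  d <- as.matrix(dist(cbind(sim$truth$row, sim$truth$col)))
  diag(d) <- Inf
  expect_gte(min(d), 6)
  # infeasible packing warns and returns what fits
  cfg2 <- noiseless_cfg(n_particles = 500, image_shape = c(32, 32),
                        n_frames = 1, min_separation = 10)
  expect_warning(sim2 <- simulate_movie(cfg2, seed = 4), "saturated")
  expect_lt(nrow(sim2$truth), 500)
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- sim_config(n_particles = 15, particle_density = NULL,
                    image_shape = c(48, 48), n_frames = 30,
                    mean_bleach_time = 10)
  a <- simulate_movie(cfg, seed = 77)
  b <- simulate_movie(cfg, seed = 77)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth, b$truth)
})

test_that("ground-truth summaries converge to the sampled distribution", {
  p <- c(0.435, 0.467, 0.049, 0.049, 0)
  n <- 20000
  orders <- sample_orders(p, n, seed = 15)
  frac <- truth_fractions(tibble::tibble(true_order = orders), n_max = 5)
  bound <- 3 * sqrt(p * (1 - p) / n) + 1e-12
  expect_true(all(abs(frac$fraction - p) < pmax(bound, 0.005)))
})

test_that("simulation config validates its bounds", {
  expect_error(sim_config(true_fractions = c(0.5, 0.6, 0, 0, 0)), "sum to 1")
  expect_error(sim_config(labeling_efficiency = 1.2), "probability")
  expect_error(sim_config(psf_sigma = 0), "psf_sigma")
  expect_error(sim_config(preacq_scale = 1), "preacq_scale")
  expect_error(sim_config(n_frames = 0), "n_frames")
})
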
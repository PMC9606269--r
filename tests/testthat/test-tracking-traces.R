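fake_spots <- function(frames, row, col, amplitude = 500) {
  tibble::tibble(frame = frames, row = row, col = col,
                 amplitude = amplitude, background = 100, sigma = 1.3,
                 fit_rss = 0, converged = TRUE)
}

test_that("stationary particles link into single full-length tracks", {
  one <- fake_spots(1:100, row = 20 + rnorm(100, 0, 0.05),
                    col = 30 + rnorm(100, 0, 0.05))
  tr <- link_spots(one)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 100)

  two <- dplyr::bind_rows(
    fake_spots(rep(1:50, each = 1), 10, 10),
    fake_spots(1:50, 10, 30))
  tr2 <- link_spots(two)
  expect_equal(length(unique(tr2$track_id)), 2)
  anc <- track_anchors(tr2)
  expect_equal(sort(anc$col), c(10, 30))

  bleached <- fake_spots(1:50, 15, 15)
  tr3 <- link_spots(bleached)
  expect_equal(track_anchors(tr3)$end_frame, 50)
})

test_that("links respect the displacement bound and gaps", {
  jumpy <- fake_spots(1:2, row = c(10, 18), col = c(10, 10))
  tr <- link_spots(jumpy, max_displacement = 2)
  expect_equal(length(unique(tr$track_id)), 2)
  gappy <- fake_spots(c(1, 2, 4), 10, 10)
  expect_equal(length(unique(link_spots(gappy, max_gap = 0)$track_id)), 2)
  expect_equal(length(unique(link_spots(gappy, max_gap = 1)$track_id)), 1)
})

test_that("trace extraction recovers integrated spot intensity then zero", {
  cfg <- noiseless_cfg(n_particles = 1, true_fractions = c(1, 0, 0, 0, 0),
                       labeling_efficiency = 1, image_shape = c(64, 64),
                       n_frames = 80, mean_bleach_time = 25,
                       min_separation = 30)
  sim <- simulate_movie(cfg, seed = 21)
  truth <- sim$truth
  bf <- as.integer(truth$bleach_frames)
  anchors <- tibble::tibble(track_id = 1L, row = truth$row, col = truth$col)
  res <- extract_traces(sim$movie, anchors)
  tr <- res$traces
  expect_equal(nrow(tr), 80)
  # aperture of radius 3 on a sigma-1.3 Gaussian captures ~93% of the flux
  expected_unit <- cfg$unit_intensity * 2 * pi * cfg$psf_sigma^2
  if (bf >= 5 && bf < 75) {
    live <- mean(tr$intensity[1:(bf - 1)])
    expect_gt(live / expected_unit, 0.85)
    expect_lt(live / expected_unit, 1.01)
    expect_lt(max(abs(tr$intensity[(bf + 1):80])), 1e-6)
  }
})

test_that("trace extraction is linear and near zero on pure background", {
  cfg <- noiseless_cfg(n_particles = 2, true_fractions = c(0, 1, 0, 0, 0),
                       labeling_efficiency = 1, image_shape = c(64, 64),
                       n_frames = 40, mean_bleach_time = 15,
                       min_separation = 25)
  sim <- simulate_movie(cfg, seed = 31)
  anchors <- tibble::tibble(track_id = seq_len(2), row = sim$truth$row,
                            col = sim$truth$col)
  t1 <- extract_traces(sim$movie, anchors)$traces
  doubled <- sim$movie
  doubled$data <- (doubled$data - cfg$background_level) * 2 +
    cfg$background_level
  t2 <- extract_traces(doubled, anchors)$traces
  expect_equal(t2$intensity, 2 * t1$intensity, tolerance = 1e-9)

  flat <- movie_stack(array(100, dim = c(32, 32, 20)))
  bg_tr <- extract_traces(flat,
                          tibble::tibble(track_id = 1, row = 16, col = 16))
  expect_true(all(abs(bg_tr$traces$intensity) < 1e-9))
})

test_that("a two-fluorophore noiseless trace has exactly three levels", {
  cfg <- noiseless_cfg(n_frames = 120)
  tr <- simulate_trace(2, cfg, bleach_frames = c(40, 90))
  expect_equal(length(unique(tr$intensity)), 3)
})

test_that("border anchors are excluded with a logged reason", {
  flat <- movie_stack(array(100, dim = c(32, 32, 5)))
  res <- extract_traces(flat, tibble::tibble(track_id = 1:2,
                                             row = c(3, 16), col = c(3, 16)))
  expect_equal(res$rejected$track_id, 1)
  expect_match(res$rejected$reason, "border")
  expect_equal(unique(res$traces$track_id), 2)
})

test_that("QC rejects unbleached, blinking, and overlapping traces", {
  unit <- 1000
  n <- 120
  mk_trace <- function(id, y) tibble::tibble(track_id = id,
                                             frame = seq_along(y),
                                             intensity = y)
  clean <- mk_trace(1, c(rep(2 * unit, 40), rep(unit, 40), rep(0, 40)))
  plateau <- mk_trace(2, rep(unit, n))
  blink <- mk_trace(3, c(rep(unit, 30), rep(0, 30), rep(unit, 30),
                         rep(0, 30)))
  res <- qc_filter_traces(dplyr::bind_rows(clean, plateau, blink),
                          unit_intensity = unit)
  expect_equal(sort(unique(res$accepted$track_id)), 1)
  expect_match(res$rejections$reason[res$rejections$track_id == 2],
               "not fully bleached")
  expect_match(res$rejections$reason[res$rejections$track_id == 3],
               "blinking")

  # neighbor rule: anchors closer than the exclusion radius reject both
  anchors <- tibble::tibble(track_id = c(1, 4), row = c(10, 12),
                            col = c(10, 10))
  both <- dplyr::bind_rows(clean, mk_trace(4, clean$intensity))
  res2 <- qc_filter_traces(both, unit_intensity = unit, anchors = anchors,
                           neighbor_radius = 3.9)
  expect_equal(nrow(res2$accepted), 0)
  expect_true(all(grepl("neighbor", res2$rejections$reason)))
})

test_that("most simulated blinking traces are caught by the QC rule", {
  unit <- 1000
  set.seed(8)
  caught <- 0
  n_blink <- 40
  for (i in seq_len(n_blink)) {
    off <- sample(20:60, 1)
    on <- off + sample(5:30, 1)
    end <- on + sample(10:40, 1)
    y <- rep(0, 150)
    y[1:off] <- unit
    y[on:end] <- unit           # re-brightening after a dark period
    y <- y + rnorm(150, 0, unit / 10)
    res <- qc_filter_traces(tibble::tibble(track_id = 1, frame = 1:150,
                                           intensity = y),
                            unit_intensity = unit)
    if (nrow(res$rejections) > 0 &&
        grepl("blinking", res$rejections$reason[1])) {
      caught <- caught + 1
    }
  }
  expect_gte(caught / n_blink, 0.9)
})
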
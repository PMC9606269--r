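# shared fixtures and oracles, all built in code at test time

# a small, fast noiseless configuration
noiseless_cfg <- function(...) {
  args <- utils::modifyList(
    list(true_fractions = c(0.5, 0.5, 0, 0, 0), n_particles = 20,
         particle_density = NULL, image_shape = c(64, 64), n_frames = 120,
         mean_bleach_time = 30, unit_intensity = 300, background_level = 100,
         shot_noise = FALSE, read_noise_sd = 0),
    list(...))
  do.call(sim_config, args)
}

# config at a target single-fluorophore SNR: pure Gaussian read noise with
# sd = unit_intensity / snr (shot noise off so the SNR is exact)
snr_cfg <- function(snr, unit_intensity = 300, ...) {
  args <- utils::modifyList(
    list(unit_intensity = unit_intensity, background_level = 100,
         shot_noise = FALSE, read_noise_sd = unit_intensity / snr),
    list(...))
  do.call(sim_config, args)
}

# independent oracle for the labeling model: exhaustive enumeration over all
# 2^order labeling outcomes of an order-i particle
enum_label_prob <- function(order, m, p_f) {
  outcomes <- expand.grid(rep(list(c(0, 1)), order))
  w <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p_f, 1 - p_f)))
  sum(w[rowSums(outcomes) == m])
}

# enumeration-based forward model: observed step fractions among visible
# particles for a truth vector, without using observation_matrix()
enum_forward <- function(fractions, p_f) {
  n_max <- length(fractions)
  r <- vapply(seq_len(n_max), function(m) {
    sum(vapply(seq_len(n_max), function(i) {
      if (m > i) 0 else fractions[i] * enum_label_prob(i, m, p_f)
    }, numeric(1)))
  }, numeric(1))
  r / sum(r)
}

# one-to-one greedy matching of detections to ground-truth positions
match_detections <- function(truth, spots, radius = 2) {
  if (nrow(truth) == 0 || nrow(spots) == 0) {
    return(list(recall = 0, precision = 0))
  }
  d <- sqrt(outer(truth$row, spots$row, "-")^2 +
              outer(truth$col, spots$col, "-")^2)
  mt <- rep(FALSE, nrow(truth))
  ms <- rep(FALSE, nrow(spots))
  for (k in order(d)) {
    if (d[k] > radius) break
    i <- (k - 1) %% nrow(truth) + 1
    j <- (k - 1) %/% nrow(truth) + 1
    if (!mt[i] && !ms[j]) {
      mt[i] <- TRUE
      ms[j] <- TRUE
    }
  }
  list(recall = mean(mt), precision = mean(ms))
}

# drop positions within `margin` px of the image border
interior_only <- function(tbl, shape, margin = 8) {
  tbl[tbl$row > margin & tbl$row <= shape[1] - margin &
        tbl$col > margin & tbl$col <= shape[2] - margin, ]
}
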
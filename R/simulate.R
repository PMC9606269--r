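#' Simulation configuration for synthetic TIRF photobleaching movies
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' Defaults describe the imaging regime the package targets: paraformaldehyde-
#' fixed cells (immobile particles), an EMCCD field of 512 x 512 px at
#' 0.107 um/px, 1000 frames at 50 ms/frame, per-subunit labeling efficiency
#' 0.8, and a sparse particle field at 0.22 particles/um^2. The default true
#' oligomer mix is mostly monomers and dimers with a small trimer/tetramer
#' tail, the regime in which incomplete-labeling correction matters most.
#'
#' @param true_fractions Probability vector over oligomer orders 1..n_max;
#'   non-negative, sums to 1.
#' @param labeling_efficiency Per-subunit labeling probability P_f in (0, 1].
#' @param n_particles Exact particle count to place; overrides
#'   `particle_density` when given.
#' @param particle_density Expected particles per um^2; the realized count is
#'   Poisson (complete spatial randomness).
#' @param image_shape Integer c(rows, cols) in pixels.
#' @param pixel_size Pixel pitch in um/px (default 0.107: a 16 um EMCCD pixel
#'   behind a 150x objective).
#' @param psf_sigma Gaussian PSF standard deviation in px.
#' @param unit_intensity Mean peak counts contributed per active fluorophore
#'   per frame.
#' @param background_level Constant background offset in counts.
#' @param read_noise_sd Gaussian read-noise standard deviation in counts.
#' @param em_gain_excess_factor Multiplier on shot variance approximating
#'   EMCCD excess noise (>= 1; 2 for a typical EM register).
#' @param shot_noise Add signal-dependent (shot-like) noise? Shot variance is
#'   `em_gain_excess_factor * (signal + background)`.
#' @param mean_bleach_time Mean single-fluorophore bleaching time in frames
#'   (exponential, memoryless; one irreversible bleach per fluorophore).
#' @param n_frames Number of frames in the movie.
#' @param frame_interval Frame interval in ms.
#' @param preacq_frames Number of leading low-excitation frames (cell search
#'   at low laser power) before the full-power upstroke; bleaching is
#'   negligible during this segment.
#' @param preacq_scale Signal scale during the pre-acquisition segment, in
#'   `[0, 1)`.
#' @param min_separation Optional hard-core minimum distance between particle
#'   centers in px (0 = pure Poisson placement).
#' @param n_max Largest oligomer order carried through the analysis.
#' @param seed Optional integer seed stored with the config and used by
#'   [simulate_movie()] when its own `seed` is NULL.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(true_fractions = c(0.435, 0.467, 0.049, 0.049, 0),
                       labeling_efficiency = 0.8,
                       n_particles = NULL,
                       particle_density = 0.22,
                       image_shape = c(512, 512),
                       pixel_size = 0.107,
                       psf_sigma = 1.3,
                       unit_intensity = 300,
                       background_level = 100,
                       read_noise_sd = 10,
                       em_gain_excess_factor = 2,
                       shot_noise = TRUE,
                       mean_bleach_time = 150,
                       n_frames = 1000,
                       frame_interval = 50,
                       preacq_frames = 0,
                       preacq_scale = 0.02,
                       min_separation = 0,
                       n_max = 5,
                       seed = NULL) {
  assert_fractions(true_fractions, what = "true_fractions")
  assert_probability(labeling_efficiency)
  if (length(true_fractions) != n_max) {
    abort("`true_fractions` must have length `n_max`.")
  }
  if (!is.null(n_particles) && n_particles < 0) {
    abort("`n_particles` must be >= 0.")
  }
  if (is.null(n_particles) &&
      (!is.numeric(particle_density) || particle_density < 0)) {
    abort("`particle_density` must be >= 0.")
  }
  if (length(image_shape) != 2 || any(image_shape < 8)) {
    abort("`image_shape` must be c(rows, cols) with both >= 8.")
  }
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  if (psf_sigma <= 0) abort("`psf_sigma` must be > 0.")
  if (n_frames < 1) abort("`n_frames` must be >= 1.")
  if (mean_bleach_time <= 0) abort("`mean_bleach_time` must be > 0.")
  if (em_gain_excess_factor < 1) abort("`em_gain_excess_factor` must be >= 1.")
  if (preacq_scale < 0 || preacq_scale >= 1) {
    abort("`preacq_scale` must be in [0, 1).")
  }
  if (preacq_frames < 0 || preacq_frames >= n_frames) {
    abort("`preacq_frames` must be in [0, n_frames).")
  }
  structure(
    list(
      true_fractions = true_fractions,
      labeling_efficiency = labeling_efficiency,
      n_particles = n_particles,
      particle_density = particle_density,
      image_shape = as.integer(image_shape),
      pixel_size = pixel_size,
      psf_sigma = psf_sigma,
      unit_intensity = unit_intensity,
      background_level = background_level,
      read_noise_sd = read_noise_sd,
      em_gain_excess_factor = em_gain_excess_factor,
      shot_noise = shot_noise,
      mean_bleach_time = mean_bleach_time,
      n_frames = as.integer(n_frames),
      frame_interval = frame_interval,
      preacq_frames = as.integer(preacq_frames),
      preacq_scale = preacq_scale,
      min_separation = min_separation,
      n_max = as.integer(n_max),
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  area <- prod(x$image_shape) * x$pixel_size^2
  cat("Synthetic TIRF simulation config\n")
  cat(sprintf("  field: %d x %d px (%.1f um^2), %d frames @ %g ms\n",
              x$image_shape[1], x$image_shape[2], area, x$n_frames,
              x$frame_interval))
  cat(sprintf("  particles: %s, P_f = %g, orders 1..%d, fractions (%s)\n",
              if (is.null(x$n_particles))
                sprintf("%.3g /um^2", x$particle_density)
              else sprintf("n = %d", x$n_particles),
              x$labeling_efficiency, x$n_max,
              paste(signif(x$true_fractions, 3), collapse = ", ")))
  cat(sprintf("  optics: psf sigma %g px, unit %g counts, bg %g, read sd %g, EM excess %g\n",
              x$psf_sigma, x$unit_intensity, x$background_level,
              x$read_noise_sd, x$em_gain_excess_factor))
  invisible(x)
}

#' Draw true oligomer orders from a particle-fraction distribution
#'
#' @param fractions Probability vector over orders 1..n_max.
#' @param n Number of particles to draw.
#' @param seed Optional integer seed.
#' @return Integer vector of orders, length `n`.
#' @export
sample_orders <- function(fractions, n, seed = NULL) {
  assert_fractions(fractions, what = "fractions")
  if (n < 0) abort("`n` must be >= 0.")
  if (n == 0) return(integer(0))
  with_seed_if(seed,
    sample.int(length(fractions), size = n, replace = TRUE, prob = fractions))
}

#' Apply stochastic incomplete labeling to a set of particles
#'
#' Each subunit of each particle independently carries a functional
#' fluorophore with probability `p_f`, so the labeled count of an order-N
#' particle is Binomial(N, p_f). Particles with zero labeled subunits are
#' invisible in the movie but kept in the ground truth.
#'
#' @param orders Integer vector of true oligomer orders (each >= 1).
#' @param p_f Per-subunit labeling efficiency in (0, 1].
#' @param seed Optional integer seed.
#' @return Integer vector of labeled counts, same length as `orders`.
#' @export
apply_labeling <- function(orders, p_f, seed = NULL) {
  assert_probability(p_f, "p_f")
  if (length(orders) && any(orders < 1)) abort("`orders` must all be >= 1.")
  with_seed_if(seed, rbinom(length(orders), size = orders, prob = p_f))
}

# exponential bleach frames, 1-based, measured from the end of the
# pre-acquisition segment; values > n_frames mean "never bleached on record"
sample_bleach_frames <- function(labeled_count, cfg, seed = NULL) {
  with_seed_if(seed, {
    t <- rexp(labeled_count, rate = 1 / cfg$mean_bleach_time)
    cfg$preacq_frames + ceiling(t)
  })
}

# active-fluorophore count for frames 1..n_frames given bleach frames:
# a fluorophore emits through its bleach frame and is dark afterwards
active_counts <- function(bleach_frames, n_frames) {
  k <- length(bleach_frames)
  if (k == 0) return(integer(n_frames))
  counts <- integer(n_frames)
  for (b in bleach_frames) {
    last <- min(b, n_frames)
    if (last >= 1) counts[seq_len(last)] <- counts[seq_len(last)] + 1L
  }
  counts
}

#' Simulate a single-particle photobleaching intensity trace
#'
#' Generates the per-frame intensity of one particle carrying
#' `labeled_count` fluorophores: a piecewise-constant staircase
#' `active * unit_intensity + background_level`, with each fluorophore
#' bleaching irreversibly at an exponential time, an optional low-excitation
#' pre-acquisition segment (producing the characteristic upstroke when the
#' laser reaches full power), and optional shot-like plus Gaussian read
#' noise.
#'
#' @param labeled_count Number of active fluorophores at the start (>= 0).
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @param bleach_frames Optional pre-drawn bleach frames (length
#'   `labeled_count`); drawn from the exponential model when NULL.
#' @return A tibble with columns `frame`, `intensity`, and `n_active` (the
#'   noiseless ground-truth fluorophore count per frame).
#' @export
simulate_trace <- function(labeled_count, cfg = sim_config(), seed = NULL,
                           bleach_frames = NULL) {
  if (labeled_count < 0) abort("`labeled_count` must be >= 0.")
  with_seed_if(seed, {
    if (is.null(bleach_frames)) {
      bleach_frames <- sample_bleach_frames(labeled_count, cfg)
    }
    act <- active_counts(bleach_frames, cfg$n_frames)
    scale <- rep(1, cfg$n_frames)
    if (cfg$preacq_frames > 0) scale[seq_len(cfg$preacq_frames)] <- cfg$preacq_scale
    signal <- act * cfg$unit_intensity * scale + cfg$background_level
    noise_var <- rep(0, cfg$n_frames)
    if (isTRUE(cfg$shot_noise)) {
      noise_var <- noise_var + cfg$em_gain_excess_factor * pmax(signal, 0)
    }
    noise_var <- noise_var + cfg$read_noise_sd^2
    intensity <- signal
    if (any(noise_var > 0)) {
      intensity <- intensity + rnorm(cfg$n_frames, sd = sqrt(noise_var))
    }
    tibble(frame = seq_len(cfg$n_frames), intensity = intensity,
           n_active = act)
  })
}

# hard-core or fully random uniform placement of n points on the image
sample_positions <- function(n, shape, min_separation) {
  rmin <- 0.5
  rows <- shape[1]; cols <- shape[2]
  if (min_separation <= 0) {
    return(cbind(row = runif(n, rmin, rows + 0.5),
                 col = runif(n, rmin, cols + 0.5)))
  }
  pos <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  placed <- 0
  tries <- 0
  max_tries <- 200 * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1
    cand <- c(runif(1, rmin, rows + 0.5), runif(1, rmin, cols + 0.5))
    if (placed == 0 ||
        min((pos[seq_len(placed), 1] - cand[1])^2 +
            (pos[seq_len(placed), 2] - cand[2])^2) >= min_separation^2) {
      placed <- placed + 1
      pos[placed, ] <- cand
    }
  }
  if (placed < n) {
    warn(sprintf(
      "Hard-core placement saturated: placed %d of %d particles at min_separation %.2g px.",
      placed, n, min_separation))
    pos <- pos[seq_len(placed), , drop = FALSE]
  }
  pos
}

#' Simulate a full synthetic TIRF movie with ground truth
#'
#' Places immobile particles in the field (Poisson at the requested density,
#' or an exact count), draws true orders and labeled counts, renders each
#' active fluorophore as a 2D Gaussian PSF while it survives, applies the
#' optional pre-acquisition scaling and camera noise, and returns both the
#' movie and the complete ground-truth table.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (falls back to `cfg$seed`).
#' @return A list of class `pb_simulation` with elements `movie` (a
#'   [movie_stack()]), `truth` (tibble: particle_id, true_order,
#'   labeled_count, row, col, bleach_frames as semicolon-joined integers,
#'   visible), `realized_density` (particles/um^2) and `config`.
#' @export
simulate_movie <- function(cfg = sim_config(), seed = NULL) {
  if (is.null(seed)) seed <- cfg$seed
  with_seed_if(seed, {
    shape <- cfg$image_shape
    area_um2 <- prod(shape) * cfg$pixel_size^2
    n <- if (!is.null(cfg$n_particles)) cfg$n_particles
         else rpois(1, cfg$particle_density * area_um2)

    orders <- sample_orders(cfg$true_fractions, n)
    labeled <- apply_labeling(orders, cfg$labeling_efficiency)
    pos <- sample_positions(n, shape, cfg$min_separation)
    if (nrow(pos) < n) {  # hard-core saturation trimmed the population
      n <- nrow(pos)
      orders <- orders[seq_len(n)]
      labeled <- labeled[seq_len(n)]
    }
    bleach <- purrr::map(labeled, sample_bleach_frames, cfg = cfg)

    sig <- array(0, dim = c(shape[1], shape[2], cfg$n_frames))
    w <- ceiling(4 * cfg$psf_sigma)
    for (p in seq_len(n)) {
      if (labeled[p] == 0) next
      r0 <- pos[p, 1]; c0 <- pos[p, 2]
      rw <- max(1, round(r0) - w):min(shape[1], round(r0) + w)
      cw <- max(1, round(c0) - w):min(shape[2], round(c0) + w)
      patch <- cfg$unit_intensity *
        exp(-(outer((rw - r0)^2, (cw - c0)^2, "+")) / (2 * cfg$psf_sigma^2))
      # piecewise-constant active count: add the patch once per survival epoch
      bf <- sort(bleach[[p]])
      starts <- c(1L, pmin(bf, cfg$n_frames) + 1L)
      ends <- c(pmin(bf, cfg$n_frames), cfg$n_frames)
      n_act <- labeled[p]:0
      for (s in seq_along(starts)) {
        if (n_act[s] > 0 && starts[s] <= ends[s]) {
          fr <- starts[s]:ends[s]
          # patch recycles across the frame dimension of the slice
          sig[rw, cw, fr] <- sig[rw, cw, fr] + c(patch) * n_act[s]
        }
      }
    }
    if (cfg$preacq_frames > 0) {
      pre <- seq_len(cfg$preacq_frames)
      sig[, , pre] <- sig[, , pre] * cfg$preacq_scale
    }
    sig <- sig + cfg$background_level
    if (isTRUE(cfg$shot_noise) || cfg$read_noise_sd > 0) {
      npx <- prod(shape)
      for (f in seq_len(cfg$n_frames)) {
        v <- cfg$read_noise_sd^2
        fr <- sig[, , f]
        nv <- if (isTRUE(cfg$shot_noise))
          cfg$em_gain_excess_factor * pmax(fr, 0) + v else v
        if (any(nv > 0)) sig[, , f] <- fr + rnorm(npx, sd = sqrt(nv))
      }
    }

    truth <- tibble(
      particle_id = seq_len(n),
      true_order = as.integer(orders),
      labeled_count = as.integer(labeled),
      row = pos[, 1],
      col = pos[, 2],
      bleach_frames = purrr::map_chr(bleach, ~ paste(sort(.x), collapse = ";")),
      visible = labeled > 0
    )
    structure(
      list(
        movie = movie_stack(sig, pixel_size = cfg$pixel_size,
                            frame_interval = cfg$frame_interval),
        truth = truth,
        realized_density = n / area_um2,
        config = cfg
      ),
      class = "pb_simulation"
    )
  })
}

#' @export
print.pb_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic photobleaching movie: %d particles (%.3g /um^2, %d visible)\n",
    nrow(x$truth), x$realized_density, sum(x$truth$visible)))
  print(x$movie)
  invisible(x)
}

#' Summarise ground-truth particle fractions
#'
#' @param truth Ground-truth tibble from [simulate_movie()].
#' @param n_max Largest order.
#' @return Tibble with columns `order`, `n`, `fraction`.
#' @export
truth_fractions <- function(truth, n_max = 5) {
  n_by <- tabulate(truth$true_order, nbins = n_max)
  tibble(order = seq_len(n_max), n = n_by,
         fraction = if (sum(n_by) > 0) n_by / sum(n_by) else rep(0, n_max))
}
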
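# ---- a trous B3-spline wavelet transform ------------------------------------

# whole-sample mirror reflection of indices onto 1..n
reflect_idx <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  i <- abs(i - 1) %% (2 * (n - 1)) + 1
  ifelse(i > n, 2L * n - i, as.integer(i))
}

B3_KERNEL <- c(1, 4, 6, 4, 1) / 16

# separable B3 smoothing with holes of size `step`, mirror boundary
b3_smooth <- function(m, step) {
  nr <- nrow(m); nc <- ncol(m)
  offs <- (-2:2) * step
  out <- matrix(0, nr, nc)
  for (k in seq_along(offs)) {
    out <- out + B3_KERNEL[k] * m[reflect_idx(seq_len(nr) + offs[k], nr), ,
                                  drop = FALSE]
  }
  m2 <- matrix(0, nr, nc)
  for (k in seq_along(offs)) {
    m2 <- m2 + B3_KERNEL[k] * out[, reflect_idx(seq_len(nc) + offs[k], nc),
                                  drop = FALSE]
  }
  m2
}

#' Undecimated a trous wavelet decomposition of an image
#'
#' Decomposes an image into `n_levels` wavelet detail planes plus a smooth
#' residual using the B3-spline "a trous" (with holes) scheme: at level j the
#' separable kernel (1,4,6,4,1)/16 is applied with holes of size 2^(j-1), and
#' the detail plane is the difference of successive smooths. The planes and
#' the final smooth sum back to the original image exactly, and
#' diffraction-limited spots concentrate in the level matching the PSF scale
#' (level 2 for a sigma ~1.3 px PSF).
#'
#' @param image Numeric matrix (at least 8 x 8).
#' @param n_levels Number of detail levels (>= 1, default 3).
#' @return List with `planes` (list of detail matrices, finest first) and
#'   `smooth` (the residual low-pass plane).
#' @export
atrous_decompose <- function(image, n_levels = 3) {
  if (!is.matrix(image) || any(dim(image) < 8)) {
    abort("`image` must be a numeric matrix of at least 8 x 8 pixels.")
  }
  if (n_levels < 1) abort("`n_levels` must be >= 1.")
  planes <- vector("list", n_levels)
  current <- image
  for (j in seq_len(n_levels)) {
    smoothed <- b3_smooth(current, step = 2^(j - 1))
    planes[[j]] <- current - smoothed
    current <- smoothed
  }
  list(planes = planes, smooth = current)
}

#' Wavelet spot filter: detail planes plus a significance mask
#'
#' Runs [atrous_decompose()] and hard-thresholds the spot-scale detail plane
#' at `k_sigma` times a robust (MAD-based) noise estimate, producing the
#' binary detection mask used by [find_candidates()]. A constant image yields
#' an empty mask.
#'
#' @param image Numeric matrix.
#' @param n_levels Number of wavelet levels (default 3).
#' @param k_sigma Threshold multiplier on the per-plane robust noise sigma
#'   (default 3).
#' @param detect_level Detail plane used for detection (default 2, the
#'   diffraction-limited spot scale; clamped to `n_levels`).
#' @return List with `planes`, `smooth`, `filtered` (the detection plane),
#'   `mask` (logical matrix), `sigma` (per-plane robust noise estimates) and
#'   `detect_level`.
#' @export
atrous_filter <- function(image, n_levels = 3, k_sigma = 3, detect_level = 2) {
  dec <- atrous_decompose(image, n_levels)
  detect_level <- min(detect_level, n_levels)
  sigma <- purrr::map_dbl(dec$planes, ~ mad(.x, center = 0))
  filtered <- dec$planes[[detect_level]]
  mask <- filtered > k_sigma * sigma[detect_level] & filtered > 0
  c(dec, list(filtered = filtered, mask = mask, sigma = sigma,
              detect_level = detect_level))
}

# ---- candidate finding and Gaussian refinement ------------------------------

local_maxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  res <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (m >= pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  res
}

#' Find spot candidates on a filtered plane
#'
#' Local maxima of the wavelet detection plane lying inside the significance
#' mask, greedily pruned so that no two candidates are closer than
#' `min_separation` px (the brighter one wins; exact ties resolve in
#' row-major order).
#'
#' @param filtered Detection plane (matrix) from [atrous_filter()].
#' @param mask Logical significance mask of the same shape.
#' @param min_separation Minimum candidate spacing in px (>= 1, default 2).
#' @return Tibble with columns `row`, `col` (integer pixel coordinates,
#'   1-based) and `value` (filtered-plane intensity), ordered bright-first.
#' @export
find_candidates <- function(filtered, mask, min_separation = 2) {
  if (min_separation < 1) abort("`min_separation` must be >= 1.")
  hit <- which(local_maxima(filtered) & mask, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble(row = integer(0), col = integer(0), value = numeric(0)))
  }
  cand <- tibble(row = as.integer(unname(hit[, 1])),
                 col = as.integer(unname(hit[, 2])),
                 value = unname(filtered[hit])) %>%
    arrange(dplyr::desc(.data$value), .data$row, .data$col)
  keep <- logical(nrow(cand))
  kr <- numeric(0); kc <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kr) == 0 ||
        min((kr - cand$row[i])^2 + (kc - cand$col[i])^2) >= min_separation^2) {
      keep[i] <- TRUE
      kr <- c(kr, cand$row[i]); kc <- c(kc, cand$col[i])
    }
  }
  cand[keep, ]
}

#' Refine a spot candidate with a 2D Gaussian least-squares fit
#'
#' Fits `amplitude * exp(-((r-r0)^2+(c-c0)^2)/(2 sigma^2)) + background` over
#' a square window around the candidate pixel (Levenberg-Marquardt), giving
#' sub-pixel localization plus amplitude and local background. The fitted
#' sigma is constrained to `sigma_bounds` to reject clumps, and the center
#' may move at most 2 px from the candidate. Candidates whose window leaves
#' the image, or fits that fail, are returned flagged `converged = FALSE`.
#'
#' @param image Numeric matrix (one frame).
#' @param row,col Candidate pixel (1-based).
#' @param half_window Half-size of the fit window in px (default 4).
#' @param sigma_init Initial PSF sigma in px (default 1.3).
#' @param sigma_bounds Allowed sigma range (default c(0.5, 3)).
#' @return One-row tibble: `row`, `col` (sub-pixel), `amplitude`,
#'   `background`, `sigma`, `fit_rss`, `converged`.
#' @export
fit_gaussian <- function(image, row, col, half_window = 4, sigma_init = 1.3,
                         sigma_bounds = c(0.5, 3)) {
  row <- unname(row); col <- unname(col)
  nr <- nrow(image); nc <- ncol(image)
  failed <- function() tibble(row = as.numeric(row), col = as.numeric(col),
                              amplitude = NA_real_, background = NA_real_,
                              sigma = NA_real_, fit_rss = NA_real_,
                              converged = FALSE)
  if (row - half_window < 1 || row + half_window > nr ||
      col - half_window < 1 || col + half_window > nc) {
    return(failed())
  }
  rw <- (row - half_window):(row + half_window)
  cw <- (col - half_window):(col + half_window)
  z <- image[rw, cw]
  rr <- matrix(rw, length(rw), length(cw))
  cc <- matrix(cw, length(rw), length(cw), byrow = TRUE)
  bg0 <- min(z)
  amp0 <- max(z[half_window + 1, half_window + 1] - bg0, 1e-6)
  start <- c(amp = amp0, r0 = row, c0 = col, sigma = sigma_init, bg = bg0)
  resid_fn <- function(p) {
    as.vector(z - (p[1] * exp(-((rr - p[2])^2 + (cc - p[3])^2) /
                                (2 * p[4]^2)) + p[5]))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      lower = c(0, row - 2, col - 2, sigma_bounds[1], -Inf),
      upper = c(Inf, row + 2, col + 2, sigma_bounds[2], Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% c(1, 2, 3, 4)) return(failed())
  p <- fit$par
  tibble(row = p[["r0"]], col = p[["c0"]], amplitude = p[["amp"]],
         background = p[["bg"]], sigma = p[["sigma"]],
         fit_rss = sum(fit$fvec^2), converged = TRUE)
}

# render the fitted Gaussians of a spot table into an image-sized model
render_spot_model <- function(dims, fits) {
  out <- matrix(0, dims[1], dims[2])
  for (i in seq_len(nrow(fits))) {
    r0 <- fits$row[i]; c0 <- fits$col[i]
    s <- fits$sigma[i]; a <- fits$amplitude[i]
    # wide support: truncating too early leaves residual rings that the
    # second detection pass would mistake for real emitters
    w <- ceiling(7 * s)
    rw <- max(1, round(r0) - w):min(dims[1], round(r0) + w)
    cw <- max(1, round(c0) - w):min(dims[2], round(c0) + w)
    out[rw, cw] <- out[rw, cw] +
      a * exp(-(outer((rw - r0)^2, (cw - c0)^2, "+")) / (2 * s^2))
  }
  out
}

# refit one spot on the image minus the model of all other spots,
# in a window around its current position
refit_on_partial <- function(img, fits, i, half_window, sigma_init,
                             sigma_bounds) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- round(fits$row[i]); c0 <- round(fits$col[i])
  if (r0 - half_window < 1 || r0 + half_window > nr ||
      c0 - half_window < 1 || c0 + half_window > nc) {
    return(fits[i, ])
  }
  others <- fits[-i, ]
  near <- which(abs(others$row - r0) <= half_window + 6 &
                  abs(others$col - c0) <= half_window + 6)
  partial <- img
  if (length(near) > 0) {
    rw <- (r0 - half_window):(r0 + half_window)
    cw <- (c0 - half_window):(c0 + half_window)
    model <- matrix(0, length(rw), length(cw))
    for (j in near) {
      model <- model + others$amplitude[j] *
        exp(-(outer((rw - others$row[j])^2, (cw - others$col[j])^2, "+")) /
              (2 * others$sigma[j]^2))
    }
    partial[rw, cw] <- partial[rw, cw] - model
  }
  ref <- fit_gaussian(partial, r0, c0, half_window, sigma_init, sigma_bounds)
  if (isTRUE(ref$converged)) {
    fits[i, c("row", "col", "amplitude", "background", "sigma",
              "fit_rss")] <-
      ref[, c("row", "col", "amplitude", "background", "sigma", "fit_rss")]
  }
  fits[i, ]
}

# cyclic refinement: refit spots that have a neighbor close enough to
# contaminate their window (isolated fits are already optimal), brightest
# first so the dominant emitter claims shared flux; prune and merge between
# cycles so flux-sharing ghost pairs collapse onto one emitter
refine_fits <- function(img, fits, half_window, sigma_init, sigma_bounds,
                        amp_min, merge_radius, cycles = 2) {
  reach <- 2 * half_window + 2
  for (cyc in seq_len(cycles)) {
    if (nrow(fits) < 2) break
    d2 <- as.matrix(stats::dist(cbind(fits$row, fits$col)))^2
    diag(d2) <- Inf
    crowded <- which(apply(d2, 1, min) <= reach^2)
    crowded <- crowded[order(-fits$amplitude[crowded])]
    for (i in crowded) {
      fits[i, ] <- refit_on_partial(img, fits, i, half_window, sigma_init,
                                    sigma_bounds)
    }
    fits <- fits[fits$amplitude >= amp_min, ]
    fits <- merge_close_fits(fits, merge_radius)
  }
  fits
}

# merge fits closer than `radius` px, keeping the brighter one
merge_close_fits <- function(fits, radius) {
  if (nrow(fits) < 2) return(fits)
  repeat {
    d2 <- as.matrix(stats::dist(cbind(fits$row, fits$col)))^2
    diag(d2) <- Inf
    k <- which.min(d2)
    if (d2[k] >= radius^2) break
    i <- (k - 1) %% nrow(fits) + 1
    j <- (k - 1) %/% nrow(fits) + 1
    drop <- if (fits$amplitude[i] >= fits$amplitude[j]) j else i
    fits <- fits[-drop, ]
    if (nrow(fits) < 2) break
  }
  fits
}

#' Detect diffraction-limited spots in movie frames
#'
#' Full per-frame detection: a trous wavelet filtering and thresholding
#' ([atrous_filter()]), candidate maxima ([find_candidates()]), and sub-pixel
#' 2D Gaussian refinement ([fit_gaussian()]), followed by an iterative
#' matching-pursuit stage that recovers emitters missed in crowded regions
#' and deconvolves semi-overlapping neighbors by refitting each spot on the
#' image minus the others' models. Converged fits below `min_amplitude` (by
#' default the larger of `k_sigma` times a robust image-noise estimate and a
#' fifth of the lower-quartile fitted amplitude) are dropped as noise.
#'
#' @param movie A [movie_stack()] (or a plain matrix for one frame).
#' @param frames Frame indices to process (default 1).
#' @param n_levels,k_sigma,detect_level Wavelet parameters, see
#'   [atrous_filter()].
#' @param min_separation Candidate spacing in px.
#' @param half_window,sigma_init,sigma_bounds Fit parameters, see
#'   [fit_gaussian()].
#' @param min_amplitude Minimum accepted fitted amplitude; NULL = automatic.
#' @param refine Iteratively improve the fit set (default TRUE): detect
#'   additional emitters on the model residual, cyclically refit every spot
#'   on the image minus its neighbors' models (deconvolving semi-overlapping
#'   particles), prune fits falling below the amplitude floor, and merge
#'   fits closer than `merge_radius`.
#' @param refine_passes Number of residual-detection passes (default 2).
#' @param merge_radius Minimum final spot separation in px; closer fits are
#'   merged keeping the brighter (default 2, about the two-point
#'   resolution limit of the fit).
#' @param exclude_overlaps Discard accepted spots whose centers lie within
#'   `3 * sigma_init` of another accepted spot in the same frame (the
#'   "isolated molecule" rule; default FALSE, applied instead at trace QC).
#' @return Spot table tibble: `frame`, `row`, `col`, `amplitude`,
#'   `background`, `sigma`, `fit_rss`, `converged`.
#' @export
detect_spots <- function(movie, frames = 1, n_levels = 3, k_sigma = 3,
                         detect_level = 2, min_separation = 2,
                         half_window = 3, sigma_init = 1.3,
                         sigma_bounds = c(0.5, 3), min_amplitude = NULL,
                         refine = TRUE, refine_passes = 2,
                         merge_radius = 2, exclude_overlaps = FALSE) {
  if (is.matrix(movie)) movie <- movie_stack(movie)
  # white-noise gain of the level-1 detail plane (delta minus B3xB3 kernel),
  # used to convert the plane's MAD sigma into a raw-image noise sd
  w1_gain <- sqrt(1 - 2 * B3_KERNEL[3]^2 + sum(outer(B3_KERNEL, B3_KERNEL)^2))
  out <- purrr::map(frames, function(f) {
    img <- get_frame(movie, f)
    filt <- atrous_filter(img, n_levels, k_sigma, detect_level)
    cand <- find_candidates(filt$filtered, filt$mask, min_separation)
    if (nrow(cand) == 0) return(NULL)
    fits <- purrr::map2(cand$row, cand$col, function(r, c) {
      fit_gaussian(img, r, c, half_window, sigma_init, sigma_bounds)
    }) %>% bind_rows() %>% mutate(frame = f, .before = 1)
    amp_min <- if (is.null(min_amplitude)) {
      # noise floor, plus a population floor (a fifth of the lower-quartile
      # amplitude) that rejects tail-saddle artifacts on low-noise data
      amps <- fits$amplitude[fits$converged]
      floor_pop <- if (length(amps) > 0) {
        0.2 * stats::quantile(amps, 0.25, names = FALSE)
      } else 0
      max(k_sigma * filt$sigma[1] / w1_gain, floor_pop)
    } else min_amplitude
    fits <- fits %>%
      filter(.data$converged, .data$amplitude >= amp_min,
             .data$row >= 1, .data$row <= nrow(img),
             .data$col >= 1, .data$col <= ncol(img))
    if (refine && nrow(fits) > 0) {
      # emitters added from the residual must clear a stricter 5-sigma
      # amplitude bar: at the 3-sigma detection level the residual of a
      # well-fit field still yields occasional noise candidates
      add_min <- max(amp_min, 5 * filt$sigma[1] / w1_gain)
      for (pass in seq_len(refine_passes)) {
        resid <- img - render_spot_model(dim(img), fits)
        filt_r <- atrous_filter(resid, n_levels, k_sigma, detect_level)
        cand_r <- find_candidates(filt_r$filtered, filt_r$mask,
                                  min_separation = 1)
        added <- 0L
        for (ci in seq_len(nrow(cand_r))) {
          d2 <- (fits$row - cand_r$row[ci])^2 + (fits$col - cand_r$col[ci])^2
          if (min(d2) < 1) next  # same emitter as an existing fit
          nf <- fit_gaussian(resid, cand_r$row[ci], cand_r$col[ci],
                             half_window, sigma_init, sigma_bounds)
          if (isTRUE(nf$converged) && nf$amplitude >= add_min) {
            fits <- bind_rows(fits, nf %>% mutate(frame = f))
            added <- added + 1L
          }
        }
        fits <- refine_fits(img, fits, half_window, sigma_init, sigma_bounds,
                            amp_min, merge_radius)
        if (added == 0L) break
      }
      fits <- fits %>% arrange(.data$row, .data$col)
    }
    if (exclude_overlaps && nrow(fits) > 1) {
      d2 <- as.matrix(stats::dist(cbind(fits$row, fits$col)))^2
      diag(d2) <- Inf
      fits <- fits[apply(d2, 1, min) >= (3 * sigma_init)^2, ]
    }
    fits
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(frame = integer(0), row = numeric(0), col = numeric(0),
                  amplitude = numeric(0), background = numeric(0),
                  sigma = numeric(0), fit_rss = numeric(0),
                  converged = logical(0))
  }
  res
}

#' Particle density from a spot table
#'
#' @param spots Spot table (typically first-frame detections from
#'   [detect_spots()]).
#' @param fov_area Field-of-view area in um^2 (see [fov_area()]).
#' @return Particles per um^2.
#' @export
spot_density <- function(spots, fov_area) {
  if (!is.numeric(fov_area) || fov_area <= 0) {
    abort("`fov_area` must be > 0.")
  }
  sum(spots$converged) / fov_area
}
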
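# best single split of x[lo..hi]: returns c(gain, k) where k is the last
# index of the left part; gain is the RSS reduction of the split
best_split <- function(cs, lo, hi) {
  n <- hi - lo + 1
  if (n < 2) return(c(0, NA))
  seg_sum <- cs[hi + 1] - cs[lo]
  k <- lo:(hi - 1)
  n1 <- k - lo + 1
  n2 <- n - n1
  s1 <- cs[k + 1] - cs[lo]
  gain <- s1^2 / n1 + (seg_sum - s1)^2 / n2 - seg_sum^2 / n
  i <- which.max(gain)
  c(gain[i], k[i])
}

#' Count photobleaching steps in an intensity trace
#'
#' Fits a piecewise-constant model to a background-subtracted trace by
#' greedy binary segmentation: change points are inserted one at a time where
#' they most reduce the residual sum of squares, and insertion stops when the
#' reduction falls below `penalty` times a robust noise-variance estimate
#' (MAD of first differences). Adjacent plateaus closer than `min_step` are
#' then merged, and the number of photobleaching steps is the number of
#' strictly decreasing level transitions. Traces retaining any upward
#' transition after merging (blinking, aggregation) or with no downward step
#' are flagged not accepted. Noiseless traces are segmented exactly.
#'
#' @param trace Numeric intensity vector, or a tibble with an `intensity`
#'   column.
#' @param penalty Penalty per change point in units of the noise variance;
#'   default `2 * log(n)` (BIC-like).
#' @param min_step Minimum plateau separation retained as a real step, in
#'   intensity counts (default 0: no merging). In the pipeline this is set to
#'   half the estimated single-fluorophore intensity.
#' @param noise_sd Noise standard deviation; estimated robustly when NULL.
#' @param max_changepoints Safety cap on inserted change points.
#' @return One-row tibble: `n_steps`, `accepted`, `n_changepoints`,
#'   `change_points` (semicolon-joined first frames of each new plateau),
#'   `levels` (semicolon-joined plateau means), `last_step_height`,
#'   `noise_sd`, `score` (residual sum of squares of the final fit).
#' @export
count_steps <- function(trace, penalty = NULL, min_step = 0,
                        noise_sd = NULL, max_changepoints = 12) {
  x <- if (is.data.frame(trace)) trace$intensity else as.numeric(trace)
  n <- length(x)
  if (n == 0) abort("`trace` is empty.")
  if (is.null(penalty)) penalty <- 2 * log(n)
  if (is.null(noise_sd)) {
    noise_sd <- mad(diff(x)) / sqrt(2)
  }

  scale0 <- max(abs(x), 1)
  if (noise_sd <= 1e-10 * scale0) {
    # noiseless: every (non-floating-point-jitter) change is a change point
    cp <- which(abs(diff(x)) > 1e-9 * scale0)
    bounds <- c(0, cp, n)
  } else {
    cs <- c(0, cumsum(x))
    bounds <- c(0, n)           # segment boundaries (end indices)
    repeat {
      if (length(bounds) - 1 >= max_changepoints + 1) break
      best <- c(0, NA); where <- NA
      for (s in seq_len(length(bounds) - 1)) {
        sp <- best_split(cs, bounds[s] + 1, bounds[s + 1])
        if (!is.na(sp[2]) && sp[1] > best[1]) { best <- sp; where <- s }
      }
      if (is.na(where) || best[1] <= penalty * noise_sd^2) break
      bounds <- sort(c(bounds, best[2]))
    }
  }

  seg_mean <- function(b) {
    purrr::map_dbl(seq_len(length(b) - 1),
                   ~ mean(x[(b[.x] + 1):b[.x + 1]]))
  }
  levels <- seg_mean(bounds)
  # merge adjacent plateaus closer than min_step (smallest gap first)
  if (min_step > 0 && length(levels) > 1) {
    repeat {
      gaps <- abs(diff(levels))
      if (all(gaps >= min_step)) break
      j <- which.min(gaps)
      bounds <- bounds[-(j + 1)]
      levels <- seg_mean(bounds)
      if (length(levels) == 1) break
    }
  }

  drops <- diff(levels)
  n_steps <- sum(drops < 0)
  upward <- any(drops > 0)
  rss <- sum((x - rep(levels, diff(bounds)))^2)
  tibble(
    n_steps = as.integer(n_steps),
    accepted = n_steps >= 1 && !upward,
    n_changepoints = length(bounds) - 2L,
    change_points = paste(bounds[c(-1, -length(bounds))] + 1L,
                          collapse = ";"),
    levels = paste(signif(levels, 8), collapse = ";"),
    last_step_height = if (n_steps >= 1)
      -drops[max(which(drops < 0))] else NA_real_,
    noise_sd = noise_sd,
    score = rss
  )
}

#' Fit steps in every trace of a trace table
#'
#' @param traces Trace tibble (`track_id`, `frame`, `intensity`).
#' @param ... Passed to [count_steps()].
#' @return Step-fit tibble with one row per track.
#' @export
count_steps_all <- function(traces, ...) {
  dots <- list(...)
  traces %>%
    group_by(.data$track_id) %>%
    dplyr::group_modify(function(.x, .y) {
      do.call(count_steps, c(list(.x$intensity), dots))
    }) %>%
    ungroup()
}

#' Estimate the single-fluorophore trace intensity
#'
#' The unit step is estimated as the median height of the *last* downward
#' step across traces — the drop to background, which is a single-fluorophore
#' bleach whatever the particle's stoichiometry.
#'
#' @param step_fits Step-fit tibble from [count_steps_all()].
#' @return The unit intensity estimate (counts), or NA if no usable fits.
#' @export
estimate_unit_intensity <- function(step_fits) {
  h <- step_fits$last_step_height[step_fits$n_steps >= 1]
  h <- h[is.finite(h)]
  if (length(h) == 0) return(NA_real_)
  median(h)
}

#' Two-pass step analysis of a trace set
#'
#' First pass fits every trace with no merging threshold to estimate the
#' unit (single-fluorophore) intensity from last-step heights; second pass
#' refits with `min_step = min_step_frac * unit`, suppressing noise-split
#' plateaus. This is the automated, deterministic replacement for manual
#' step scoring.
#'
#' @param traces Trace tibble (`track_id`, `frame`, `intensity`).
#' @param min_step_frac Merge threshold as a fraction of the unit intensity
#'   (default 0.5).
#' @param penalty Change-point penalty, see [count_steps()].
#' @return List with `step_fits` (tibble) and `unit_intensity` (counts).
#' @export
analyze_traces <- function(traces, min_step_frac = 0.5, penalty = NULL) {
  pass1 <- count_steps_all(traces, penalty = penalty)
  unit <- estimate_unit_intensity(pass1)
  fits <- if (is.finite(unit) && unit > 0) {
    count_steps_all(traces, penalty = penalty,
                    min_step = min_step_frac * unit)
  } else {
    pass1
  }
  list(step_fits = fits, unit_intensity = unit)
}

#' Aggregate accepted step fits into an observed step histogram
#'
#' @param step_fits Step-fit tibble from [count_steps_all()] or
#'   [analyze_traces()].
#' @param n_max Largest step number retained (default 5); accepted traces
#'   with more steps are excluded and counted in the `n_overflow` attribute.
#' @return Tibble with columns `m` (1..n_max) and `count`; attributes
#'   `total` (sum of counts) and `n_overflow`.
#' @export
aggregate_histogram <- function(step_fits, n_max = 5) {
  ok <- step_fits %>% filter(.data$accepted, .data$n_steps >= 1)
  overflow <- sum(ok$n_steps > n_max)
  counts <- tabulate(ok$n_steps[ok$n_steps <= n_max], nbins = n_max)
  out <- tibble(m = seq_len(n_max), count = as.integer(counts))
  attr(out, "total") <- sum(counts)
  attr(out, "n_overflow") <- overflow
  out
}
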
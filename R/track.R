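#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbor frame-to-frame linking for (near-)stationary
#' particles: within each new frame, detection/track pairs are matched in
#' order of increasing displacement, links longer than `max_displacement` are
#' rejected, unmatched detections start new tracks, and a track survives up
#' to `max_gap` frames without a detection. Defaults (2 px, no gaps) reflect
#' fixed-cell imaging where particles do not move.
#'
#' @param spots Spot table from [detect_spots()] (converged rows are used).
#' @param max_displacement Maximum frame-to-frame displacement in px.
#' @param max_gap Maximum number of missed frames inside a track.
#' @return The spot table with a `track_id` column, ordered by track and
#'   frame.
#' @export
link_spots <- function(spots, max_displacement = 2, max_gap = 0) {
  spots <- spots %>% filter(.data$converged) %>% arrange(.data$frame)
  if (nrow(spots) == 0) {
    return(spots %>% mutate(track_id = integer(0)))
  }
  spots$track_id <- NA_integer_
  next_id <- 1L
  # active track state: id, row, col, last frame
  act_id <- integer(0); act_r <- numeric(0); act_c <- numeric(0)
  act_f <- integer(0)
  for (f in sort(unique(spots$frame))) {
    idx <- which(spots$frame == f)
    live <- which(f - act_f <= max_gap + 1L & f > act_f)
    if (length(live) > 0 && length(idx) > 0) {
      dr <- outer(act_r[live], spots$row[idx], "-")
      dc <- outer(act_c[live], spots$col[idx], "-")
      d2 <- dr^2 + dc^2
      ok <- which(d2 <= max_displacement^2)
      if (length(ok) > 0) {
        ord <- ok[order(d2[ok])]
        used_t <- logical(length(live)); used_d <- logical(length(idx))
        for (lin in ord) {
          ti <- (lin - 1L) %% length(live) + 1L
          di <- (lin - 1L) %/% length(live) + 1L
          if (used_t[ti] || used_d[di]) next
          used_t[ti] <- TRUE; used_d[di] <- TRUE
          tr <- live[ti]
          spots$track_id[idx[di]] <- act_id[tr]
          act_r[tr] <- spots$row[idx[di]]
          act_c[tr] <- spots$col[idx[di]]
          act_f[tr] <- f
        }
      }
    }
    new <- idx[is.na(spots$track_id[idx])]
    if (length(new) > 0) {
      ids <- next_id + seq_along(new) - 1L
      spots$track_id[new] <- ids
      act_id <- c(act_id, ids)
      act_r <- c(act_r, spots$row[new])
      act_c <- c(act_c, spots$col[new])
      act_f <- c(act_f, rep(f, length(new)))
      next_id <- next_id + length(new)
    }
  }
  spots %>% arrange(.data$track_id, .data$frame)
}

#' Summarise tracks into anchor positions
#'
#' The anchor of a track is the mean sub-pixel position of its detections;
#' for fixed particles this is the best estimate of the true position and is
#' used to extract the full-length intensity trace (including post-bleach
#' frames).
#'
#' @param tracks Linked spot table from [link_spots()].
#' @return Tibble: `track_id`, `row`, `col`, `start_frame`, `end_frame`,
#'   `n_detections`.
#' @export
track_anchors <- function(tracks) {
  tracks %>%
    group_by(.data$track_id) %>%
    summarise(row = mean(.data$row), col = mean(.data$col),
              start_frame = min(.data$frame), end_frame = max(.data$frame),
              n_detections = dplyr::n(), .groups = "drop")
}

# column medians via a single vectorized within-column sort (much faster
# than apply(x, 2, median) for the many small matrices used per track)
col_medians <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  xs <- matrix(x[order(col(x), x)], nr, nc)
  if (nr %% 2 == 1) xs[(nr + 1) / 2, ] else
    (xs[nr / 2, ] + xs[nr / 2 + 1, ]) / 2
}

disc_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

annulus_offsets <- function(inner, outer) {
  r <- ceiling(outer)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  d2 <- g$dr^2 + g$dc^2
  g[d2 >= inner^2 & d2 <= outer^2, , drop = FALSE]
}

#' Extract background-subtracted intensity traces at fixed anchors
#'
#' For every anchor, sums the counts in a disc of `aperture_radius` px around
#' the (rounded) anchor position in every frame and subtracts the median of a
#' surrounding annulus times the disc pixel count — a robust local background
#' that keeps the trace near zero after the last fluorophore bleaches.
#' Anchors whose annulus leaves the image are excluded and logged.
#'
#' @param movie A [movie_stack()].
#' @param anchors Tibble with `track_id`, `row`, `col` (see
#'   [track_anchors()]).
#' @param aperture_radius Signal disc radius in px (default 3).
#' @param annulus Inner and outer background annulus radii in px (default
#'   c(5, 7)).
#' @return List with `traces` (tibble: track_id, frame, intensity) and
#'   `rejected` (tibble: track_id, reason).
#' @export
extract_traces <- function(movie, anchors, aperture_radius = 3,
                           annulus = c(5, 7)) {
  d <- dim(movie$data)
  nfr <- d[3]
  disc <- disc_offsets(aperture_radius)
  ann <- annulus_offsets(annulus[1], annulus[2])
  n_disc <- nrow(disc)
  flat <- movie$data
  dim(flat) <- c(d[1] * d[2], nfr)
  margin <- ceiling(annulus[2])
  out <- vector("list", nrow(anchors))
  rej <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    r0 <- round(anchors$row[i]); c0 <- round(anchors$col[i])
    if (r0 - margin < 1 || r0 + margin > d[1] ||
        c0 - margin < 1 || c0 + margin > d[2]) {
      rej[[i]] <- tibble(track_id = anchors$track_id[i],
                         reason = "anchor too close to image border")
      next
    }
    disc_lin <- (c0 + disc$dc - 1) * d[1] + (r0 + disc$dr)
    ann_lin <- (c0 + ann$dc - 1) * d[1] + (r0 + ann$dr)
    ap <- colSums(flat[disc_lin, , drop = FALSE])
    bg <- col_medians(flat[ann_lin, , drop = FALSE])
    out[[i]] <- tibble(track_id = anchors$track_id[i],
                       frame = seq_len(nfr),
                       intensity = ap - bg * n_disc)
  }
  list(traces = bind_rows(out),
       rejected = bind_rows(rej) %||%
         tibble(track_id = integer(0), reason = character(0)))
}

`%||%` <- function(a, b) if (is.null(a) || (is.data.frame(a) && nrow(a) == 0)) b else a

first_background_frame <- function(smooth, thresh, run = 3) {
  below <- smooth < thresh
  r <- rle(below)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run)
  if (length(hit) == 0) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

#' Quality-control filter for photobleaching traces
#'
#' Applies explicit, logged acceptance rules replacing manual trace curation:
#' a trace is rejected if (a) it does not end within `end_tol` unit steps of
#' zero (incomplete bleaching), (b) its anchor lies within
#' `neighbor_radius` of another trace's anchor (overlapping particles),
#' (c) it re-brightens above `blink_thresh` unit steps after first reaching
#' background (blinking), or (d) it reaches background in fewer than
#' `min_duration` frames (too short to score).
#'
#' @param traces Trace tibble (`track_id`, `frame`, `intensity`).
#' @param unit_intensity Estimated single-fluorophore trace intensity
#'   (aperture-summed counts per frame); see [estimate_unit_intensity()].
#' @param anchors Optional anchor tibble for the neighbor rule (b).
#' @param neighbor_radius Exclusion radius in px (default `3 * 1.3`, three
#'   PSF sigmas).
#' @param end_tol,blink_thresh Tolerances as fractions of one unit step
#'   (defaults 0.5).
#' @param end_window Number of final frames averaged for rule (a).
#' @param min_duration Minimum frames before background for rule (d). The
#'   default (3) is deliberately small: any duration cut censors
#'   fast-bleaching monomers more than oligomers and biases the step
#'   histogram, so the rule only removes traces too short to segment.
#' @return List with `accepted` (trace tibble) and `rejections` (tibble:
#'   track_id, reason).
#' @export
qc_filter_traces <- function(traces, unit_intensity, anchors = NULL,
                             neighbor_radius = 3 * 1.3, end_tol = 0.5,
                             blink_thresh = 0.5, end_window = 20,
                             min_duration = 3) {
  rej <- list()
  bad_neighbor <- integer(0)
  if (!is.null(anchors) && nrow(anchors) > 1) {
    d2 <- as.matrix(stats::dist(cbind(anchors$row, anchors$col)))^2
    diag(d2) <- Inf
    bad_neighbor <- anchors$track_id[apply(d2, 1, min) < neighbor_radius^2]
  }
  verdicts <- traces %>%
    group_by(.data$track_id) %>%
    summarise(reason = {
      x <- .data$intensity
      sm <- if (length(x) >= 5) stats::runmed(x, 5) else x
      bg_frame <- first_background_frame(sm, blink_thresh * unit_intensity)
      if (.data$track_id[1] %in% bad_neighbor) {
        "overlapping neighbor within exclusion radius"
      } else if (mean(tail(x, min(end_window, length(x)))) >
                 end_tol * unit_intensity) {
        "not fully bleached"
      } else if (!is.na(bg_frame) &&
                 any(sm[seq(bg_frame, length(sm))] >
                     blink_thresh * unit_intensity)) {
        "re-brightening after background (blinking)"
      } else if (is.na(bg_frame) || bg_frame - 1L < min_duration) {
        "visible for fewer frames than minimum duration"
      } else {
        NA_character_
      }
    }, .groups = "drop")
  ok <- verdicts$track_id[is.na(verdicts$reason)]
  list(
    accepted = traces %>% filter(.data$track_id %in% ok),
    rejections = verdicts %>% filter(!is.na(.data$reason)) %>%
      select("track_id", "reason")
  )
}
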
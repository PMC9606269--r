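#' Movie stack container
#'
#' A lightweight container for a TIRF image sequence: a rows x cols x frames
#' numeric array plus the two pieces of metadata the pipeline needs (pixel
#' pitch and frame interval).
#'
#' @param data Numeric array, dim = c(rows, cols, frames); a single matrix is
#'   promoted to one frame.
#' @param pixel_size Pixel pitch in um/px.
#' @param frame_interval Frame interval in ms.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(data, pixel_size = 0.107, frame_interval = 50) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("`data` must be a rows x cols x frames array.")
  }
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  structure(
    list(data = data, pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Movie stack: %d x %d px x %d frames (%.4g um/px, %g ms/frame, %.1f um^2)\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval,
    d[1] * d[2] * x$pixel_size^2))
  invisible(x)
}

#' @rdname movie_stack
#' @param x A `movie_stack`.
#' @export
n_frames <- function(x) dim(x$data)[3]

#' @rdname movie_stack
#' @param frame Frame index (1-based).
#' @export
get_frame <- function(x, frame = 1) {
  d <- dim(x$data)
  if (frame < 1 || frame > d[3]) abort("`frame` out of range.")
  x$data[, , frame]
}

#' Field-of-view area of a movie in square microns
#'
#' @param movie A [movie_stack()].
#' @return Area in um^2.
#' @export
fov_area <- function(movie) {
  d <- dim(movie$data)
  d[1] * d[2] * movie$pixel_size^2
}

#' Read and write movies as multi-page 16-bit TIFF
#'
#' Movies are stored as unsigned 16-bit multi-page TIFF, with counts clamped
#' to `[0, 65535]` and rounded to integers on write. Pixel size and frame
#' interval are not carried by the TIFF and must be supplied on read.
#'
#' @param movie A [movie_stack()].
#' @param path Output (or input) file path.
#' @return `write_movie_tiff()` returns `path` invisibly; `read_movie_tiff()`
#'   returns a [movie_stack()].
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- purrr::map(seq_len(n_frames(movie)), function(f) {
    m <- movie$data[, , f]
    pmin(pmax(round(m), 0), 65535) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param pixel_size,frame_interval Metadata to attach on read.
#' @export
read_movie_tiff <- function(path, pixel_size = 0.107, frame_interval = 50) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(frames)) frames <- list(frames)
  arr <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    arr[, , f] <- m * 65535
  }
  movie_stack(arr, pixel_size = pixel_size, frame_interval = frame_interval)
}

#' Write pipeline tables to CSV
#'
#' Thin wrappers fixing the column contracts of the pipeline's tabular
#' artifacts (ground truth, spot tables, traces, step fits, histograms).
#'
#' @param x The tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pb_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pb_csv
#' @export
read_pb_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
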
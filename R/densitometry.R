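#' Read a grayscale gel image
#'
#' Reads a PNG or TIFF gel image into a numeric matrix (rows = migration
#' axis). Multi-channel images are averaged to grayscale. Gels photographed
#' as dark bands on a light background are inverted with
#' \code{polarity = "dark_bands"} so that, internally, band signal is always
#' bright-on-dark (larger value = more DNA).
#'
#' @param path path to a \code{.png}, \code{.tif} or \code{.tiff} file.
#' @param polarity \code{"light_bands"} (fluorescence imaging, default) or
#'   \code{"dark_bands"} (invert on load).
#' @return A numeric matrix of intensities >= 0.
#' @export
read_gel_image <- function(path, polarity = c("light_bands", "dark_bands")) {
  polarity <- match.arg(polarity)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  if (polarity == "dark_bands") img <- max(img) - img
  img
}

#' Extract a lane intensity profile from a gel image
#'
#' Sums pixel intensities across the width of a lane rectangle, producing
#' the 1-D migration-axis profile ("lane plot") on which bands appear as
#' bumps. Rows index migration distance from the well.
#'
#' @param image numeric matrix (rows = migration axis), e.g. from
#'   [read_gel_image()] or [simulate_gel_image()].
#' @param rect lane rectangle \code{c(row1, row2, col1, col2)}, 1-based
#'   inclusive pixel indices within the image.
#' @return A data frame of class \code{"lane_profile"} with columns
#'   \code{position} (row index) and \code{intensity}.
#' @export
lane_profile <- function(image, rect) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix", call. = FALSE)
  rect <- as.numeric(rect)
  if (length(rect) != 4L || anyNA(rect))
    stop("'rect' must be c(row1, row2, col1, col2)", call. = FALSE)
  if (rect[1] < 1 || rect[2] > nrow(image) || rect[3] < 1 ||
      rect[4] > ncol(image) || rect[1] > rect[2] || rect[3] > rect[4])
    stop("lane rectangle out of image bounds or zero-area", call. = FALSE)
  rows <- rect[1]:rect[2]
  block <- image[rows, rect[3]:rect[4], drop = FALSE]
  structure(data.frame(position = rows, intensity = rowSums(block)),
            class = c("lane_profile", "data.frame"))
}

as_lane_profile <- function(profile) {
  if (!is.data.frame(profile) ||
      !all(c("position", "intensity") %in% names(profile)))
    stop("a lane profile needs 'position' and 'intensity' columns",
         call. = FALSE)
  if (is.unsorted(profile$position, strictly = TRUE))
    stop("profile positions must be strictly increasing", call. = FALSE)
  if (any(profile$intensity < 0))
    stop("profile intensities must be nonnegative", call. = FALSE)
  profile
}

#' Subtract the background baseline from a lane profile
#'
#' Removes background signal (gel autofluorescence, illumination gradients)
#' before band quantification. Three estimators are provided:
#' \describe{
#'   \item{\code{"snip"} (default)}{iterative peak clipping (the SNIP
#'     scheme): each point is lowered to the mean of its two neighbours at
#'     span m whenever it exceeds that mean, for spans m decreasing from
#'     half the window to 1. Bands narrower than the window are carved down
#'     to the chord between the flanking background, so band areas on a
#'     linearly varying background are recovered essentially exactly,
#'     whatever the slope.}
#'   \item{\code{"rolling_minimum"}}{morphological opening (running minimum
#'     followed by running maximum). Simple and robust, but on a sloped
#'     background it clips a slice of order (slope x band width) off each
#'     band; prefer it only when the background is locally flat.}
#'   \item{\code{"linear_endpoints"}}{straight line through the two profile
#'     endpoints.}
#' }
#' Corrected intensities are clipped at zero. \code{window} should be about
#' 3x the widest band so the smoother bridges bands instead of following
#' them.
#'
#' Pixel noise is averaged out with a short running mean (\code{smooth}
#' points) before the baseline is estimated; without it the clipping
#' estimators hug the lower noise envelope and every corrected point picks
#' up a positive pedestal of order the noise amplitude, which biases wide
#' window integrals. Set \code{smooth = 1} to disable.
#'
#' @param profile a [lane_profile()] (or data frame with \code{position} and
#'   \code{intensity}).
#' @param method baseline estimator, see Details.
#' @param window smoothing / minimum window width in pixels. Ignored by
#'   \code{linear_endpoints}.
#' @param smooth running-mean width (pixels, odd) applied to the profile
#'   before baseline estimation; much narrower than any band.
#' @return The profile with baseline-corrected intensities; the method and
#'   window are recorded in attributes.
#' @export
subtract_baseline <- function(profile,
                              method = c("snip", "rolling_minimum",
                                         "linear_endpoints"),
                              window = 51, smooth = 7) {
  method <- match.arg(method)
  profile <- as_lane_profile(profile)
  n <- nrow(profile)
  y <- profile$intensity
  smooth <- as.integer(smooth)
  if (smooth < 1 || smooth > n)
    stop("'smooth' must be between 1 and the profile length", call. = FALSE)
  if (smooth > 1) y <- running_mean(y, smooth %/% 2)
  if (method != "linear_endpoints") {
    window <- as.integer(window)
    if (window < 1 || window > n)
      stop("'window' must be between 1 and the profile length", call. = FALSE)
  }
  half <- if (method == "linear_endpoints") NA_integer_ else window %/% 2
  base <- switch(method,
    linear_endpoints = seq(y[1], y[n], length.out = n),
    rolling_minimum = {
      erode <- vapply(seq_len(n), function(i)
        min(y[max(1, i - half):min(n, i + half)]), numeric(1))
      vapply(seq_len(n), function(i)
        max(erode[max(1, i - half):min(n, i + half)]), numeric(1))
    },
    snip = {
      b <- y
      for (m in rev(seq_len(half))) {
        if (n > 2 * m) {
          i <- (m + 1L):(n - m)
          b[i] <- pmin(b[i], (b[i - m] + b[i + m]) / 2)
        }
      }
      b
    })
  out <- profile
  out$intensity <- pmax(y - base, 0)
  attr(out, "baseline_method") <- method
  attr(out, "baseline_window") <- if (method == "linear_endpoints") NA else window
  out
}

# truncated-window running mean (cumsum-based)
running_mean <- function(v, half) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Band windows on a lane profile
#'
#' @param supercoiled,relaxed,linear half-open position intervals
#'   \code{c(start, end)} — the window covers positions with
#'   \code{start <= position < end}.
#' @return A list of class \code{"band_windows"}.
#' @export
band_windows <- function(supercoiled, relaxed, linear) {
  w <- list(supercoiled = as.numeric(supercoiled),
            relaxed = as.numeric(relaxed), linear = as.numeric(linear))
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2L || anyNA(w[[nm]]) || w[[nm]][1] >= w[[nm]][2])
      stop("window '", nm, "' must be c(start, end) with start < end",
           call. = FALSE)
  }
  cmb <- utils::combn(names(w), 2)
  for (k in seq_len(ncol(cmb))) {
    a <- w[[cmb[1, k]]]; b <- w[[cmb[2, k]]]
    if (max(a[1], b[1]) < min(a[2], b[2]))
      stop("windows '", cmb[1, k], "' and '", cmb[2, k], "' overlap",
           call. = FALSE)
  }
  structure(w, class = "band_windows")
}

#' Quantify band percentages within a lane
#'
#' Integrates the (baseline-corrected) profile over each band window and
#' expresses each band as a percentage of the summed band signal — the
#' quantity tabulated per lane in the plasmid assay. When more than 10\% of
#' the total corrected signal falls outside all three windows (e.g. smeared
#' linear fragments at high dose) a warning is emitted.
#'
#' @param profile a baseline-corrected [lane_profile()].
#' @param windows a [band_windows()] object.
#' @return Named numeric vector \code{c(supercoiled, relaxed, linear)} of
#'   percentages summing to 100.
#' @export
quantify_bands <- function(profile, windows) {
  profile <- as_lane_profile(profile)
  if (!inherits(windows, "band_windows"))
    windows <- band_windows(windows$supercoiled, windows$relaxed, windows$linear)
  pos <- profile$position
  rng <- range(pos)
  ints <- vapply(windows, function(w) {
    if (w[1] < rng[1] || w[2] > rng[2] + 1)
      stop("band window [", w[1], ", ", w[2], ") outside the profile range",
           call. = FALSE)
    sum(profile$intensity[pos >= w[1] & pos < w[2]])
  }, numeric(1))
  total <- sum(ints)
  if (total <= 0)
    stop("no band signal inside the windows; cannot form percentages",
         call. = FALSE)
  grand <- sum(profile$intensity)
  if (grand > 0 && (grand - total) / grand > 0.10)
    warning(sprintf("%.0f%% of corrected signal lies outside all band windows",
                    100 * (grand - total) / grand), call. = FALSE)
  100 * ints / total
}

#' Automatically place band windows from profile peaks
#'
#' Detects the three band peaks on a baseline-corrected profile and splits
#' the profile at the intensity minima between adjacent peaks, assigning
#' species labels by migration order. For an intact plasmid on native
#' agarose the supercoiled form migrates fastest (largest position), the
#' relaxed form slowest and the linear form in between; pass
#' \code{migration_order} to override.
#'
#' @param profile a baseline-corrected [lane_profile()].
#' @param migration_order species labels in order of increasing migration
#'   position (well to front).
#' @param min_height minimum peak height as a fraction of the profile
#'   maximum.
#' @return A [band_windows()] object.
#' @export
auto_detect_windows <- function(profile,
                                migration_order = c("relaxed", "linear",
                                                    "supercoiled"),
                                min_height = 0.05) {
  profile <- as_lane_profile(profile)
  if (!setequal(migration_order, c("supercoiled", "relaxed", "linear")))
    stop("'migration_order' must be a permutation of the three species",
         call. = FALSE)
  y <- profile$intensity
  if (max(y) <= 0)
    stop("flat profile: no peaks detected; supply windows manually",
         call. = FALSE)
  pk <- pracma::findpeaks(y, minpeakheight = min_height * max(y),
                          minpeakdistance = 3, npeaks = 3, sortstr = TRUE)
  if (is.null(pk) || nrow(pk) < 3)
    stop("detected ", if (is.null(pk)) 0 else nrow(pk),
         " peaks but 3 bands are expected; supply windows manually",
         call. = FALSE)
  centers_idx <- sort(pk[, 2])
  pos <- profile$position
  # split at the minimum between adjacent peak centres
  cut1 <- which.min(y[centers_idx[1]:centers_idx[2]]) + centers_idx[1] - 1
  cut2 <- which.min(y[centers_idx[2]:centers_idx[3]]) + centers_idx[2] - 1
  iv <- list(c(pos[1], pos[cut1]),
             c(pos[cut1], pos[cut2]),
             c(pos[cut2], pos[length(pos)] + 1))
  names(iv) <- migration_order
  band_windows(supercoiled = iv$supercoiled, relaxed = iv$relaxed,
               linear = iv$linear)
}

#' Quantify every lane of a synthetic or measured gel image
#'
#' Convenience wrapper: profile extraction, baseline subtraction, window
#' placement and band quantification for each lane rectangle.
#'
#' @param image numeric matrix.
#' @param lane_rects list of lane rectangles (see [lane_profile()]).
#' @param windows optional fixed [band_windows()]; default auto-detects per
#'   lane.
#' @param baseline_method,baseline_window passed to [subtract_baseline()].
#' @param migration_order passed to [auto_detect_windows()].
#' @return A data frame with one row per lane: \code{lane},
#'   \code{pct_supercoiled}, \code{pct_relaxed}, \code{pct_linear}.
#' @export
quantify_gel <- function(image, lane_rects, windows = NULL,
                         baseline_method = "snip",
                         baseline_window = 51,
                         migration_order = c("relaxed", "linear",
                                             "supercoiled")) {
  res <- lapply(seq_along(lane_rects), function(i) {
    prof <- subtract_baseline(lane_profile(image, lane_rects[[i]]),
                              method = baseline_method,
                              window = baseline_window)
    w <- if (is.null(windows))
      auto_detect_windows(prof, migration_order = migration_order)
    else windows
    pct <- quantify_bands(prof, w)
    data.frame(lane = i, pct_supercoiled = pct[["supercoiled"]],
               pct_relaxed = pct[["relaxed"]], pct_linear = pct[["linear"]])
  })
  do.call(rbind, res)
}
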
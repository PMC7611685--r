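#' Simulate a band-percentage dataset from known conversion rates
#'
#' Generates replicate gel-lane measurements with the statistical structure
#' the kinetic fit assumes: true proportions from the consecutive-break
#' closed form, perturbed per lane by one of two noise models.
#'
#' \describe{
#'   \item{\code{"gaussian"}}{independent Gaussian noise of standard
#'     deviation \code{sd} percentage points added to each species, clipped
#'     to \code{[0, 1]} and renormalized so each lane keeps the true total.
#'     \code{sd = 5} matches the mid-range of replicate scatter seen in this
#'     assay (roughly 1--25 percentage points depending on dose).}
#'   \item{\code{"dirichlet"}}{lane proportions drawn from a Dirichlet
#'     distribution centred on the truth with the given \code{concentration};
#'     preferred near the 0/1 boundaries where clipped Gaussians are
#'     distorted. The mean equals the truth exactly.}
#' }
#'
#' Default design grids mirror the assay's standard designs: external beam
#' \code{c(0, 0.5, 1, 2, 5, 10, 20, 40)} Gy and radionuclide co-incubation
#' \code{c(0, 2, 4, 21, 25)} h.
#'
#' @param ksr,krl,ksl true conversion rates (per Gy or per h).
#' @param s0,r0,l0 true initial fractions.
#' @param grid design exposures; default depends on \code{axis}.
#' @param n replicates per design point.
#' @param sd Gaussian noise SD in percentage points (0 = noiseless).
#' @param noise \code{"gaussian"} or \code{"dirichlet"}.
#' @param concentration Dirichlet concentration (total); larger = tighter.
#' @param axis \code{"dose"} or \code{"time"}.
#' @param condition condition label stored in the dataset.
#' @param seed integer seed; identical arguments and seed give identical
#'   output.
#' @return A [gel_dataset()] (percentages, one row per simulated lane).
#' @examples
#' simulate_gel_dataset(ksr = 1.21, krl = 0.017, s0 = 0.97, n = 2, seed = 1)
#' @export
simulate_gel_dataset <- function(ksr, krl, ksl = 0, s0 = 0.97, r0 = 0, l0 = 0,
                                 grid = NULL, n = 6, sd = 5,
                                 noise = c("gaussian", "dirichlet"),
                                 concentration = 200,
                                 axis = c("dose", "time"),
                                 condition = "synthetic", seed = 1L) {
  noise <- match.arg(noise)
  axis <- match.arg(axis)
  if (is.null(grid))
    grid <- if (axis == "dose") c(0, 0.5, 1, 2, 5, 10, 20, 40)
            else c(0, 2, 4, 21, 25)
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (sd < 0) stop("'sd' must be >= 0", call. = FALSE)
  if (concentration <= 0) stop("'concentration' must be > 0", call. = FALSE)
  grid <- sort(grid)
  truth <- predict_topology(grid, ksr = ksr, krl = krl, ksl = ksl,
                            init = plasmid_init(s0, r0, l0))
  total <- s0 + r0 + l0

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    tr <- c(truth$s[i], truth$r[i], truth$l[i])
    mat <- matrix(NA_real_, nrow = n, ncol = 3)
    for (j in seq_len(n)) {
      mat[j, ] <- if (noise == "gaussian") {
        if (sd == 0) tr else {
          y <- pmin(pmax(tr + stats::rnorm(3, 0, sd / 100), 0), 1)
          if (sum(y) > 0) y * total / sum(y) else tr
        }
      } else {
        draw_dirichlet(tr, concentration, total)
      }
    }
    rows[[i]] <- data.frame(x = grid[i], replicate = seq_len(n),
                            s = 100 * mat[, 1], r = 100 * mat[, 2],
                            l = 100 * mat[, 3])
  }
  d <- do.call(rbind, rows)
  gel_dataset(x = d$x, s = d$s, r = d$r, l = d$l, replicate = d$replicate,
              axis = axis, condition = condition)
}

# Dirichlet draw centred on tr (fractions summing to <= total); components with
# zero truth stay exactly zero, mirroring species absent from a lane.
draw_dirichlet <- function(tr, concentration, total) {
  p <- tr / total
  g <- numeric(3)
  pos <- p > 0
  g[pos] <- stats::rgamma(sum(pos), shape = concentration * p[pos], rate = 1)
  if (sum(g) == 0) return(tr)
  total * g / sum(g)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Render a synthetic agarose gel image with known band proportions
#'
#' Draws one or more gel lanes as grayscale images in which each lane shows
#' up to three Gaussian bands (supercoiled, relaxed, linear) whose
#' integrated intensities are proportional to the lane's topology
#' proportions. An optional linear background ramp and additive Gaussian
#' pixel noise emulate real imaging conditions. A ground-truth table
#' accompanies the image so densitometry can be validated by round trip.
#'
#' The migration axis runs along image rows (row 1 = well). By default the
#' supercoiled form migrates fastest (largest row), the relaxed form
#' slowest, the linear form in between, as for an intact plasmid on a
#' native agarose gel.
#'
#' @param lanes a list (or single vector) of per-lane proportions
#'   \code{c(s, r, l)}; need not sum to 1.
#' @param nrow_img image height in pixels (migration axis).
#' @param lane_width,lane_gap lane width and inter-lane gap in pixels.
#' @param centers named numeric vector of band centre rows for
#'   \code{supercoiled}, \code{relaxed}, \code{linear}.
#' @param sigma Gaussian band SD along the migration axis, pixels.
#' @param amplitude total integrated intensity of a lane with proportions
#'   summing to 1.
#' @param noise_sd additive pixel noise SD.
#' @param background_ramp background intensity added linearly from 0 (top
#'   row) to this value (bottom row).
#' @param seed integer seed for the pixel noise.
#' @return A list: \code{image} (matrix, rows = migration axis),
#'   \code{truth} (data frame of generating proportions per lane),
#'   \code{lane_rects} (list of \code{c(row1, row2, col1, col2)} rectangles),
#'   \code{centers}, \code{sigma}.
#' @examples
#' g <- simulate_gel_image(list(c(0.5, 0.4, 0.1)), noise_sd = 0)
#' dim(g$image)
#' @export
simulate_gel_image <- function(lanes, nrow_img = 200, lane_width = 20,
                               lane_gap = 10,
                               centers = c(relaxed = 60, linear = 100,
                                           supercoiled = 150),
                               sigma = 4, amplitude = 1000, noise_sd = 0,
                               background_ramp = 0, seed = 1L) {
  if (is.numeric(lanes)) lanes <- list(lanes)
  if (!all(c("supercoiled", "relaxed", "linear") %in% names(centers)))
    stop("'centers' must name supercoiled, relaxed and linear rows",
         call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (any(centers < 1 | centers > nrow_img))
    stop("band centers must lie within the image", call. = FALSE)

  nlanes <- length(lanes)
  ncol_img <- nlanes * lane_width + (nlanes + 1) * lane_gap
  img <- matrix(0, nrow = nrow_img, ncol = ncol_img)
  rows_axis <- seq_len(nrow_img)

  lane_rects <- vector("list", nlanes)
  truth <- data.frame(lane = seq_len(nlanes), s = NA_real_, r = NA_real_,
                      l = NA_real_)
  for (i in seq_len(nlanes)) {
    p <- lanes[[i]]
    if (length(p) != 3 || any(p < 0))
      stop("each lane needs nonnegative proportions c(s, r, l)", call. = FALSE)
    col1 <- lane_gap + (i - 1) * (lane_width + lane_gap) + 1
    col2 <- col1 + lane_width - 1
    lane_rects[[i]] <- c(row1 = 1, row2 = nrow_img, col1 = col1, col2 = col2)
    truth[i, c("s", "r", "l")] <- p
    areas <- amplitude * c(p[1], p[2], p[3])
    ctr <- centers[c("supercoiled", "relaxed", "linear")]
    prof <- rep(0, nrow_img)
    for (b in 1:3)
      prof <- prof + areas[b] * stats::dnorm(rows_axis, ctr[b], sigma)
    img[, col1:col2] <- img[, col1:col2] + prof / lane_width
  }

  if (background_ramp > 0)
    img <- img + matrix(background_ramp * (rows_axis - 1) / (nrow_img - 1),
                        nrow = nrow_img, ncol = ncol_img)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow = nrow_img)
    img[img < 0] <- 0
  }
  list(image = img, truth = truth, lane_rects = lane_rects,
       centers = centers, sigma = sigma)
}
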
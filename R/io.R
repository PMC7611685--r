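gel_table_header <- c("condition", "axis_kind", "x", "replicate",
                      "pct_supercoiled", "pct_relaxed", "pct_linear")

#' Read and write gel band-percentage tables
#'
#' The on-disk format is a plain CSV with the exact header
#' \code{condition, axis_kind, x, replicate, pct_supercoiled, pct_relaxed,
#' pct_linear} — one row per gel lane, percentages on the 0--100 scale, and
#' \code{axis_kind} either \code{dose} (x in Gy) or \code{time} (x in h).
#' Reading validates every row and reports the first offending row and
#' field; writing uses a fixed column order and no quoting, so a
#' read--write cycle of a canonical file is byte-stable.
#'
#' @param path file path.
#' @return \code{read_gel_table()} returns a [gel_dataset()];
#'   \code{write_gel_table()} returns \code{path} invisibly.
#' @export
read_gel_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(raw), gel_table_header))
    stop("malformed header in ", path, ": expected exactly '",
         paste(gel_table_header, collapse = ","), "'", call. = FALSE)
  tryCatch(validate_gel_dataset(raw),
           error = function(e)
             stop("invalid gel table ", path, ": ", conditionMessage(e),
                  call. = FALSE))
}

#' @rdname read_gel_table
#' @param data a [gel_dataset()].
#' @export
write_gel_table <- function(data, path) {
  data <- validate_gel_dataset(as.data.frame(data))
  if (any(grepl("[,\"\n]", data$condition)))
    stop("condition labels may not contain commas, quotes or newlines",
         call. = FALSE)
  utils::write.table(data[gel_table_header], path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and write lane profiles as 2-column CSV
#'
#' @param profile a [lane_profile()].
#' @param path file path; columns \code{position}, \code{intensity}.
#' @export
write_lane_profile <- function(profile, path) {
  profile <- as_lane_profile(profile)
  utils::write.table(profile[c("position", "intensity")], path, sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_lane_profile
#' @export
read_lane_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(raw), c("position", "intensity")))
    stop("lane profile CSV must have columns 'position,intensity'",
         call. = FALSE)
  structure(as_lane_profile(raw), class = c("lane_profile", "data.frame"))
}

#' Serialize a kinetic fit to a JSON report
#'
#' Writes the fitted parameters with standard errors, the covariance
#' matrix, fit diagnostics and the fitting options to JSON, so a fit can be
#' archived and fed back to the equivalence calculator.
#'
#' @param fit a \code{topo_fit}.
#' @param path output path (\code{.json}).
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "topo_fit"))
  rep <- list(
    model = "consecutive-break S->R->L",
    variant = fit$variant,
    axis = fit$axis,
    rate_unit = rate_unit(fit$axis),
    coefficients = as.list(fit$coefficients),
    standard_errors = as.list(fit$se),
    covariance = fit$vcov,
    diagnostics = list(weighted_rss = fit$deviance,
                       df_residual = fit$df.residual,
                       n_obs = fit$n_obs,
                       converged = fit$converged,
                       info = fit$info,
                       message = fit$message,
                       at_boundary = as.list(fit$at_boundary),
                       note = fit$cov_note),
    options = list(fit_s0 = fit$fit_s0, weights = fit$weights,
                   sd_floor = fit$sd_floor,
                   scale_covariance = fit$scale_covariance,
                   drop_linear_above = fit$drop_linear_above))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_fit_report
#' @return \code{read_fit_report()} returns the report as a list; the
#'   \code{coefficients} and \code{standard_errors} elements are named
#'   numeric vectors usable with [equivalent_dose()] via [report_rate()].
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$coefficients <- unlist(rep$coefficients)
  rep$standard_errors <- unlist(rep$standard_errors)
  rep
}

#' Rate estimate from a stored fit report
#'
#' @param report a list from [read_fit_report()].
#' @param which parameter name.
#' @export
report_rate <- function(report, which = "ksr") {
  if (!which %in% names(report$coefficients))
    stop("no parameter '", which, "' in this report", call. = FALSE)
  list(value = unname(report$coefficients[which]),
       se = unname(report$standard_errors[which]),
       axis = report$axis, unit = report$rate_unit)
}

#' Write a grayscale image as PNG or TIFF
#'
#' Intensities are rescaled to \code{[0, 1]} by the image maximum before
#' writing.
#'
#' @param image numeric matrix.
#' @param path output path ending in \code{.png}, \code{.tif} or
#'   \code{.tiff}.
#' @export
write_gel_image <- function(image, path) {
  if (!is.matrix(image)) stop("'image' must be a matrix", call. = FALSE)
  m <- max(image)
  if (m > 0) image <- image / m
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(image, path),
         tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 16L),
         stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}
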
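#' Assemble a gel band-percentage dataset
#'
#' Bundles per-lane band percentages into the replicate-structured table the
#' fitting routines consume. Each row is one gel lane: an exposure value (Gy
#' of external beam dose, or hours of incubation with a radionuclide), a
#' replicate index, and the percentage of total lane signal in the
#' supercoiled, relaxed and linear bands.
#'
#' Percentages in a lane may sum to slightly less than 100 (faint smears fall
#' outside the band windows); a slack of 2 percentage points above 100 is
#' tolerated before a row is rejected, matching the precision of manual gel
#' quantification.
#'
#' @param x numeric vector of exposures, one per lane, all >= 0.
#' @param s,r,l numeric vectors of band percentages (0--100+slack) for the
#'   supercoiled, relaxed and linear bands.
#' @param replicate integer replicate identifiers (default: all lanes at the
#'   same \code{x} are consecutive replicates).
#' @param axis \code{"dose"} (x in Gy) or \code{"time"} (x in h). Rates
#'   fitted against the dataset inherit the reciprocal unit.
#' @param condition free-text condition label (agent, activity, plasmid
#'   concentration).
#' @return A data frame of class \code{"gel_dataset"} with columns
#'   \code{condition}, \code{axis_kind}, \code{x}, \code{replicate},
#'   \code{pct_supercoiled}, \code{pct_relaxed}, \code{pct_linear}.
#' @examples
#' gel_dataset(x = c(0, 0, 1, 1), s = c(97, 95, 50, 55),
#'             r = c(2, 4, 45, 40), l = c(1, 1, 5, 5), axis = "dose")
#' @export
gel_dataset <- function(x, s, r, l, replicate = NULL, axis = c("dose", "time"),
                        condition = "unspecified") {
  axis <- match.arg(axis)
  n <- length(x)
  if (!all(lengths(list(s, r, l)) == n))
    stop("'x', 's', 'r', 'l' must have equal length", call. = FALSE)
  if (is.null(replicate)) replicate <- stats::ave(x, x, FUN = seq_along)
  if (length(replicate) != n)
    stop("'replicate' must match the number of lanes", call. = FALSE)
  out <- data.frame(condition = as.character(condition), axis_kind = axis,
                    x = as.numeric(x), replicate = as.integer(replicate),
                    pct_supercoiled = as.numeric(s), pct_relaxed = as.numeric(r),
                    pct_linear = as.numeric(l))
  validate_gel_dataset(out)
}

#' @rdname gel_dataset
#' @param data a data frame with the \code{gel_dataset} columns, to validate
#'   and classify.
#' @export
validate_gel_dataset <- function(data) {
  needed <- c("condition", "axis_kind", "x", "replicate",
              "pct_supercoiled", "pct_relaxed", "pct_linear")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("gel dataset is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!all(data$axis_kind %in% c("dose", "time")))
    stop("'axis_kind' must be \"dose\" or \"time\"", call. = FALSE)
  if (length(unique(data$axis_kind)) > 1)
    stop("a gel dataset must live on a single exposure axis; ",
         "mixing dose and time rows is an error", call. = FALSE)
  bad <- which(is.na(data$x) | data$x < 0)
  if (length(bad))
    stop("row ", bad[1], ": exposure 'x' must be a nonnegative number",
         call. = FALSE)
  pct <- data[c("pct_supercoiled", "pct_relaxed", "pct_linear")]
  bad <- which(apply(is.na(pct) | pct < 0, 1, any))
  if (length(bad))
    stop("row ", bad[1], ": band percentages must be nonnegative numbers",
         call. = FALSE)
  tot <- rowSums(pct)
  bad <- which(tot > 100 + 2)
  if (length(bad))
    stop("row ", bad[1], ": band percentages sum to ", round(tot[bad[1]], 2),
         " (> 102)", call. = FALSE)
  class(data) <- unique(c("gel_dataset", class(data)))
  data
}

#' Per-exposure means and standard deviations of band percentages
#'
#' Collapses replicate lanes to the mean and sample standard deviation (n-1
#' denominator) of each species at each exposure value — the summary the
#' paper-style plots show and the global fit is weighted by.
#'
#' @param data a [gel_dataset()].
#' @return A data frame with one row per distinct exposure: \code{x},
#'   \code{n}, then \code{mean_*} and \code{sd_*} for each species
#'   (percentages). \code{sd_*} is 0 where only one replicate exists.
#' @export
summarize_replicates <- function(data) {
  data <- validate_gel_dataset(as.data.frame(data))
  if (nrow(data) == 0L) stop("empty gel dataset", call. = FALSE)
  xs <- sort(unique(data$x))
  one <- function(v, f) vapply(xs, function(xi) f(v[data$x == xi]), numeric(1))
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  data.frame(
    x = xs,
    n = vapply(xs, function(xi) sum(data$x == xi), numeric(1)),
    mean_supercoiled = one(data$pct_supercoiled, mean),
    mean_relaxed     = one(data$pct_relaxed, mean),
    mean_linear      = one(data$pct_linear, mean),
    sd_supercoiled   = one(data$pct_supercoiled, sd0),
    sd_relaxed       = one(data$pct_relaxed, sd0),
    sd_linear        = one(data$pct_linear, sd0))
}

#' Published topology conversion rates
#'
#' Reference table of the fitted conversion rates reported for the pBR322
#' assay: external-beam (Cs-137) rates per Gy at two plasmid concentrations,
#' and per-hour rates for co-incubation with ionic 67Ga and 111In. These are
#' reference values for use as simulation truths and as inputs to the
#' dose--time equivalence calculator; the raw gel data behind them are not
#' publicly deposited, so the rates themselves cannot be re-derived here (see
#' the package vignette).
#'
#' @return A data frame with columns \code{condition}, \code{axis}
#'   (\code{"dose"} or \code{"time"}), \code{ksr}, \code{ksr_se},
#'   \code{krl}, \code{krl_se}; rates in Gy^-1 on the dose axis and h^-1 on
#'   the time axis.
#' @examples
#' published_rates()
#' @export
published_rates <- function() {
  data.frame(
    condition = c("EBRT 1.25 ng/uL", "EBRT 5 ng/uL",
                  "67Ga 0.5 MBq 1.25 ng/uL", "67Ga 5 ng/uL",
                  "111In 0.5 MBq 1.25 ng/uL"),
    axis   = c("dose", "dose", "time", "time", "time"),
    ksr    = c(1.21, 0.45, 0.590, 0.159, 0.131),
    ksr_se = c(0.04, 0.06, 0.100, 0.009, 0.010),
    krl    = c(0.017, 0.004, 0.003, NA, 0.0010),
    krl_se = c(0.001, 0.002, 0.001, NA, 0.0002))
}
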
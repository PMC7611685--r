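#' Dose--time equivalence of external beam and radionuclide exposure
#'
#' Using the proportion of supercoiled DNA remaining as the damage proxy,
#' equal damage from \code{t} hours of radionuclide incubation and \code{D}
#' Gy of external beam requires \eqn{S_0 e^{-k_{sr,t} t} = S_0 e^{-k_{sr,D} D}},
#' i.e. \eqn{D = (k_{sr,t} / k_{sr,D})\, t} and conversely
#' \eqn{t = (k_{sr,D} / k_{sr,t})\, D}. Uncertainty is propagated to first
#' order (delta method) through the rate ratio, assuming the two rate
#' estimates are independent:
#' \deqn{\mathrm{SE}(D) = D \sqrt{ (\mathrm{SE}_t/k_t)^2 +
#'   (\mathrm{SE}_D/k_D)^2 }.}
#'
#' @param ksr_time supercoiled decay rate on the time axis (h^-1), either a
#'   single number or a \code{topo_fit} / [rate_estimate()] list.
#' @param ksr_dose supercoiled decay rate on the dose axis (Gy^-1), same
#'   forms accepted.
#' @param t incubation time in hours (>= 0).
#' @param se_time,se_dose standard errors of the two rates; taken from the
#'   fit objects when those are supplied.
#' @return An object of class \code{"topo_equiv"}: list with \code{value}
#'   (Gy), \code{se} (Gy), \code{unit}, \code{basis_species}
#'   (\code{"supercoiled"}) and the echoed inputs.
#' @examples
#' # 1 h with 0.5 MBq ionic 67Ga at 1.25 ng/uL plasmid:
#' equivalent_dose(0.585, 1.21, t = 1, se_time = 0.1, se_dose = 0.04)
#' @export
equivalent_dose <- function(ksr_time, ksr_dose, t, se_time = 0, se_dose = 0) {
  kt <- as_rate(ksr_time, se_time, "time")
  kd <- as_rate(ksr_dose, se_dose, "dose")
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("'t' must be a single nonnegative time in hours", call. = FALSE)
  if (kd$value <= 0)
    stop("the dose-axis rate must be positive", call. = FALSE)
  if (t == 0) return(new_equiv(0, 0, "Gy", kt, kd, t, "h"))
  val <- kt$value / kd$value * t
  se <- val * sqrt((kt$se / kt$value)^2 + (kd$se / kd$value)^2)
  new_equiv(val, se, "Gy", kt, kd, t, "h")
}

#' @rdname equivalent_dose
#' @param D external beam dose in Gy (>= 0).
#' @return For \code{equivalent_time()}: the same structure with \code{value}
#'   and \code{se} in hours.
#' @examples
#' # incubation time with 0.5 MBq ionic 67Ga matching 1 Gy of EBRT:
#' equivalent_time(1.21, 0.590, D = 1, se_dose = 0.04, se_time = 0.1)
#' @export
equivalent_time <- function(ksr_dose, ksr_time, D, se_dose = 0, se_time = 0) {
  kd <- as_rate(ksr_dose, se_dose, "dose")
  kt <- as_rate(ksr_time, se_time, "time")
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D < 0)
    stop("'D' must be a single nonnegative dose in Gy", call. = FALSE)
  if (kt$value <= 0)
    stop("the time-axis rate must be positive", call. = FALSE)
  if (D == 0) return(new_equiv(0, 0, "h", kt, kd, D, "Gy"))
  val <- kd$value / kt$value * D
  se <- val * sqrt((kd$se / kd$value)^2 + (kt$se / kt$value)^2)
  new_equiv(val, se, "h", kt, kd, D, "Gy")
}

as_rate <- function(k, se, axis) {
  if (inherits(k, "topo_fit")) {
    if (k$axis != axis)
      stop("fit is on the ", k$axis, " axis; a ", axis, "-axis rate is required",
           call. = FALSE)
    return(rate_estimate(k, "ksr"))
  }
  if (is.list(k)) {
    if (!is.null(k$axis) && k$axis != axis)
      stop("rate is on the ", k$axis, " axis; a ", axis,
           "-axis rate is required", call. = FALSE)
    return(list(value = k$value, se = k$se %||% 0, axis = axis,
                unit = rate_unit(axis)))
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("rates must be single nonnegative numbers", call. = FALSE)
  if (!is.numeric(se) || length(se) != 1L || is.na(se) || se < 0)
    stop("standard errors must be single nonnegative numbers", call. = FALSE)
  list(value = k, se = se, axis = axis, unit = rate_unit(axis))
}

new_equiv <- function(value, se, unit, kt, kd, given, given_unit,
                      basis = "supercoiled") {
  structure(list(value = value, se = se, unit = unit, basis_species = basis,
                 ksr_time = kt, ksr_dose = kd,
                 given = given, given_unit = given_unit),
            class = "topo_equiv")
}

#' @export
print.topo_equiv <- function(x, ...) {
  cat(sprintf("Equivalent %s: %s +/- %s %s (for %g %s; basis: %s DNA)\n",
              if (x$unit == "Gy") "EBRT dose" else "incubation time",
              signif(x$value, 3), signif(x$se, 2), x$unit,
              x$given, x$given_unit, x$basis_species))
  cat(sprintf("  rates: ksr_time = %s +/- %s h^-1, ksr_dose = %s +/- %s Gy^-1\n",
              signif(x$ksr_time$value, 3), signif(x$ksr_time$se, 2),
              signif(x$ksr_dose$value, 3), signif(x$ksr_dose$se, 2)))
  invisible(x)
}

#' Numeric exposure equivalence for any DNA species
#'
#' Generalizes the rate-ratio equivalence to the relaxed and linear species,
#' where no convenient closed form exists: given two fitted models on
#' different exposure axes, finds the exposure \code{x_b} under \code{fit_b}
#' at which the modelled proportion of the chosen species equals its value
#' under \code{fit_a} at \code{x_a}, by bracketed root search on a monotone
#' branch. The supercoiled proportion is monotone decreasing, the linear
#' proportion nondecreasing; the relaxed proportion rises and then falls, so
#' a \code{branch} must be chosen for it.
#'
#' For the supercoiled species with a shared initial state this reproduces
#' the analytic rate-ratio result of [equivalent_dose()] /
#' [equivalent_time()] to high accuracy, which is tested.
#'
#' @param fit_a,fit_b \code{topo_fit} objects (or plain lists with elements
#'   \code{ksr}, \code{krl}, optional \code{ksl}, \code{s0}, \code{r0},
#'   \code{l0}).
#' @param species \code{"supercoiled"}, \code{"relaxed"} or \code{"linear"}.
#' @param x_a exposure under \code{fit_a} whose damage is to be matched.
#' @param branch for the relaxed species: \code{"rising"} or
#'   \code{"falling"}.
#' @param x_max upper end of the search interval under \code{fit_b};
#'   extended automatically for monotone species when the default does not
#'   bracket the target.
#' @param tol tolerance on the matched proportion.
#' @return The matching exposure \code{x_b} (a single number, units of
#'   \code{fit_b}'s axis).
#' @export
equivalent_exposure <- function(fit_a, fit_b,
                                species = c("supercoiled", "relaxed", "linear"),
                                x_a, branch = NULL, x_max = 100, tol = 1e-12) {
  species <- match.arg(species)
  pa <- as_kin_pars(fit_a)
  pb <- as_kin_pars(fit_b)
  if (!is.numeric(x_a) || length(x_a) != 1L || is.na(x_a) || x_a < 0)
    stop("'x_a' must be a single nonnegative exposure", call. = FALSE)

  col <- c(supercoiled = "s", relaxed = "r", linear = "l")[species]
  eval_at <- function(p, x) {
    predict_topology(x, ksr = p$ksr, krl = p$krl, ksl = p$ksl,
                     init = plasmid_init(p$s0, p$r0, p$l0))[[col]][1]
  }
  target <- eval_at(pa, x_a)

  if (species == "relaxed") {
    if (is.null(branch))
      stop("the relaxed proportion is not monotone; choose branch = \"rising\" ",
           "or \"falling\"", call. = FALSE)
    branch <- match.arg(branch, c("rising", "falling"))
    # locate the interior maximum of R under fit_b
    peak <- stats::optimize(function(x) eval_at(pb, x), c(0, x_max),
                            maximum = TRUE, tol = 1e-12)
    lohi <- if (branch == "rising") c(0, peak$maximum) else c(peak$maximum, x_max)
  } else {
    lohi <- c(0, x_max)
    # monotone species: extend the bracket while the target lies beyond it
    limit <- asymptote(pb, col)
    f_end <- eval_at(pb, lohi[2])
    tries <- 0
    while (tries < 60 &&
           sign_gap(target, eval_at(pb, lohi[1]), f_end) &&
           abs(f_end - limit) > tol) {
      lohi[2] <- lohi[2] * 2
      f_end <- eval_at(pb, lohi[2])
      tries <- tries + 1
    }
  }
  f_lo <- eval_at(pb, lohi[1]) - target
  f_hi <- eval_at(pb, lohi[2]) - target
  if (abs(f_lo) <= tol) return(lohi[1])
  if (abs(f_hi) <= tol && species != "linear") return(lohi[2])
  if (f_lo * f_hi > 0)
    stop("no solution: the ", species, " proportion never reaches ",
         signif(target, 6), " on the selected branch of fit_b", call. = FALSE)
  r <- stats::uniroot(function(x) eval_at(pb, x) - target,
                      interval = lohi, tol = 1e-14)
  r$root
}

sign_gap <- function(target, f_lo, f_hi) {
  (f_lo - target) * (f_hi - target) > 0
}

# species proportion in the limit x -> Inf
asymptote <- function(p, col) {
  total <- p$s0 + p$r0 + p$l0
  kdec <- p$ksr + p$ksl
  s_inf <- if (kdec > 0) 0 else p$s0
  r_inf <- if (p$krl > 0) 0 else p$r0 + if (kdec > 0) p$ksr / kdec * p$s0 else 0
  switch(col, s = s_inf, r = r_inf, l = total - s_inf - r_inf)
}

as_kin_pars <- function(fit) {
  if (inherits(fit, "topo_fit")) {
    cf <- fit$coefficients
    return(list(ksr = unname(cf["ksr"]), krl = unname(cf["krl"]),
                ksl = if ("ksl" %in% names(cf)) unname(cf["ksl"]) else 0,
                s0 = unname(cf["s0"]),
                r0 = fit$fixed$r0 %||% 0, l0 = fit$fixed$l0 %||% 0))
  }
  if (is.list(fit)) {
    need <- c("ksr", "krl")
    if (!all(need %in% names(fit)))
      stop("parameter list needs at least 'ksr' and 'krl'", call. = FALSE)
    return(list(ksr = fit$ksr, krl = fit$krl, ksl = fit$ksl %||% 0,
                s0 = fit$s0 %||% 1, r0 = fit$r0 %||% 0, l0 = fit$l0 %||% 0))
  }
  stop("'fit' must be a topo_fit or a parameter list", call. = FALSE)
}
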
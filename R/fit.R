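#' Data-driven starting values for the kinetic fit
#'
#' The supercoiled closed form is a pure exponential, so a log-linear
#' regression of the mean supercoiled fraction on exposure gives the decay
#' rate directly; zero-signal points (which have no log) are excluded. The
#' relaxed-to-linear rate starts at 1/50 of that (the second step is strongly
#' rate-limiting in this assay), and the initial supercoiled fraction starts
#' at the mean observed at the smallest exposure. If the log fit is
#' degenerate the guess falls back to fixed defaults (1, 0.02, 1).
#'
#' @param data a [gel_dataset()].
#' @return Named numeric vector \code{c(ksr, krl, s0)}.
#' @export
initial_guess <- function(data) {
  sm <- summarize_replicates(data)
  s <- sm$mean_supercoiled / 100
  keep <- s > 1e-6
  if (sum(keep) >= 2 && length(unique(sm$x[keep])) >= 2) {
    slope <- stats::coef(stats::lm(log(s[keep]) ~ sm$x[keep]))[2]
    ksr0 <- max(-slope, 1e-6)
    if (!is.finite(ksr0)) ksr0 <- 1
  } else {
    ksr0 <- 1
  }
  s00 <- s[which.min(sm$x)]
  if (!is.finite(s00) || s00 <= 0) s00 <- 1
  c(ksr = unname(ksr0), krl = unname(ksr0) / 50, s0 = min(s00, 1))
}

#' Fit the consecutive-break kinetic model to gel band percentages
#'
#' Estimates the topology conversion rates (supercoiled-to-relaxed
#' \code{ksr}, relaxed-to-linear \code{krl}, optionally the direct
#' supercoiled-to-linear \code{ksl}) and the initial supercoiled fraction
#' \code{s0} by global weighted nonlinear least squares: the three species
#' proportions are fit jointly, each per-exposure replicate mean weighted by
#' the inverse squared replicate standard deviation. Optimization is
#' bounded Levenberg--Marquardt (\code{minpack.lm::nls.lm}) with all rates
#' constrained nonnegative and \code{s0} in \code{[0, 1]}.
#'
#' Weighting uses the sample SD of the replicate percentages at each
#' exposure, floored at \code{sd_floor} percentage points so that
#' single-replicate or zero-variance points cannot acquire infinite weight.
#' Standard errors come from the inverse of the weighted
#' Gauss--Newton Hessian (J'WJ), by default rescaled by the reduced
#' chi-square (\code{scale_covariance = FALSE} disables the rescaling, in
#' which case the supplied SDs are taken as exact error bars). No standard
#' errors are reported when the fit has no residual degrees of freedom.
#'
#' At high exposures the linear band becomes hard to quantify (fragments
#' smear); \code{drop_linear_above} excludes linear-band observations above
#' that exposure from the objective. The default keeps all points.
#'
#' @param data a [gel_dataset()] (percentages; see [read_gel_table()]).
#' @param fit_s0 estimate the initial supercoiled fraction (default) or fix
#'   it at \code{s0}.
#' @param s0 value at which \code{s0} is fixed when \code{fit_s0 = FALSE}
#'   (default: the data-driven guess).
#' @param variant \code{"basic"} (S -> R -> L) or \code{"direct_break"}
#'   (adds the S -> L rate \code{ksl} as a free parameter).
#' @param weights \code{"sd"} (inverse-variance from replicate SDs, the
#'   default) or \code{"unit"} (unweighted; for data without replicate
#'   structure).
#' @param sd_floor lower bound on the per-point SD, in percentage points.
#' @param scale_covariance rescale the covariance by the reduced chi-square.
#' @param drop_linear_above exposure above which linear-band observations are
#'   excluded (default \code{Inf} = keep all).
#' @param start optional named starting vector overriding [initial_guess()].
#' @param r0,l0 fixed initial relaxed/linear fractions (defaults 0, the
#'   textbook scheme).
#' @param control a \code{minpack.lm::nls.lm.control} list; the default runs
#'   to relative tolerances of 1e-15 with generous evaluation limits.
#' @return An object of class \code{"topo_fit"}; see [coef.topo_fit()],
#'   [summary.topo_fit()], [predict.topo_fit()], [plot.topo_fit()],
#'   [simulate.topo_fit()].
#' @examples
#' d <- simulate_gel_dataset(ksr = 1.21, krl = 0.017, s0 = 0.97,
#'                           grid = c(0, 0.5, 1, 2, 5, 10, 20, 40),
#'                           n = 6, sd = 5, seed = 1)
#' fit <- fit_topology(d)
#' coef(fit)
#' @export
fit_topology <- function(data, fit_s0 = TRUE, s0 = NULL,
                         variant = c("basic", "direct_break"),
                         weights = c("sd", "unit"), sd_floor = 1,
                         scale_covariance = TRUE, drop_linear_above = Inf,
                         start = NULL, r0 = 0, l0 = 0,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, gtol = 0,
                           maxfev = 10000, maxiter = 1024)) {
  variant <- match.arg(variant)
  weights <- match.arg(weights)
  data <- validate_gel_dataset(as.data.frame(data))
  sm <- summarize_replicates(data)
  if (nrow(sm) < 2L)
    stop("fitting requires at least 2 distinct exposure values", call. = FALSE)
  axis <- data$axis_kind[1]

  guess <- initial_guess(data)
  if (is.null(s0)) s0 <- unname(guess["s0"])

  # observations in fraction scale; one block per species
  obs <- c(sm$mean_supercoiled, sm$mean_relaxed, sm$mean_linear) / 100
  species <- rep(c("s", "r", "l"), each = nrow(sm))
  xx <- rep(sm$x, 3)
  if (weights == "sd") {
    sdv <- c(sm$sd_supercoiled, sm$sd_relaxed, sm$sd_linear) / 100
    w <- 1 / pmax(sdv, sd_floor / 100)
  } else {
    w <- rep(1, length(obs))
  }
  keep <- !(species == "l" & xx > drop_linear_above)
  obs <- obs[keep]; species <- species[keep]; xx <- xx[keep]; w <- w[keep]

  par_names <- if (variant == "basic") c("ksr", "krl") else c("ksr", "ksl", "krl")
  if (fit_s0) par_names <- c(par_names, "s0")
  p0 <- c(ksr = unname(guess["ksr"]), ksl = unname(guess["ksr"]) / 100,
          krl = unname(guess["krl"]), s0 = s0)[par_names]
  if (!is.null(start)) {
    unknown <- setdiff(names(start), par_names)
    if (length(unknown))
      stop("unknown start parameters: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p0[names(start)] <- start
  }
  if (length(obs) < length(p0))
    stop("fewer observations than free parameters", call. = FALSE)

  model_at <- function(p) {
    pr <- predict_topology(sort(unique(xx)),
                           ksr = p[["ksr"]],
                           krl = p[["krl"]],
                           ksl = if (variant == "direct_break") p[["ksl"]] else 0,
                           init = plasmid_init(if (fit_s0) p[["s0"]] else s0,
                                               r0, l0))
    idx <- match(xx, pr$x)
    ifelse(species == "s", pr$s[idx],
           ifelse(species == "r", pr$r[idx], pr$l[idx]))
  }
  resid_fn <- function(p) {
    p <- stats::setNames(pmax(p, 0), par_names)
    w * (obs - model_at(p))
  }

  lower <- rep(0, length(p0))
  upper <- ifelse(par_names == "s0", 1, Inf)
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = resid_fn, control = control)
  est <- stats::setNames(pmax(unlist(fit$par), 0), par_names)
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("kinetic fit did not converge (info = ", fit$info, "): ",
            fit$message, call. = FALSE)

  dof <- length(obs) - length(p0)
  wrss <- sum(fit$fvec^2)
  sigma2 <- if (scale_covariance && dof > 0) wrss / dof else 1
  vc <- se <- NULL
  cov_note <- ""
  if (dof > 0) {
    vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
    if (is.null(vc)) {
      vc <- pracma::pinv(fit$hessian)
      cov_note <- "Hessian singular (parameter at boundary?); pseudo-inverse used"
    }
    vc <- sigma2 * vc
    dimnames(vc) <- list(par_names, par_names)
    se <- sqrt(pmax(diag(vc), 0))
  } else {
    cov_note <- "no residual degrees of freedom; standard errors not reported"
    se <- stats::setNames(rep(NA_real_, length(p0)), par_names)
  }

  full_coef <- est
  if (!fit_s0) full_coef <- c(est, s0 = s0)

  structure(list(
    coefficients = full_coef,
    se = se,
    vcov = vc,
    data = data,
    summary_data = sm,
    axis = axis,
    variant = variant,
    fit_s0 = fit_s0,
    fixed = if (fit_s0) list(r0 = r0, l0 = l0) else list(s0 = s0, r0 = r0, l0 = l0),
    weights = weights,
    sd_floor = sd_floor,
    scale_covariance = scale_covariance,
    drop_linear_above = drop_linear_above,
    residuals = stats::setNames(fit$fvec, paste(species, xx, sep = "@")),
    obs = obs, obs_species = species, obs_x = xx, w = w,
    deviance = wrss,
    df.residual = dof,
    n_obs = length(obs),
    converged = converged,
    info = fit$info,
    message = fit$message,
    niter = fit$niter,
    at_boundary = stats::setNames(est <= 1e-8, par_names),
    cov_note = cov_note,
    start = p0,
    call = match.call()),
    class = "topo_fit")
}

rate_unit <- function(axis) if (axis == "dose") "Gy^-1" else "h^-1"

#' @export
coef.topo_fit <- function(object, ...) object$coefficients

#' @export
vcov.topo_fit <- function(object, ...) object$vcov

#' @export
deviance.topo_fit <- function(object, ...) object$deviance

#' @export
df.residual.topo_fit <- function(object, ...) object$df.residual

#' Extract a fitted rate with its standard error
#'
#' @param object a \code{topo_fit}.
#' @param which parameter name (\code{"ksr"}, \code{"krl"}, \code{"ksl"}).
#' @return A named list \code{(value, se, axis, unit)} suitable for the
#'   equivalence calculator.
#' @export
rate_estimate <- function(object, which = "ksr") {
  stopifnot(inherits(object, "topo_fit"))
  if (!which %in% names(object$coefficients))
    stop("no parameter '", which, "' in this fit", call. = FALSE)
  list(value = unname(object$coefficients[which]),
       se = unname(if (which %in% names(object$se)) object$se[which] else NA_real_),
       axis = object$axis, unit = rate_unit(object$axis))
}

#' @export
print.topo_fit <- function(x, digits = 3, ...) {
  cat("Consecutive-break kinetic fit (S -> R -> L",
      if (x$variant == "direct_break") "+ S -> L", ")\n", sep = " ")
  cat("Exposure axis:", x$axis, sprintf("(rates in %s)\n", rate_unit(x$axis)))
  est <- x$coefficients
  se <- x$se[names(est)]
  lab <- ifelse(is.na(se), "(fixed)", paste0("+/- ", signif(se, 2)))
  for (p in names(est))
    cat(sprintf("  %-4s %s %s\n", p, signif(est[p], digits), lab[p]))
  cat(sprintf("Weighted RSS %.4g on %d degrees of freedom (%d observations)\n",
              x$deviance, x$df.residual, x$n_obs))
  if (!x$converged) cat("WARNING: fit did not converge:", x$message, "\n")
  if (nzchar(x$cov_note)) cat("Note:", x$cov_note, "\n")
  invisible(x)
}

#' Summary of a kinetic fit
#'
#' @param object a \code{topo_fit}.
#' @param ... unused.
#' @return An object of class \code{summary.topo_fit}: the coefficient table
#'   (estimate, SE), fit diagnostics and options.
#' @export
summary.topo_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se[names(est)]
  tab <- cbind(Estimate = est, `Std. Error` = se)
  structure(list(coefficients = tab, axis = object$axis,
                 variant = object$variant, deviance = object$deviance,
                 df.residual = object$df.residual, n_obs = object$n_obs,
                 reduced_chisq = if (object$df.residual > 0)
                   object$deviance / object$df.residual else NA_real_,
                 converged = object$converged, niter = object$niter,
                 at_boundary = object$at_boundary, cov_note = object$cov_note,
                 weights = object$weights, sd_floor = object$sd_floor,
                 scale_covariance = object$scale_covariance),
            class = "summary.topo_fit")
}

#' @export
print.summary.topo_fit <- function(x, digits = 4, ...) {
  cat("Global weighted fit of the consecutive-break model (variant:",
      x$variant, ")\n")
  cat("Axis:", x$axis, " Weighting:", x$weights,
      sprintf("(SD floor %g pct points)\n", x$sd_floor))
  stats::printCoefmat(x$coefficients, digits = digits, na.print = "fixed")
  cat(sprintf("\nWeighted RSS: %.4g  df: %d  reduced chi-square: %.3g\n",
              x$deviance, x$df.residual, x$reduced_chisq))
  cat("Converged:", x$converged, sprintf("(%d iterations)\n", x$niter))
  if (any(x$at_boundary))
    cat("At lower boundary:", paste(names(which(x$at_boundary)), collapse = ", "),
        "\n")
  if (nzchar(x$cov_note)) cat("Note:", x$cov_note, "\n")
  invisible(x)
}

fit_init <- function(object) {
  cf <- object$coefficients
  plasmid_init(unname(cf["s0"]), object$fixed$r0 %||% 0, object$fixed$l0 %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Model predictions from a kinetic fit
#'
#' @param object a \code{topo_fit}.
#' @param newdata numeric vector of exposures; default is a fine grid over
#'   the fitted data range.
#' @param ... unused.
#' @return A data frame \code{x}, \code{s}, \code{r}, \code{l} (fractions).
#' @export
predict.topo_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- seq(min(object$summary_data$x), max(object$summary_data$x),
                   length.out = 200)
  cf <- object$coefficients
  predict_topology(newdata, ksr = unname(cf["ksr"]), krl = unname(cf["krl"]),
                   ksl = if ("ksl" %in% names(cf)) unname(cf["ksl"]) else 0,
                   init = fit_init(object))
}

#' @export
fitted.topo_fit <- function(object, ...) {
  predict.topo_fit(object, newdata = object$summary_data$x)
}

#' Residuals of a kinetic fit
#'
#' @param object a \code{topo_fit}.
#' @param type \code{"weighted"} (residual/SD, the objective's scale) or
#'   \code{"response"} (fraction scale).
#' @param ... unused.
#' @export
residuals.topo_fit <- function(object, type = c("weighted", "response"), ...) {
  type <- match.arg(type)
  if (type == "weighted") object$residuals else object$residuals / object$w
}

#' Plot data and fitted kinetic curves
#'
#' Plots the per-exposure replicate means with +/- SD error bars for the
#' three topologies and overlays the fitted model curves.
#'
#' @param x a \code{topo_fit}.
#' @param ... passed to \code{plot()}.
#' @export
plot.topo_fit <- function(x, ...) {
  sm <- x$summary_data
  cols <- c(s = "#1b6ca8", r = "#c0392b", l = "#27ae60")
  graphics::plot(NA, xlim = range(sm$x),
                 ylim = c(0, max(100, sm$mean_supercoiled + sm$sd_supercoiled)),
                 xlab = if (x$axis == "dose") "Dose (Gy)" else "Time (h)",
                 ylab = "% of total DNA", ...)
  pr <- predict.topo_fit(x)
  means <- list(s = sm$mean_supercoiled, r = sm$mean_relaxed, l = sm$mean_linear)
  sds <- list(s = sm$sd_supercoiled, r = sm$sd_relaxed, l = sm$sd_linear)
  for (sp in names(cols)) {
    graphics::points(sm$x, means[[sp]], pch = 19, col = cols[sp])
    graphics::arrows(sm$x, means[[sp]] - sds[[sp]], sm$x, means[[sp]] + sds[[sp]],
                     angle = 90, code = 3, length = 0.03, col = cols[sp])
    graphics::lines(pr$x, 100 * pr[[sp]], col = cols[sp])
  }
  graphics::legend("topright", legend = c("supercoiled", "relaxed", "linear"),
                   col = cols, pch = 19, lty = 1, bty = "n")
  invisible(x)
}

#' Simulate datasets from a fitted kinetic model
#'
#' Draws new gel datasets from the fitted rates with the same design grid
#' and replicate count as the fitted data, using the Gaussian noise model of
#' [simulate_gel_dataset()] with per-species SDs taken from the data.
#'
#' @param object a \code{topo_fit}.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of \code{nsim} [gel_dataset()] objects.
#' @export
simulate.topo_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sm <- object$summary_data
  cf <- object$coefficients
  sdv <- mean(c(sm$sd_supercoiled, sm$sd_relaxed, sm$sd_linear))
  if (!is.finite(sdv) || sdv <= 0) sdv <- 5
  n <- max(1L, as.integer(round(mean(sm$n))))
  if (is.null(seed)) seed <- 1L
  lapply(seq_len(nsim), function(i)
    simulate_gel_dataset(ksr = unname(cf["ksr"]), krl = unname(cf["krl"]),
                         ksl = if ("ksl" %in% names(cf)) unname(cf["ksl"]) else 0,
                         s0 = unname(cf["s0"]),
                         r0 = object$fixed$r0 %||% 0, l0 = object$fixed$l0 %||% 0,
                         grid = sm$x, n = n, sd = sdv,
                         axis = object$axis, seed = seed + i - 1L))
}
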
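# Empirical threshold estimation: detect the lactate-producing region of a
# flux dataset, fit a line there, and read the switch threshold off the
# x-intercept. Also derives respiration and ATP rates from measured
# oxidized-glucose fluxes and compares datasets against model predictions.

#' Construct a flux dataset
#'
#' Paired glucose-uptake / lactate-excretion measurements (optionally with
#' the oxidized-glucose rate), tagged with the unit system they were
#' reported in and any context needed to convert to mM/min.
#'
#' @param glucose_uptake,lactate_excretion numeric vectors of equal length,
#'   nonnegative.
#' @param oxidized_glucose optional numeric vector: glucose flux oxidized in
#'   mitochondria, same units.
#' @param unit_tag one of `"mM_per_min"`, `"per_cell_day"`,
#'   `"per_cell_hour"`, `"per_mass_hour"` (see [convert_rate()]).
#' @param context named list of conversion context (`cell_volume_um3` or
#'   `density_g_per_ml`) when `unit_tag` is not `"mM_per_min"`.
#' @return A `data.frame` of class `flux_dataset` with attributes
#'   `unit_tag` and `context`.
#' @export
flux_dataset <- function(glucose_uptake, lactate_excretion,
                         oxidized_glucose = NULL,
                         unit_tag = "mM_per_min", context = list()) {
  stopifnot(is.numeric(glucose_uptake), is.numeric(lactate_excretion),
            length(glucose_uptake) == length(lactate_excretion))
  if (any(glucose_uptake < 0) || any(lactate_excretion < 0))
    stop("rates must be nonnegative", call. = FALSE)
  if (!unit_tag %in% c("mM_per_min", "per_cell_day", "per_cell_hour",
                       "per_mass_hour"))
    stop("unknown unit tag: ", unit_tag, call. = FALSE)
  d <- data.frame(glucose_uptake = glucose_uptake,
                  lactate_excretion = lactate_excretion)
  if (!is.null(oxidized_glucose)) {
    stopifnot(is.numeric(oxidized_glucose),
              length(oxidized_glucose) == length(glucose_uptake))
    if (any(oxidized_glucose < 0))
      stop("rates must be nonnegative", call. = FALSE)
    d$oxidized_glucose <- oxidized_glucose
  }
  structure(d, unit_tag = unit_tag, context = context,
            class = c("flux_dataset", "data.frame"))
}

#' Convert a flux dataset to mM/min
#'
#' @param d a [flux_dataset()].
#' @return The same dataset with all rate columns converted to mM/min and
#'   `unit_tag` reset to `"mM_per_min"`.
#' @export
convert_dataset <- function(d) {
  stopifnot(inherits(d, "flux_dataset"))
  tag <- attr(d, "unit_tag")
  ctx <- attr(d, "context")
  flux_dataset(
    glucose_uptake = convert_rate(d$glucose_uptake, tag, ctx),
    lactate_excretion = convert_rate(d$lactate_excretion, tag, ctx),
    oxidized_glucose = if (!is.null(d$oxidized_glucose))
      convert_rate(d$oxidized_glucose, tag, ctx),
    unit_tag = "mM_per_min"
  )
}

#' Detect the lactate-producing (overflow) region
#'
#' Marks the records whose lactate excretion exceeds a cutoff: by default a
#' fraction (15%) of the dataset's maximum observed lactate excretion, or
#' an absolute cutoff when given. "Significant lactate production" has no
#' universal definition, so the cutoff is an explicit, overridable knob;
#' the default sits well above typical measurement noise (about 3 sd when
#' noise is 5% of the maximum) so baseline scatter cannot masquerade as
#' overflow. Records exactly at the cutoff are included.
#'
#' @param d a [flux_dataset()].
#' @param cutoff_frac cutoff as a fraction of the maximum observed lactate
#'   excretion (default 0.15).
#' @param cutoff_abs absolute cutoff in the dataset's own units; overrides
#'   `cutoff_frac` when non-NULL.
#' @return Logical mask over records, with attributes `cutoff` (the value
#'   used) and `no_overflow` (TRUE when no record passes — an outcome, not
#'   an error).
#' @export
detect_active_region <- function(d, cutoff_frac = 0.15, cutoff_abs = NULL) {
  stopifnot(inherits(d, "flux_dataset"))
  if (nrow(d) < 3) stop("need at least 3 records", call. = FALSE)
  cutoff <- if (!is.null(cutoff_abs)) cutoff_abs
            else cutoff_frac * max(d$lactate_excretion)
  mask <- d$lactate_excretion >= cutoff & d$lactate_excretion > 0
  structure(mask, cutoff = cutoff, no_overflow = !any(mask))
}

#' Fit the overflow threshold by linear regression
#'
#' Ordinary least squares of lactate excretion on glucose uptake over the
#' lactate-producing region; the threshold estimate is the x-intercept
#' f1_hat = -intercept/slope. An alternative `"hinge"` estimator jointly
#' fits a two-segment model max(0, slope * (f_G - f1)) to all records by
#' nonlinear least squares; the x-intercept line fit remains the default.
#'
#' @param d a [flux_dataset()] with at least 3 records.
#' @param cutoff_frac,cutoff_abs passed to [detect_active_region()].
#' @param method `"ols"` (default) or `"hinge"`.
#' @return An object of class `threshold_fit`: list with `f1_hat`, `slope`,
#'   `intercept`, `active_mask`, `residual_sd`, `n_active`, `method`,
#'   `unit_tag`.
#' @export
fit_threshold <- function(d, cutoff_frac = 0.15, cutoff_abs = NULL,
                          method = c("ols", "hinge")) {
  stopifnot(inherits(d, "flux_dataset"))
  method <- match.arg(method)
  mask <- detect_active_region(d, cutoff_frac = cutoff_frac,
                               cutoff_abs = cutoff_abs)
  if (attr(mask, "no_overflow"))
    stop("no overflow detected: no record passes the lactate cutoff",
         call. = FALSE)
  x <- d$glucose_uptake[mask]
  y <- d$lactate_excretion[mask]
  if (length(x) < 2 || length(unique(x)) < 2)
    stop("active region needs >= 2 records with distinct glucose uptakes",
         call. = FALSE)
  if (method == "ols") {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    resid_sd <- if (length(x) > 2)
      sqrt(sum(stats::residuals(fit)^2) / (length(x) - 2)) else 0
  } else {
    # joint hinge over all records, seeded from the OLS line
    ols <- stats::lm(y ~ x)
    b0 <- max(-stats::coef(ols)[1] / stats::coef(ols)[2], 0)
    s0 <- max(stats::coef(ols)[2], .Machine$double.eps)
    xs <- d$glucose_uptake
    ys <- d$lactate_excretion
    obj <- function(par) sum((ys - pmax(0, par[2] * (xs - par[1])))^2)
    opt <- stats::optim(c(b0, s0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    slope <- opt$par[2]
    intercept <- -opt$par[1] * opt$par[2]
    dof <- max(length(xs) - 2, 1)
    resid_sd <- sqrt(opt$value / dof)
  }
  if (!is.finite(slope) || slope <= 0)
    stop("fit failed: nonpositive slope; lactate excretion does not ",
         "increase with glucose uptake in the active region", call. = FALSE)
  structure(list(f1_hat = -intercept / slope, slope = slope,
                 intercept = intercept, active_mask = as.logical(mask),
                 residual_sd = resid_sd, n_active = sum(mask),
                 method = method, unit_tag = attr(d, "unit_tag")),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("Threshold fit (%s, %d active records, units %s)\n",
              x$method, x$n_active, x$unit_tag))
  cat(sprintf("  f1_hat = %.4g  slope = %.4g  intercept = %.4g  residual sd = %.3g\n",
              x$f1_hat, x$slope, x$intercept, x$residual_sd))
  invisible(x)
}

#' Derive respiration and ATP rates from measured fluxes
#'
#' When the oxidized-glucose rate is reported, the respiratory flux is
#' f_M = oxidized_glucose and the ATP production rate follows from the
#' flux balance: f_ATP = 2 glucose_uptake + 36 f_M.
#'
#' @param d a [flux_dataset()].
#' @return A list with `available` (logical) and, when available, `table`
#'   (`data.frame` with columns `f_M`, `f_ATP` per record); when the
#'   oxidized-glucose column is absent, `available = FALSE` with a `reason`
#'   — an outcome, not an error.
#' @export
derive_respiration_and_atp <- function(d) {
  stopifnot(inherits(d, "flux_dataset"))
  if (is.null(d$oxidized_glucose))
    return(list(available = FALSE,
                reason = "oxidized_glucose not measured in this dataset"))
  f_M <- d$oxidized_glucose
  list(available = TRUE,
       table = data.frame(f_M = f_M,
                          f_ATP = 2 * d$glucose_uptake + 36 * f_M))
}

#' Compare a flux dataset against the model prediction
#'
#' Converts the dataset to mM/min, fits the empirical overflow threshold
#' and slope, and sets them against the model's regime curve: pointwise
#' lactate residuals (observed minus the 2 f_L predicted at each uptake)
#' and the predicted post-threshold lactate slope
#' 2 (1 + (a_G + a_L)/(a_M - a_L)).
#'
#' @param d a [flux_dataset()] convertible to mM/min.
#' @param m a [crowding_model()].
#' @param cutoff_frac,cutoff_abs passed to [fit_threshold()].
#' @return A list: `fit` (the [fit_threshold()] result on the converted
#'   data), `predicted_slope`, `fitted_slope`, `residuals` (mM/min),
#'   `table` (per-record observed and predicted lactate excretion).
#' @export
compare_to_model <- function(d, m, cutoff_frac = 0.15, cutoff_abs = NULL) {
  stopifnot(inherits(d, "flux_dataset"), inherits(m, "crowding_model"))
  dc <- convert_dataset(d)
  pred <- vapply(dc$glucose_uptake,
                 function(F_G) 2 * optimal_fluxes(F_G, m)$f_L, numeric(1))
  resid <- dc$lactate_excretion - pred
  fit <- fit_threshold(dc, cutoff_frac = cutoff_frac, cutoff_abs = cutoff_abs)
  list(fit = fit,
       predicted_slope = predicted_lactate_slope(m),
       fitted_slope = fit$slope,
       residuals = resid,
       table = data.frame(glucose_uptake = dc$glucose_uptake,
                          observed_lactate = dc$lactate_excretion,
                          predicted_lactate = pred,
                          residual = resid))
}
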
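# Synthetic flux-data generation: hinge-shaped lactate-vs-glucose datasets
# with additive Gaussian noise, and datasets sampled around the model's own
# regime curve so model-vs-data comparisons have a known ground truth.
#
# The generator treats glucose uptake as the controlled variable (as in
# chemostat designs, where the dilution rate sets it) and puts noise on the
# excretion measurement only. Negative noisy excretions are truncated at 0.

#' Generate a hinge-shaped flux dataset
#'
#' Lactate excretion is zero below the breakpoint and linear above it:
#' lactate = max(0, lactate_slope * (f_G - f1_true)) + N(0, noise_sd),
#' truncated at 0. The uptake grid is either given explicitly or as `n`
#' equally spaced points on [0, uptake_max]. Deterministic for a fixed
#' seed; the seed scopes a local random stream and never touches global
#' state.
#'
#' @param f1_true true breakpoint (same units as the grid), > 0.
#' @param lactate_slope slope of the post-breakpoint line (dimensionless).
#' @param n number of grid points (>= 3) when `uptake_grid` is NULL.
#' @param uptake_max grid upper end; defaults to `3 * f1_true`.
#' @param uptake_grid explicit nonnegative uptake grid (overrides `n`).
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   lactate excretion, >= 0.
#' @param seed integer seed for the local random stream.
#' @param oxidized if TRUE (default) fill the oxidized-glucose column with
#'   the model-consistent value (2 f_G - lactate)/2, clamped at 0.
#' @param unit_tag,context unit system for the emitted dataset (the hinge
#'   is generated in these units directly).
#' @return A [flux_dataset()].
#' @export
generate_flux_dataset <- function(f1_true, lactate_slope, n = 20,
                                  uptake_max = 3 * f1_true,
                                  uptake_grid = NULL, noise_sd = 0,
                                  seed = 1L, oxidized = TRUE,
                                  unit_tag = "mM_per_min", context = list()) {
  stopifnot(f1_true > 0, lactate_slope > 0, noise_sd >= 0)
  if (is.null(uptake_grid)) {
    stopifnot(n >= 3)
    uptake_grid <- seq(0, uptake_max, length.out = n)
  }
  stopifnot(all(uptake_grid >= 0))
  lact0 <- pmax(0, lactate_slope * (uptake_grid - f1_true))
  lact <- withr::with_seed(as.integer(seed), {
    pmax(0, lact0 + stats::rnorm(length(uptake_grid), 0, noise_sd))
  })
  flux_dataset(
    glucose_uptake = uptake_grid,
    lactate_excretion = lact,
    oxidized_glucose = if (oxidized) pmax(0, (2 * uptake_grid - lact) / 2),
    unit_tag = unit_tag, context = context
  )
}

#' Generate a dataset around the model's regime curve
#'
#' The noiseless columns equal the [atp_curve()] output at the given grid;
#' independent Gaussian noise is then added to the lactate-excretion and
#' oxidized-glucose measurements (truncated at 0). Useful as ground truth
#' for [compare_to_model()].
#'
#' @param m a [crowding_model()].
#' @param uptake_grid sorted nonnegative uptake grid (mM/min).
#' @param noise_sd standard deviation of the measurement noise (mM/min).
#' @param seed integer seed for the local random stream.
#' @return A [flux_dataset()] in mM/min.
#' @export
generate_model_consistent_dataset <- function(m, uptake_grid, noise_sd = 0,
                                              seed = 1L) {
  stopifnot(inherits(m, "crowding_model"), noise_sd >= 0)
  curve <- atp_curve(uptake_grid, m)
  noisy <- withr::with_seed(as.integer(seed), {
    k <- nrow(curve)
    list(lact = pmax(0, curve$lactate_excretion + stats::rnorm(k, 0, noise_sd)),
         oxid = pmax(0, curve$f_M + stats::rnorm(k, 0, noise_sd)))
  })
  flux_dataset(glucose_uptake = curve$f_G,
               lactate_excretion = noisy$lact,
               oxidized_glucose = noisy$oxid,
               unit_tag = "mM_per_min")
}
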
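# Estimation chain from raw literature measurements (specific volumes,
# pathway rates per unit dry mass) to crowding coefficients, and the unit
# conversions that bring published flux data onto the canonical mM/min
# scale.

#' Round to significant figures, half to even
#'
#' The single arbiter used when matching values reported at a fixed number
#' of significant figures: several reported coefficients are 2-significant-
#' figure roundings of chained computations, so all such comparisons go
#' through this helper. Uses banker's (half-to-even) rounding, the IEEE-754
#' default.
#'
#' @param x numeric vector.
#' @param digits number of significant figures.
#' @return `x` rounded to `digits` significant figures.
#' @export
round_sig <- function(x, digits) {
  stopifnot(is.numeric(x), digits >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz]))) - (digits - 1)
  out[nz] <- round(x[nz] / 10^e) * 10^e
  out
}

#' Pathway rate per unit enzyme mass
#'
#' Converts a volumetric flux density and a protein concentration into a
#' rate per unit dry mass: `flux_density / protein_conc / stoich_divisor`,
#' with units cancelling from (umol/min/mL) / (mg/mL) to mmol/min/g. The
#' stoichiometric divisor maps a measured product rate onto the modeled
#' flux basis (e.g. 2 lactate per glucose when expressing a lactate
#' production rate as a glucose uptake rate).
#'
#' @param flux_density volumetric rate (umol/min/mL).
#' @param protein_conc enzyme concentration (mg/mL).
#' @param stoich_divisor dimensionless divisor, default 1.
#' @return rate per unit mass (mmol/min/g).
#' @export
pathway_rate_per_mass <- function(flux_density, protein_conc,
                                  stoich_divisor = 1) {
  stopifnot(is.numeric(flux_density), is.numeric(protein_conc),
            is.numeric(stoich_divisor))
  if (any(flux_density <= 0) || any(protein_conc <= 0) ||
      any(stoich_divisor <= 0))
    stop("all inputs must be strictly positive", call. = FALSE)
  flux_density / protein_conc / stoich_divisor
}

#' Raw kinetic inputs for one pathway
#'
#' @param v specific volume (mL per g dry mass).
#' @param r pathway rate per unit mass (mmol per min per g dry mass).
#' @param s stoichiometric multiplier mapping the pathway rate to the
#'   modeled flux: 1 for glycolysis, 2 for lactate production, 36 for
#'   mitochondrial ATP. Any positive value is accepted.
#' @return An object of class `enzyme_kinetics`.
#' @export
enzyme_kinetics <- function(v, r, s = 1) {
  stopifnot(is.numeric(v), is.numeric(r), is.numeric(s),
            length(v) == 1L, length(r) == 1L, length(s) == 1L)
  if (v <= 0 || r <= 0 || s <= 0)
    stop("v, r and s must be strictly positive", call. = FALSE)
  structure(list(v = v, r = r, s = s), class = "enzyme_kinetics")
}

#' Crowding coefficient from raw kinetics
#'
#' a = s * v / r, converted from mL min/mmol to min/mM (divide by 1000,
#' since 1 min/mM = 1000 mL min/mmol). Accepts either an
#' [enzyme_kinetics()] object or the three raw numbers.
#'
#' @param k an [enzyme_kinetics()] object, or the specific volume `v`
#'   (mL/g) when `r` is given.
#' @param v,r,s raw inputs, used when `k` is not supplied.
#' @return crowding coefficient (min/mM).
#' @export
crowding_coefficient <- function(k = NULL, v = NULL, r = NULL, s = 1) {
  if (inherits(k, "enzyme_kinetics")) {
    v <- k$v; r <- k$r; s <- k$s
  } else if (!is.null(k)) {
    stop("first argument must be an enzyme_kinetics object; ",
         "pass raw numbers as v=, r=, s=", call. = FALSE)
  }
  k <- enzyme_kinetics(v = v, r = r, s = s)  # validates
  k$s * k$v / k$r / 1000
}

#' Range of available volume fractions
#'
#' @param lo,hi endpoints of the cytoplasmic volume fraction available to
#'   ATP-producing machinery, 0 < lo <= hi < 1.
#' @return An object of class `phi_range`.
#' @export
phi_range <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo > 0 && lo <= hi && hi < 1))
    stop("need 0 < lo <= hi < 1", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "phi_range")
}

#' Predicted switch-threshold range over a volume-fraction range
#'
#' Evaluates [threshold_f1()] at both endpoints of the available volume
#' fraction, holding the glycolytic and mitochondrial crowding coefficients
#' fixed.
#'
#' @param phi a [phi_range()].
#' @param a_G glycolytic crowding coefficient (min/mM).
#' @param a_M mitochondrial crowding coefficient (min/mM).
#' @return Named numeric vector `c(lo=, hi=)` in mM/min.
#' @export
f1_range <- function(phi, a_G, a_M) {
  stopifnot(inherits(phi, "phi_range"))
  lo <- threshold_f1(crowding_model(a_G = a_G, a_L = a_M / 2, a_M = a_M,
                                    phi_ATP = phi$lo))
  hi <- threshold_f1(crowding_model(a_G = a_G, a_L = a_M / 2, a_M = a_M,
                                    phi_ATP = phi$hi))
  c(lo = lo, hi = hi)
}

# --- unit conversions to the canonical mM/min basis -------------------------

.time_to_minutes <- c(day = 1440, hour = 60, minute = 1)
.amount_to_mmol <- c(mmol = 1, umol = 1e-3)

#' Convert a per-cell rate to mM/min
#'
#' Divides the total excreted/consumed amount by the total cell volume
#' (count x volume, 1 um^3 = 1e-15 L) and rescales time to minutes, so a
#' rate reported per cell count per day or hour becomes an intracellular
#' concentration change in mM/min.
#'
#' @param rate amount per `cell_count_basis` cells per `time_unit`.
#' @param amount_unit `"umol"` or `"mmol"`.
#' @param cell_count_basis the cell count the rate is normalized to
#'   (e.g. 1e6 or 1e9).
#' @param cell_volume_um3 typical single-cell volume (um^3).
#' @param time_unit `"day"`, `"hour"` or `"minute"`.
#' @return rate in mM/min.
#' @export
convert_per_cell_rate <- function(rate, amount_unit = c("umol", "mmol"),
                                  cell_count_basis, cell_volume_um3,
                                  time_unit = c("day", "hour", "minute")) {
  amount_unit <- match.arg(amount_unit)
  time_unit <- match.arg(time_unit)
  stopifnot(is.numeric(rate), is.numeric(cell_count_basis),
            is.numeric(cell_volume_um3))
  if (any(rate < 0)) stop("rate must be nonnegative", call. = FALSE)
  if (cell_count_basis <= 0 || cell_volume_um3 <= 0)
    stop("cell count and volume must be positive", call. = FALSE)
  total_volume_L <- cell_count_basis * cell_volume_um3 * 1e-15
  mmol <- rate * .amount_to_mmol[[amount_unit]]
  mmol / total_volume_L / .time_to_minutes[[time_unit]]
}

#' Convert a per-dry-mass rate to mM/min
#'
#' rate (mmol per g per hour) x density (g per mL) gives mmol per mL per
#' hour; x1000 mL/L and /60 min/hour yields mmol per L per minute, i.e.
#' mM/min.
#'
#' @param rate mmol per g per hour.
#' @param density_g_per_ml cell density (g/mL).
#' @return rate in mM/min.
#' @export
convert_per_mass_rate <- function(rate, density_g_per_ml) {
  stopifnot(is.numeric(rate), is.numeric(density_g_per_ml))
  if (any(rate < 0)) stop("rate must be nonnegative", call. = FALSE)
  if (density_g_per_ml <= 0) stop("density must be positive", call. = FALSE)
  rate * density_g_per_ml * 1000 / 60
}

#' Convert a rate to mM/min by unit tag
#'
#' Dispatcher over the supported unit systems. `context` supplies whatever
#' the tag needs: `cell_volume_um3` for the per-cell bases,
#' `density_g_per_ml` for the per-mass basis. Unknown tags and missing
#' context are errors, never silent assumptions.
#'
#' @param rate numeric vector of rates.
#' @param unit_tag one of `"mM_per_min"` (identity), `"per_cell_day"`
#'   (umol per 1e6 cells per day), `"per_cell_hour"` (mmol per 1e9 cells
#'   per hour), `"per_mass_hour"` (mmol per g per hour).
#' @param context named list of conversion context.
#' @return rate(s) in mM/min.
#' @export
convert_rate <- function(rate, unit_tag, context = list()) {
  stopifnot(is.character(unit_tag), length(unit_tag) == 1L)
  switch(unit_tag,
    mM_per_min = rate,
    per_cell_day = {
      if (is.null(context$cell_volume_um3))
        stop("per_cell_day conversion needs context$cell_volume_um3", call. = FALSE)
      convert_per_cell_rate(rate, "umol", 1e6, context$cell_volume_um3, "day")
    },
    per_cell_hour = {
      if (is.null(context$cell_volume_um3))
        stop("per_cell_hour conversion needs context$cell_volume_um3", call. = FALSE)
      convert_per_cell_rate(rate, "mmol", 1e9, context$cell_volume_um3, "hour")
    },
    per_mass_hour = {
      if (is.null(context$density_g_per_ml))
        stop("per_mass_hour conversion needs context$density_g_per_ml", call. = FALSE)
      convert_per_mass_rate(rate, context$density_g_per_ml)
    },
    stop("unknown unit tag: ", unit_tag, call. = FALSE)
  )
}

#' Run the full literature estimation chain
#'
#' From per-pathway raw blocks (specific volume v, rate per mass r,
#' stoichiometric multiplier s) and a volume-fraction range, derives the
#' three crowding coefficients, builds a [crowding_model()] at the lower
#' volume-fraction endpoint, and evaluates the predicted switch-threshold
#' range. Every arithmetic step is recorded in an `audit` attribute so the
#' chain from raw numbers to derived parameters is reproducible line by
#' line.
#'
#' @param glycolysis,ldh,mito lists with elements `v`, `r`, `s` (see
#'   [enzyme_kinetics()]).
#' @param phi a [phi_range()].
#' @return A list with elements `model` (a [crowding_model()] at
#'   `phi$lo`), `coefficients` (named vector a_G, a_L, a_M) and `f1_range`
#'   (mM/min), with attribute `audit` (character vector).
#' @export
estimate_crowding_parameters <- function(glycolysis, ldh, mito, phi) {
  ks <- list(glycolysis = glycolysis, ldh = ldh, mito = mito)
  audit <- character()
  a <- vapply(names(ks), function(nm) {
    k <- ks[[nm]]
    ki <- enzyme_kinetics(v = k$v, r = k$r, s = if (is.null(k$s)) 1 else k$s)
    ai <- crowding_coefficient(ki)
    audit <<- c(audit, sprintf(
      "a[%s] = %g * %g / %g / 1000 = %.6g min/mM", nm, ki$s, ki$v, ki$r, ai))
    ai
  }, numeric(1))
  model <- crowding_model(a_G = a[["glycolysis"]], a_L = a[["ldh"]],
                          a_M = a[["mito"]], phi_ATP = phi$lo)
  fr <- f1_range(phi, a_G = a[["glycolysis"]], a_M = a[["mito"]])
  audit <- c(audit, sprintf(
    "f1 = phi/(a_G + a_M): [%g, %g] / (%.6g + %.6g) = [%.6g, %.6g] mM/min",
    phi$lo, phi$hi, a[["glycolysis"]], a[["mito"]], fr[["lo"]], fr[["hi"]]))
  structure(list(model = model,
                 coefficients = c(a_G = a[["glycolysis"]], a_L = a[["ldh"]],
                                  a_M = a[["mito"]]),
                 f1_range = fr),
            audit = audit)
}
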
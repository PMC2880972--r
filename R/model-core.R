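# Core reduced flux-balance model: ATP production from glucose partitioned
# between aerobic glycolysis (2 ATP/glucose) and oxidative phosphorylation
# (38 ATP/glucose), constrained by the glucose uptake capacity and by the
# cytoplasmic solvent capacity (molecular crowding).
#
# Canonical internal units: all fluxes mM/min (= mmol L^-1 min^-1), all
# crowding coefficients min/mM, volume fractions dimensionless.

#' Numerical tolerances used throughout the package
#'
#' Single table of the package's numerical constants: the feasibility
#' tolerance of the vertex-enumeration linear-program oracle, the agreement
#' tolerance between the analytic optimum and the oracle, the relative
#' tolerance on the flux-balance identity f_G = f_L + f_M, and the relative
#' tolerance at which the two algebraic forms of the ATP rate must agree.
#'
#' @return Named list of tolerances.
#' @export
fba_tolerances <- function() {
  list(
    lp_feasibility = 1e-9,
    oracle_agreement = 1e-7,
    partition_balance_rel = 1e-9,
    atp_algebra_rel = 1e-12
  )
}

#' Fixed ATP yields of the two catabolic pathways
#'
#' Aerobic glycolysis (glucose -> 2 lactate) yields 2 mol ATP per mol
#' glucose; oxidative phosphorylation (glycolysis + TCA cycle + respiratory
#' chain) yields 38, of which 36 are the mitochondrial surplus over
#' glycolysis.
#'
#' @return Named list with `y_glycolysis` (2), `y_oxphos` (38) and
#'   `y_mito_extra` (36); always `y_oxphos == y_glycolysis + y_mito_extra`.
#' @export
pathway_yields <- function() {
  list(y_glycolysis = 2, y_oxphos = 38, y_mito_extra = 36)
}

#' Construct a crowding model
#'
#' Bundles the three crowding coefficients (occupied cytoplasmic volume
#' fraction per unit of pathway flux, min/mM) and the cytoplasmic volume
#' fraction available to ATP-producing machinery.
#'
#' @param a_G crowding coefficient of the glycolytic enzymes (min/mM).
#' @param a_L crowding coefficient of lactate dehydrogenase (min/mM).
#' @param a_M crowding coefficient of mitochondria (min/mM); must exceed
#'   `a_L`, otherwise the space-limited optimum is undefined.
#' @param phi_ATP volume fraction of the cytoplasm available to the ATP
#'   producing pathways, strictly between 0 and 1.
#' @return An object of class `crowding_model`.
#' @export
crowding_model <- function(a_G, a_L, a_M, phi_ATP) {
  stopifnot(
    is.numeric(a_G), length(a_G) == 1L, is.finite(a_G),
    is.numeric(a_L), length(a_L) == 1L, is.finite(a_L),
    is.numeric(a_M), length(a_M) == 1L, is.finite(a_M),
    is.numeric(phi_ATP), length(phi_ATP) == 1L, is.finite(phi_ATP)
  )
  if (a_G <= 0 || a_L <= 0 || a_M <= 0)
    stop("crowding coefficients must be strictly positive", call. = FALSE)
  if (a_M <= a_L)
    stop("a_M must exceed a_L: the mixed-regime flux split divides by a_M - a_L",
         call. = FALSE)
  if (phi_ATP <= 0 || phi_ATP >= 1)
    stop("phi_ATP must lie strictly between 0 and 1", call. = FALSE)
  structure(list(a_G = a_G, a_L = a_L, a_M = a_M, phi_ATP = phi_ATP),
            class = "crowding_model")
}

#' @export
print.crowding_model <- function(x, ...) {
  cat("Crowding model (units min/mM; phi dimensionless)\n")
  cat(sprintf("  a_G = %g  a_L = %g  a_M = %g  phi_ATP = %g\n",
              x$a_G, x$a_L, x$a_M, x$phi_ATP))
  cat(sprintf("  f1 = %g mM/min  f2 = %g mM/min\n",
              threshold_f1(x), threshold_f2(x)))
  invisible(x)
}

#' Built-in parameter profiles
#'
#' Two coefficient sets derived from the literature estimation chain (see
#' [crowding_coefficient()]): `"printed"` keeps each coefficient at the
#' two-significant-figure precision customarily reported (a_G = 0.0027,
#' a_L = 0.00023, a_M = 0.10 min/mM), `"full_precision"` recomputes them
#' from the raw inputs (v_G = v_L = 0.79 mL/g, r_G = 23/40/2, r_L = 23/3.2
#' mmol/min/g; v_M = 2.9 mL/g, r_M = 1.0 mmol/min/g), e.g.
#' a_M = 36 * 2.9 / 1.0 / 1000 = 0.1044 min/mM.
#'
#' @param name `"printed"` or `"full_precision"`.
#' @param phi_ATP available volume fraction; defaults to 0.07, the lower
#'   endpoint of the reported mitochondrial volume-fraction range 0.07-0.38.
#' @return A [crowding_model()].
#' @export
crowding_profile <- function(name = c("printed", "full_precision"),
                             phi_ATP = 0.07) {
  name <- match.arg(name)
  if (name == "printed") {
    crowding_model(a_G = 0.0027, a_L = 0.00023, a_M = 0.10, phi_ATP = phi_ATP)
  } else {
    crowding_model(
      a_G = crowding_coefficient(v = 0.79, r = pathway_rate_per_mass(23, 40, 2), s = 1),
      a_L = crowding_coefficient(v = 0.79, r = pathway_rate_per_mass(23, 3.2, 1), s = 2),
      a_M = crowding_coefficient(v = 2.9, r = 1.0, s = 36),
      phi_ATP = phi_ATP
    )
  }
}

#' Construct a flux partition
#'
#' A feasible point of the reduced model: glucose uptake `f_G` split into a
#' lactate-excretion component `f_L` and a mitochondrial respiration
#' component `f_M`, all in mM/min. The flux balance f_G = f_L + f_M must
#' hold to within the package's relative tolerance.
#'
#' @param f_G glucose uptake rate (mM/min); if missing, computed as
#'   `f_L + f_M`.
#' @param f_L glucose flux routed to lactate excretion (mM/min).
#' @param f_M glucose flux routed to respiration (mM/min).
#' @return An object of class `flux_partition`.
#' @export
flux_partition <- function(f_L, f_M, f_G = f_L + f_M) {
  stopifnot(is.numeric(f_G), is.numeric(f_L), is.numeric(f_M),
            length(f_G) == 1L, length(f_L) == 1L, length(f_M) == 1L,
            is.finite(f_G), is.finite(f_L), is.finite(f_M))
  if (f_G < 0 || f_L < 0 || f_M < 0)
    stop("fluxes must be nonnegative", call. = FALSE)
  tol <- fba_tolerances()$partition_balance_rel
  if (abs(f_G - (f_L + f_M)) > tol * max(1, abs(f_G)))
    stop("flux balance violated: f_G must equal f_L + f_M", call. = FALSE)
  structure(list(f_G = f_G, f_L = f_L, f_M = f_M), class = "flux_partition")
}

#' ATP production rate of a flux partition
#'
#' f_ATP = 2 f_L + 38 f_M, equivalently 2 f_G + 36 f_M via the flux balance
#' f_G = f_L + f_M. Both algebraic forms are evaluated and must agree to the
#' package's relative tolerance.
#'
#' @param p a [flux_partition()].
#' @return ATP production rate (mM ATP/min).
#' @export
atp_rate <- function(p) {
  if (!inherits(p, "flux_partition"))
    p <- flux_partition(f_L = p$f_L, f_M = p$f_M, f_G = p$f_G)
  y <- pathway_yields()
  r1 <- y$y_glycolysis * p$f_L + y$y_oxphos * p$f_M
  r2 <- y$y_glycolysis * p$f_G + y$y_mito_extra * p$f_M
  if (abs(r1 - r2) > fba_tolerances()$atp_algebra_rel * max(1, abs(r1)))
    stop("internal inconsistency: the two ATP-rate forms disagree", call. = FALSE)
  r1
}

#' Cytoplasmic volume fraction occupied by the ATP machinery
#'
#' The left-hand side of the crowding constraint:
#' a_G f_G + a_L f_L + a_M f_M. Feasibility requires it not to exceed
#' `phi_ATP`; at any space-limited optimum it equals `phi_ATP` exactly.
#'
#' @param p a [flux_partition()].
#' @param m a [crowding_model()].
#' @return Occupied volume fraction (dimensionless).
#' @export
crowding_usage <- function(p, m) {
  stopifnot(inherits(m, "crowding_model"))
  if (!inherits(p, "flux_partition"))
    p <- flux_partition(f_L = p$f_L, f_M = p$f_M, f_G = p$f_G)
  m$a_G * p$f_G + m$a_L * p$f_L + m$a_M * p$f_M
}

#' Switch threshold: onset of aerobic glycolysis
#'
#' The glucose uptake rate at which mitochondria fill the entire available
#' volume fraction and lactate excretion first becomes optimal:
#' f1 = phi_ATP / (a_G + a_M), obtained by setting f_M = f_G, f_L = 0 in the
#' crowding constraint at equality.
#'
#' @param m a [crowding_model()].
#' @return Threshold uptake rate (mM/min).
#' @export
threshold_f1 <- function(m) {
  stopifnot(inherits(m, "crowding_model"))
  m$phi_ATP / (m$a_G + m$a_M)
}

#' Upper threshold: extinction of respiration
#'
#' The uptake rate at which the space-limited optimum drives the
#' respiratory flux to zero: f2 = phi_ATP / (a_G + a_L). Always exceeds
#' [threshold_f1()] since a_L < a_M.
#'
#' @param m a [crowding_model()].
#' @return Upper threshold uptake rate (mM/min).
#' @export
threshold_f2 <- function(m) {
  stopifnot(inherits(m, "crowding_model"))
  m$phi_ATP / (m$a_G + m$a_L)
}

#' Is lactate overflow ever optimal for this parameter set?
#'
#' The metabolic switch exists only when aerobic glycolysis produces more
#' ATP per unit of occupied solvent capacity than oxidative
#' phosphorylation: 2 / (a_G + a_L) > 38 / (a_G + a_M), equivalently
#' a_M - a_L > 18 (a_G + a_L). When this fails, diverting glucose to
#' lactate never pays and the optimum stays at pure respiration pinned at
#' [threshold_f1()] for every uptake capacity above it. Measured mammalian
#' coefficients satisfy the condition by a wide margin (mitochondria are
#' bulky per unit flux).
#'
#' @param m a [crowding_model()].
#' @return TRUE when overflow is part of the optimal strategy above f1.
#' @export
overflow_favorable <- function(m) {
  stopifnot(inherits(m, "crowding_model"))
  (m$a_M - m$a_L) > 18 * (m$a_G + m$a_L)
}

#' Analytic ATP-optimal flux partition at a given uptake capacity
#'
#' Maximizes the ATP production rate subject to f_L + f_M <= F_G and the
#' crowding constraint. Below [threshold_f1()] the optimum is pure
#' respiration (f_M = F_G, f_L = 0, glucose-limited regime). Above f1 the
#' crowding constraint binds (space-limited regime): when overflow is
#' favorable ([overflow_favorable()]) the fluxes follow
#' f_M = (phi_ATP - (a_G + a_L) F_G) / (a_M - a_L), f_L = F_G - f_M up to
#' [threshold_f2()]; otherwise the optimum stays at (f_L, f_M) = (0, f1).
#' Uptake capacity that cannot raise the ATP rate — beyond f2, or beyond f1
#' for overflow-unfavorable parameters — is left unused: glucose
#' utilization is capped and the returned partition carries
#' `capped = TRUE`, since taking up glucose that cannot be catabolized has
#' no objective benefit in this model.
#'
#' @param F_G maximum glucose uptake rate (mM/min), nonnegative.
#' @param m a [crowding_model()].
#' @return A [flux_partition()] with additional fields `regime`
#'   (`"glucose-limited"` or `"space-limited"`) and `capped` (logical).
#' @export
optimal_fluxes <- function(F_G, m) {
  stopifnot(inherits(m, "crowding_model"), is.numeric(F_G), length(F_G) == 1L,
            is.finite(F_G))
  if (F_G < 0) stop("F_G must be nonnegative", call. = FALSE)
  f1 <- threshold_f1(m)
  f2 <- threshold_f2(m)
  capped <- FALSE
  if (F_G <= f1) {
    f_M <- F_G
    f_L <- 0
    regime <- "glucose-limited"
  } else {
    regime <- "space-limited"
    if (!overflow_favorable(m)) {
      # lactate never pays: respiration pinned at the crowding limit
      F_G <- f1
      f_M <- f1
      f_L <- 0
      capped <- TRUE
    } else {
      if (F_G > f2) {
        F_G <- f2
        capped <- TRUE
      }
      f_M <- (m$phi_ATP - (m$a_G + m$a_L) * F_G) / (m$a_M - m$a_L)
      f_M <- max(f_M, 0)  # guards tiny negative rounding at F_G == f2
      f_L <- F_G - f_M
    }
  }
  p <- flux_partition(f_L = f_L, f_M = f_M, f_G = F_G)
  p$regime <- regime
  p$capped <- capped
  p
}

#' Linear-program oracle by vertex enumeration
#'
#' Independent verifier of [optimal_fluxes()]: solves the two-variable
#' linear program in (f_L, f_M) -- maximize 2 f_L + 38 f_M subject to
#' f_L + f_M <= F_G, a_G (f_L + f_M) + a_L f_L + a_M f_M <= phi_ATP,
#' f_L >= 0, f_M >= 0 -- by enumerating every pairwise intersection of
#' constraint boundaries, keeping the feasible vertices (feasibility
#' tolerance from [fba_tolerances()]) and returning the objective-maximizing
#' one, ties broken toward larger f_M.
#'
#' @param F_G maximum glucose uptake rate (mM/min), nonnegative.
#' @param m a [crowding_model()].
#' @return A [flux_partition()].
#' @export
lp_solve_oracle <- function(F_G, m) {
  stopifnot(inherits(m, "crowding_model"), is.numeric(F_G), length(F_G) == 1L,
            is.finite(F_G))
  if (F_G < 0) stop("F_G must be nonnegative", call. = FALSE)
  # constraint rows: A %*% c(f_L, f_M) <= b
  A <- rbind(c(1, 1),
             c(m$a_G + m$a_L, m$a_G + m$a_M),
             c(-1, 0),
             c(0, -1))
  b <- c(F_G, m$phi_ATP, 0, 0)
  tol <- fba_tolerances()$lp_feasibility
  obj <- c(2, 38)
  best <- NULL
  best_val <- -Inf
  for (i in 1:3) for (j in (i + 1):4) {
    M <- A[c(i, j), , drop = FALSE]
    if (abs(det(M)) < 1e-14) next
    x <- solve(M, b[c(i, j)])
    if (any(A %*% x > b + tol * pmax(1, abs(b)))) next
    v <- sum(obj * x)
    if (v > best_val + tol || (v > best_val - tol && !is.null(best) && x[2] > best[2])) {
      best <- x
      best_val <- v
    }
  }
  # the origin is always feasible, so best is never NULL
  flux_partition(f_L = max(best[1], 0), f_M = max(best[2], 0))
}

#' Regime curve over a grid of uptake capacities
#'
#' Applies [optimal_fluxes()] and [atp_rate()] row-wise over a sorted grid
#' of glucose uptake capacities, labelling each row `"glucose-limited"`
#' (F_G <= f1) or `"space-limited"`.
#'
#' @param uptake_grid nondecreasing vector of nonnegative uptake rates
#'   (mM/min).
#' @param m a [crowding_model()].
#' @return `data.frame` with columns `f_G`, `f_L`, `f_M`,
#'   `lactate_excretion` (= 2 f_L), `f_ATP`, `regime`.
#' @export
atp_curve <- function(uptake_grid, m) {
  stopifnot(inherits(m, "crowding_model"), is.numeric(uptake_grid),
            length(uptake_grid) >= 1L, all(is.finite(uptake_grid)))
  if (any(uptake_grid < 0))
    stop("uptake grid must be nonnegative", call. = FALSE)
  if (is.unsorted(uptake_grid))
    stop("uptake grid must be sorted nondecreasing", call. = FALSE)
  rows <- lapply(uptake_grid, function(F_G) {
    p <- optimal_fluxes(F_G, m)
    data.frame(f_G = p$f_G, f_L = p$f_L, f_M = p$f_M,
               lactate_excretion = 2 * p$f_L, f_ATP = atp_rate(p),
               regime = p$regime, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model-predicted slope of lactate excretion versus glucose uptake
#'
#' In the space-limited regime the lactate excretion rate 2 f_L grows
#' linearly in F_G with slope 2 (1 + (a_G + a_L) / (a_M - a_L)); with the
#' printed coefficient profile this is ~2.06, slightly above the
#' stoichiometric 2 because respiration recedes as glycolytic machinery
#' displaces mitochondria.
#'
#' @param m a [crowding_model()].
#' @return Dimensionless slope.
#' @export
predicted_lactate_slope <- function(m) {
  stopifnot(inherits(m, "crowding_model"))
  2 * (1 + (m$a_G + m$a_L) / (m$a_M - m$a_L))
}
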
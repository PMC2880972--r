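# Shared generators for property-style tests.

# Random valid crowding model: log-uniform coefficients spanning 1e-4..1
# min/mM with a_M > a_L enforced by swapping, phi uniform in (0.01, 0.5).
# With require_overflow, rejection-sample until lactate overflow is part of
# the optimal strategy (the two-regime phenomenology exists only there).
random_model <- function(require_overflow = FALSE) {
  repeat {
    a <- 10^stats::runif(3, -4, 0)
    a_L <- min(a[2], a[3])
    a_M <- max(a[2], a[3])
    if (a_M == a_L) a_M <- a_L * 2
    m <- crowding_model(a_G = a[1], a_L = a_L, a_M = a_M,
                        phi_ATP = stats::runif(1, 0.01, 0.5))
    if (!require_overflow || overflow_favorable(m)) return(m)
  }
}

printed_model <- function(phi_ATP = 0.07) crowding_profile("printed", phi_ATP)

# Smallest F_G at which the LP oracle first routes flux to lactate,
# located by bisection; independent of the closed-form threshold.
lp_switch_point <- function(m, what = c("f_L_on", "f_M_off"), tol = 1e-10) {
  what <- match.arg(what)
  crit <- function(F_G) {
    p <- lp_solve_oracle(F_G, m)
    if (what == "f_L_on") p$f_L > 1e-9 else p$f_M < 1e-9
  }
  hi <- 10 * m$phi_ATP / m$a_G  # far beyond any switch
  # for respiration extinction start above zero: at F = 0 the origin
  # trivially has f_M = 0
  lo <- if (what == "f_M_off") 1e-6 * hi else 0
  stopifnot(!crit(lo), crit(hi))
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (crit(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
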
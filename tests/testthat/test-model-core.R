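test_that("ATP rate reproduces the pathway yields and both algebraic forms", {
  expect_equal(atp_rate(flux_partition(f_L = 0, f_M = 1)), 38)
  expect_equal(atp_rate(flux_partition(f_L = 1, f_M = 0)), 2)
  expect_equal(atp_rate(flux_partition(f_L = 0, f_M = 0)), 0)
  # 2 f_L + 38 f_M == 2 f_G + 36 f_M for random partitions
  withr::with_seed(11, {
    for (i in 1:50) {
      fl <- runif(1, 0, 5); fm <- runif(1, 0, 5)
      p <- flux_partition(f_L = fl, f_M = fm)
      expect_equal(atp_rate(p), 2 * p$f_G + 36 * fm, tolerance = 1e-12)
    }
  })
})

test_that("flux partitions enforce nonnegativity and flux balance", {
  expect_error(flux_partition(f_L = -1, f_M = 2), "nonnegative")
  expect_error(flux_partition(f_L = 1, f_M = 1, f_G = 3), "flux balance")
  p <- flux_partition(f_L = 1, f_M = 2)
  expect_equal(p$f_G, 3)
})

test_that("crowding usage is the exact weighted sum of fluxes", {
  m <- printed_model(0.2)
  expect_equal(crowding_usage(flux_partition(0, 0), m), 0)
  withr::with_seed(21, {
    for (i in 1:25) {
      fl <- runif(1, 0, 3); fm <- runif(1, 0, 3)
      p <- flux_partition(f_L = fl, f_M = fm)
      # term-by-term oracle
      expect_equal(crowding_usage(p, m),
                   m$a_G * (fl + fm) + m$a_L * fl + m$a_M * fm,
                   tolerance = 1e-14)
    }
  })
})

test_that("model validation rejects degenerate parameter sets", {
  expect_error(crowding_model(0.0027, 0.1, 0.1, 0.2), "a_M must exceed a_L")
  expect_error(crowding_model(-1, 0.001, 0.1, 0.2), "strictly positive")
  expect_error(crowding_model(0.0027, 0.00023, 0.1, 1.2), "between 0 and 1")
})

test_that("switch threshold matches the closed form and the LP switch point", {
  m <- crowding_model(a_G = 0.0027, a_L = 0.00023, a_M = 0.10, phi_ATP = 0.07)
  expect_equal(threshold_f1(m), 0.07 / (0.0027 + 0.10), tolerance = 1e-12)
  expect_equal(round(threshold_f1(m), 1), 0.7)
  # independent location of the switch: bisection on the LP oracle's f_L
  m2 <- crowding_model(a_G = 0.0027, a_L = 0.00023, a_M = 0.1044,
                       phi_ATP = 0.2)
  expect_equal(lp_switch_point(m2, "f_L_on"), threshold_f1(m2),
               tolerance = 1e-6)
})

test_that("upper threshold exceeds the switch and matches LP respiration extinction", {
  m <- crowding_model(a_G = 0.0027, a_L = 0.00023, a_M = 0.1044,
                      phi_ATP = 0.2)
  expect_equal(lp_switch_point(m, "f_M_off"), threshold_f2(m),
               tolerance = 1e-6)
  withr::with_seed(31, {
    for (i in 1:50) {
      mi <- random_model()
      expect_gt(threshold_f2(mi), threshold_f1(mi))
    }
  })
})

test_that("optimal fluxes: pure respiration below f1, continuity at f1, mixed above", {
  m <- printed_model(0.2)
  f1 <- threshold_f1(m)
  p <- optimal_fluxes(0.5 * f1, m)
  expect_equal(p$f_L, 0)
  expect_equal(p$f_M, 0.5 * f1)
  expect_identical(p$regime, "glucose-limited")
  # continuity: both branches agree at the boundary
  at <- optimal_fluxes(f1, m)
  just_above <- optimal_fluxes(f1 * (1 + 1e-12), m)
  expect_equal(at$f_L, 0, tolerance = 1e-9)
  expect_equal(just_above$f_M, at$f_M, tolerance = 1e-9)
  # worked mixed-regime point against the closed form and the LP oracle
  m2 <- crowding_model(0.0027, 0.00023, 0.1044, 0.2)
  p3 <- optimal_fluxes(3, m2)
  expect_equal(p3$f_M, (0.2 - (0.0027 + 0.00023) * 3) / (0.1044 - 0.00023),
               tolerance = 1e-12)
  expect_equal(p3$f_L, 3 - p3$f_M, tolerance = 1e-12)
  o3 <- lp_solve_oracle(3, m2)
  expect_equal(p3$f_L, o3$f_L, tolerance = 1e-7)
  expect_equal(p3$f_M, o3$f_M, tolerance = 1e-7)
})

test_that("uptake beyond the respiration-extinction point is capped and flagged", {
  m <- printed_model(0.2)
  f2 <- threshold_f2(m)
  p <- optimal_fluxes(2 * f2, m)
  expect_true(p$capped)
  expect_equal(p$f_M, 0, tolerance = 1e-9)
  expect_equal(p$f_L, f2, tolerance = 1e-9)
  expect_false(optimal_fluxes(0.9 * f2, m)$capped)
  expect_error(optimal_fluxes(-1, m), "nonnegative")
})

test_that("LP oracle hits the uptake-limited and crowding-limited corners", {
  m <- crowding_model(0.0027, 0.00023, 0.10, phi_ATP = 0.9)  # crowding slack
  p <- lp_solve_oracle(1, m)
  expect_equal(p$f_M, 1, tolerance = 1e-9)
  expect_equal(p$f_L, 0, tolerance = 1e-9)
  m2 <- printed_model(0.07)
  p2 <- lp_solve_oracle(1e6, m2)  # uptake constraint slack
  expect_equal(p2$f_M, 0, tolerance = 1e-6)
  expect_equal(p2$f_L, threshold_f2(m2), tolerance = 1e-6)
})

test_that("analytic optimum agrees with the vertex-enumeration oracle on random models", {
  tol <- fba_tolerances()$oracle_agreement
  withr::with_seed(42, {
    for (i in 1:300) {
      m <- random_model()
      F_G <- runif(1, 0, 1.5 * threshold_f2(m))
      a <- optimal_fluxes(F_G, m)
      b <- lp_solve_oracle(min(F_G, threshold_f2(m)), m)
      expect_equal(a$f_L, b$f_L, tolerance = tol)
      expect_equal(a$f_M, b$f_M, tolerance = tol)
      expect_equal(a$f_G, b$f_G, tolerance = tol)
    }
  })
})

test_that("flux curves have the predicted two-regime shape", {
  withr::with_seed(52, {
    for (i in 1:20) {
      m <- random_model(require_overflow = TRUE)
      f1 <- threshold_f1(m)
      f2 <- threshold_f2(m)
      grid <- sort(c(seq(0, 1.2 * f2, length.out = 80), f1, f2))
      cv <- atp_curve(grid, m)
      below <- cv$f_G <= f1 + 1e-12
      expect_true(all(cv$f_L[below] == 0))
      above <- cv$f_G > f1 * (1 + 1e-9)
      expect_true(all(diff(cv$f_L[above]) > -1e-12))
      expect_true(all(cv$f_L[above] > 0))
      # f_M rises to f1 then recedes
      expect_true(all(diff(cv$f_M[below]) >= -1e-12))
      expect_true(all(diff(cv$f_M[!below]) <= 1e-12))
      # f_ATP nondecreasing, yield between 2 and 38
      expect_true(all(diff(cv$f_ATP) >= -1e-9))
      pos <- cv$f_G > 0
      yield <- cv$f_ATP[pos] / cv$f_G[pos]
      expect_true(all(yield >= 2 - 1e-9 & yield <= 38 + 1e-9))
    }
  })
})

test_that("crowding constraint is active exactly in the space-limited window", {
  withr::with_seed(62, {
    for (i in 1:20) {
      m <- random_model(require_overflow = TRUE)
      f1 <- threshold_f1(m)
      f2 <- threshold_f2(m)
      for (F_G in c(0.3 * f1, f1, 0.5 * (f1 + f2), f2)) {
        p <- optimal_fluxes(F_G, m)
        if (F_G >= f1) {
          expect_equal(crowding_usage(p, m), m$phi_ATP, tolerance = 1e-9)
        } else {
          expect_lt(crowding_usage(p, m), m$phi_ATP)
        }
        expect_equal(p$f_G, F_G, tolerance = 1e-12)  # uptake binds up to f2
      }
    }
  })
})

test_that("near-universal mixed-regime approximation error is bounded", {
  # with a_M dominating, f_M stays close to f1 and f_L close to f_G - f1
  m <- printed_model(0.2)
  f1 <- threshold_f1(m)
  f2 <- threshold_f2(m)
  lam <- (m$a_G + m$a_L) / (m$a_M - m$a_L)
  for (F_G in seq(f1, f2, length.out = 40)) {
    p <- optimal_fluxes(F_G, m)
    expect_lte(abs(p$f_M - f1), f1 * lam * (F_G / f1 - 1) + 1e-12)
  }
})

test_that("ATP curve slopes change from 38 to the closed-form mixed slope at f1", {
  m <- printed_model(0.07)
  f1 <- threshold_f1(m)
  h <- f1 * 1e-3
  grid <- c(0.5 * f1 - h, 0.5 * f1 + h, 2 * f1 - h, 2 * f1 + h)
  cv <- atp_curve(grid, m)
  slope_lo <- (cv$f_ATP[2] - cv$f_ATP[1]) / (2 * h)
  slope_hi <- (cv$f_ATP[4] - cv$f_ATP[3]) / (2 * h)
  expect_equal(slope_lo, 38, tolerance = 1e-9)
  expect_equal(slope_hi, 2 - 36 * (m$a_G + m$a_L) / (m$a_M - m$a_L),
               tolerance = 1e-9)
  expect_lt(slope_hi, 38)
  # lactate excretion slope above f1 matches the predicted ~2.06
  lac_slope <- (cv$lactate_excretion[4] - cv$lactate_excretion[3]) / (2 * h)
  expect_equal(lac_slope, predicted_lactate_slope(m), tolerance = 1e-9)
})

test_that("ATP curve handles edge grids and rejects invalid ones", {
  m <- printed_model()
  cv0 <- atp_curve(0, m)
  expect_equal(nrow(cv0), 1L)
  expect_equal(unlist(cv0[1, c("f_G", "f_L", "f_M", "f_ATP")]),
               c(f_G = 0, f_L = 0, f_M = 0, f_ATP = 0))
  f1 <- threshold_f1(m)
  expect_equal(atp_curve(f1, m), atp_curve(c(f1), m))
  expect_error(atp_curve(c(2, 1), m), "sorted")
  expect_error(atp_curve(c(-1, 0), m), "nonnegative")
})
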
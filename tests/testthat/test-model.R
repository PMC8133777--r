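test_that("constitutive relations are the stated linear maps", {
  q <- nematic(0.2, 0)
  expect_equal(unname(shear_stress(nematic(0, 0), q, K = 1, zeta = 0.5)),
               c(0.1, 0))
  expect_equal(unname(shear_stress(nematic(0.1, 0), nematic(-0.1, 0),
                                   K = 1, zeta = 1)), c(0.1, 0))
  expect_equal(unname(rearrangement_rate(nematic(0.2, 0), nematic(0.1, 0),
                                         tau = 2, lam = 0.5)), c(0.15, 0))
  # steady-state identity: R(Q = -tau lam q, q) = 0
  set.seed(3)
  for (i in 1:10) {
    qi <- nematic(rnorm(1, sd = 0.1), rnorm(1, sd = 0.1))
    tau <- runif(1, 0.5, 4); lam <- runif(1, 0.1, 2)
    Q <- steady_state_elongation(qi, tau, lam)
    expect_lt(nematic_norm(rearrangement_rate(Q, qi, tau, lam)), 1e-14)
  }
  # tau lam = 1: Q_rr = -q_rr
  expect_equal(unname(steady_state_elongation(nematic(0.1, 0), 2, 0.5)),
               c(-0.1, 0))
})

test_that("the stress relation in terms of Q and R is an algebraic identity", {
  # sigma~ = 2 K* Q + (zeta / lam) R follows from eliminating q
  set.seed(8)
  for (i in 1:20) {
    K <- runif(1, 0.5, 3); zeta <- runif(1, 0, 2)
    tau <- runif(1, 0.5, 3); lam <- runif(1, 0.2, 2)
    Q <- nematic(rnorm(1, sd = 0.2), rnorm(1, sd = 0.2))
    q <- nematic(rnorm(1, sd = 0.2), rnorm(1, sd = 0.2))
    lhs <- shear_stress(Q, q, K, zeta)
    Ks <- effective_modulus(K, zeta, tau, lam)
    R <- rearrangement_rate(Q, q, tau, lam)
    rhs <- 2 * as.numeric(Ks) * Q + 2 * (K - as.numeric(Ks)) * tau * R
    expect_equal(unname(lhs), unname(rhs), tolerance = 1e-12)
  }
})

test_that("pressure and area convert both ways and monotonically", {
  expect_equal(pressure_from_area(5, 5, 2), 0)
  expect_equal(pressure_from_area(5 / exp(1), 5, 2), 2)
  a <- seq(2, 8, 0.5)
  P <- pressure_from_area(a, 5, 2)
  expect_true(all(diff(P) < 0)) # smaller cells, higher pressure
  expect_equal(area_from_pressure(P, 5, 2), a, tolerance = 1e-12)
  expect_error(pressure_from_area(-1, 5, 2), "positive")
})

test_that("force-balance quadrature matches closed forms", {
  r <- seq(5, 50, length.out = 91)
  # sigma ~ 0: constant pressure
  expect_equal(integrate_force_balance(function(s) rep(0, length(s)), r,
                                       P_out = 0.3),
               rep(0.3, length(r)), tolerance = 1e-10)
  # constant sigma: P = P0 + 2 c ln(r / r0)
  P1 <- integrate_force_balance(function(s) rep(0.2, length(s)), r,
                                P_out = 1)
  expect_equal(P1, 1 + 0.4 * log(r / 50), tolerance = 1e-8)
  # power law sigma = c r^n: P = c r^n (1 + 2/n) + const
  cc <- 0.01; nn <- 2
  P2 <- integrate_force_balance(function(s) cc * s^nn, r,
                                P_out = cc * 50^nn * (1 + 2 / nn))
  expect_equal(P2, cc * r^nn * (1 + 2 / nn), tolerance = 1e-8)
  expect_error(integrate_force_balance(function(s) s, seq(0, 10, 1)),
               "singular|r = 0")
})

test_that("effective modulus limits and sign flag", {
  expect_equal(as.numeric(effective_modulus(2, 0, 2, 0.5)), 2)
  expect_equal(as.numeric(effective_modulus(1, 2 * 1 * 2 * 0.5, 2, 0.5)), 0)
  ks <- effective_modulus(1, 5, 2, 0.5)
  expect_lt(as.numeric(ks), 0)
  expect_true(attr(ks, "polarity_dominated"))
})

test_that("the stress-elongation regression recovers its generating line", {
  set.seed(77)
  n <- 40
  Q <- rnorm(n, -0.05, 0.1)
  sig <- 0.05 * Q + 0.011 + rnorm(n, 0, 0.01) # published-scale noise
  fit <- fit_eq7(Q, sig)
  expect_lt(abs(fit$slope - 0.05), 2 * fit$slope_se)
  expect_lt(abs(fit$intercept - 0.011), 2 * fit$intercept_se)
  # noise-free collinear data is exact
  fit0 <- fit_eq7(Q, 0.05 * Q + 0.011)
  expect_equal(fit0$slope, 0.05, tolerance = 1e-12)
  expect_equal(fit0$intercept, 0.011, tolerance = 1e-12)
  # a zeta = 0 tissue has slope 1 and intercept tau R
  fit1 <- fit_eq7(Q, Q + 2 * 0.00579 * 0)
  expect_equal(fit1$slope, 1, tolerance = 1e-12)
  expect_error(fit_eq7(rep(0.1, 5), rnorm(5)), "rank")
})

test_that("the relaxation time follows from the fitted line and Rrr", {
  expect_equal(estimate_tau(0.011, 0.05, 0.00579), 2, tolerance = 0.01)
  expect_warning(tau <- estimate_tau(0.011, 1, 0.00579), "undefined")
  expect_true(is.na(tau))
  # doubling Rrr halves tau
  expect_equal(estimate_tau(0.011, 0.05, 2 * 0.00579),
               estimate_tau(0.011, 0.05, 0.00579) / 2)
})

test_that("the pitchfork threshold, amplitude and ODE limit agree", {
  base <- list(K = 1, zeta = 0.2, tau = 2, lam = 0.5, tau_q = 1, alpha = 1)
  mu_c <- 1 / (base$tau_q * (2 * base$K * base$tau * base$lam - base$zeta))
  # below and at threshold: q0 = 0 and the isotropic state is stable
  for (m in c(0.5, 1)) {
    P <- do.call(model_params, c(base, list(mu = m * mu_c)))
    hp <- homogeneous_polarity(P)
    expect_equal(hp$q0, 0)
    expect_true(hp$isotropic_stable)
  }
  # above threshold the ODE converges to the closed-form amplitude
  for (m in c(1.2, 1.5, 2)) {
    P <- do.call(model_params, c(base, list(mu = m * mu_c)))
    hp <- homogeneous_polarity(P)
    expect_false(hp$isotropic_stable)
    tr <- simulate_homogeneous(P, q_init = 1e-2, t_end = 600)
    expect_equal(abs(tail(tr$q, 1)), hp$q0, tolerance = 1e-6)
  }
  # amplitude scales as sqrt(mu - mu_c) just above threshold
  eps <- c(0.02, 0.08)
  q0s <- vapply(eps, function(e) {
    P <- do.call(model_params, c(base, list(mu = (1 + e) * mu_c)))
    homogeneous_polarity(P)$q0
  }, numeric(1))
  expect_equal(q0s[2] / q0s[1], 2, tolerance = 0.01)
  expect_error(homogeneous_polarity(
    do.call(model_params, c(base[-2], list(zeta = 3)))), "regime")
})

test_that("the radial steady state is grid-independent and matches the
           collocation cross-check", {
  bc <- c(0.024, -1.2e-3)
  r1 <- seq(10, 45, by = 0.35)
  r2 <- seq(10, 45, by = 0.07)
  a <- solve_polarity_bvp(0.01, 1, 0.5, 5e-4, bc, r1)
  b <- solve_polarity_bvp(0.01, 1, 0.5, 5e-4, bc, r2)
  ix <- match(round(r1, 6), round(r2, 6))
  expect_lt(max(abs(a$qrr - b$qrr[ix])), 1e-6)
  cl <- solve_polarity_bvp(0.01, 1, 0.5, 5e-4, bc, seq(10, 45,
                                                       length.out = 1601),
                           method = "collocation")
  am <- solve_polarity_bvp(0.01, 1, 0.5, 5e-4, bc,
                           seq(10, 45, length.out = 1601))
  expect_lt(max(abs(cl$qrr - am$qrr)), 1e-4)
})

test_that("the polarity field plateaus at the homogeneous amplitude far
           from boundaries", {
  p <- solve_polarity_bvp(0.01, 1, 0.5, 0, bc = c(0.1, NA),
                          r = seq(20, 200, length.out = 301),
                          method = "collocation", outer_deriv = 0)
  far <- p$r >= 100
  # the residual deviation is the analytic -4q/r^2 curvature correction
  expect_lt(max(abs(p$qrr[far] - 0.1)), 2e-3)
})

test_that("zero feedback and zero rearrangement give the trivial solution", {
  s <- solve_polarity_bvp(q0_sq = -1 / 1, lam_tau = 1, D_over_alpha = 0.5,
                          forcing = 0, bc = c(0, 0),
                          r = seq(10, 45, length.out = 101))
  expect_true(all(s$qrr == 0))
  expect_true(all(s$Qrr == 0))
})

test_that("Table-1-style parameters produce a tangential profile falling
           with radius", {
  s <- solve_polarity_bvp(0.01, 1, 0.5, 5e-4, bc = c(0.024, -1.2e-3),
                          r = seq(10, 45, length.out = 101))
  expect_true(all(s$Qrr < 0))            # tangential throughout
  expect_lt(tail(s$Qrr, 1), -0.09)      # strengthens toward the margin
  expect_gt(s$Qrr[1], -0.03)
})

test_that("the self-organized fit honors the resample count and degenerate
           input", {
  r <- seq(10, 45, by = 5)
  sol <- solve_polarity_bvp(0.01, 1, 0.5, 5e-4, bc = c(0.024, -1.2e-3),
                            r = seq(10, 45, length.out = 71))
  prof <- data.frame(bin_r = r,
                     Qrr = approx(sol$r, sol$Qrr, r)$y, sd_Qrr = 0)
  fit <- fit_self_organized(prof, resamples = 5, seed = 2)
  expect_equal(fit$n_resamples, 5)
  expect_equal(nrow(fit$resample_estimates), 5)
  # zero-SD profiles: every refit identical, zero-width intervals
  expect_equal(unname(fit$intervals[1, ]), unname(fit$intervals[2, ]),
               tolerance = 1e-10)
  expect_error(fit_self_organized(prof[1:4, ], resamples = 3), "bins")
})
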
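test_that("eta extraction is stable across disjoint probe sets", {
  sys <- dopc_system()
  e1 <- extract_eta(sys, n0_probes = c(-0.4, 0.4), quadrant = TRUE)
  e2 <- extract_eta(sys, n0_probes = c(-0.2, 0.2), quadrant = TRUE)
  expect_equal(coef(e1)[["eta"]], coef(e2)[["eta"]], tolerance = 1e-3)
  expect_lt(abs(e1$fit$intercept), 1e-3 * abs(coef(e1)[["eta"]]))
  expect_error(extract_eta(sys, n0_probes = 0.4), "two distinct")
})

test_that("beta and gamma separate cleanly on restricted probe grids", {
  sys <- dopc_system()
  full <- extract_beta_gamma(sys, n0_probes = c(-0.3, 0, 0.3),
                             h_p_probes = c(2.2, 2.9, 3.3),
                             mesh = test_rmesh)
  b_only <- extract_beta_gamma(sys, n0_probes = c(-0.3, 0.3),
                               h_p_probes = 2.9, mesh = test_rmesh)
  g_only <- extract_beta_gamma(sys, n0_probes = 0,
                               h_p_probes = c(2.2, 2.9, 3.3),
                               mesh = test_rmesh)
  expect_equal(coef(b_only)[["beta"]], coef(full)[["beta"]],
               tolerance = 1e-6)
  expect_equal(coef(g_only)[["gamma"]], coef(full)[["gamma"]],
               tolerance = 1e-6)
  expect_error(extract_beta_gamma(sys, n0_probes = 0, h_p_probes = 2.9),
               "rank deficient")
})

test_that("lipid-patch affinity: matched thickness nulls both coefficients", {
  sys <- dopc_system()
  kb <- extract_k_b(sys, h_inc = 1.45, params_inc = inclusion_params(),
                    J0inc_probes = c(-0.4, 0, 0.2), mesh = test_rmesh)
  expect_lt(abs(coef(kb)[["k"]]), 0.05)
  expect_lt(abs(coef(kb)[["b"]]), 0.05)
  kb2 <- extract_k_b(sys, h_inc = 1.35, params_inc = inclusion_params(),
                     J0inc_probes = c(-0.4, -0.2, 0, 0.2),
                     mesh = test_rmesh)
  ## three+ probes collinear: affine residual tiny relative to max |Delta|
  expect_lt(max(abs(kb2$fit$residuals)),
            1e-4 * max(abs(kb2$probes$Delta)))
})

test_that("the forward thickness relation is affine with regime warnings", {
  s <- forward_thickness(c(0, 0.005, 0.01), Delta = -3.664, h = 1.45)
  expect_equal(s$thickness[1], 2.9)
  expect_equal(s$thickness[3], 2.9 - 0.03664, tolerance = 1e-12)
  expect_true(all(diff(s$thickness) < 0))
  expect_warning(forward_thickness(c(0, 0.2), Delta = -3.664, h = 1.45),
                 "linear regime")
  expect_error(forward_thickness(c(0.01, 0.005), -3.664, 1.45), "increasing")
})

test_that("noiseless series invert exactly and degenerate designs are rejected", {
  s <- generate_series(-0.42, eta = 9.16, h = 1.45,
                       C = seq(0.002, 0.016, length.out = 8), noise_sd = 0)
  f <- fit_n0(s, eta = 9.16, h = 1.45)
  expect_equal(coef(f)[["n0"]], -0.42, tolerance = 1e-10)
  expect_error(fit_n0(s[1:2, ], eta = 9.16, h = 1.45), "insufficient")
  s0 <- s; s0$concentration <- rep(0.01, 8)
  expect_error(fit_n0(s0, eta = 9.16, h = 1.45), "degenerate")
})

test_that("mole-fraction series convert with the declared area per lipid", {
  ## <d> = 2h + C*Delta with C = 2x/A_L
  A_L <- 0.65
  x <- seq(0.001, 0.01, length.out = 6)
  d <- 2 * 1.45 + (2 * x / A_L) * 9.16 * (-0.48)
  ser <- data.frame(molefraction = x, thickness = d)
  f_both <- fit_n0(ser, eta = 9.16, h = 1.45, A_L = A_L)
  expect_equal(coef(f_both)[["n0"]], -0.48, tolerance = 1e-10)
  ## per-leaflet counting halves the concentration, doubling |n0|
  f_one <- fit_n0(ser, eta = 9.16, h = 1.45, A_L = A_L, leaflets = "one")
  expect_equal(coef(f_one)[["n0"]], 2 * (-0.48), tolerance = 1e-10)
  expect_error(fit_n0(ser, eta = 9.16, h = 1.45), "A_L")
})

test_that("confidence intervals from noisy series are calibrated", {
  set.seed(11)
  hits <- 0; nrep <- 60
  for (i in seq_len(nrep)) {
    n0t <- runif(1, -0.6, -0.2)
    s <- generate_series(n0t, eta = 9.16, h = 1.45,
                         C = seq(0.002, 0.016, length.out = 8),
                         noise_sd = 0.01, seed = sample.int(1e6, 1))
    f <- fit_n0(s, eta = 9.16, h = 1.45)
    hits <- hits + (f$ci[1] <= n0t && n0t <= f$ci[2])
  }
  expect_gte(hits / nrep, 0.85)   # loose sanity band for a short run
})

test_that("the geometric boundary-director estimate follows the right-triangle form", {
  expect_equal(estimate_boundary_director(0.65, 1.45),
               0.65 / sqrt(0.65^2 + 1.45^2), tolerance = 1e-15)
  expect_equal(round(estimate_boundary_director(0.65, 1.45), 1), 0.4)
  expect_identical(estimate_boundary_director(0, 1.45), 0)
  expect_equal(estimate_boundary_director(1.2, 1.2), 1 / sqrt(2))
  expect_error(estimate_boundary_director(0.65, -1), "positive")
})
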
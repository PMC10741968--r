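test_that("unit conversion bridges mN/m to kBT/nm^2 at the stated temperature", {
  ## 40 mN/m = 40e-21 J/nm^2; kBT at 300 K = 4.141947e-21 J
  expect_equal(convert_to_internal(40, "mN/m", 300),
               40e-21 / (1.380649e-23 * 300), tolerance = 1e-12)
  expect_equal(convert_to_internal(40, "mN/m", 300), 9.66, tolerance = 1e-3)
  expect_identical(convert_to_internal(0, "mN/m", 300), 0)
  expect_identical(convert_to_internal(10, "kBT"), 10)
  expect_identical(convert_to_internal(-0.091, "1/nm"), -0.091)
  expect_error(convert_to_internal(1, "furlong"), "unsupported unit")
  expect_error(convert_to_internal(Inf, "kBT"), "finite")
})

test_that("presets carry the documented parameter values", {
  d <- preset_parameters("DOPC")
  expect_equal(d$B, 10)
  expect_equal(d$J0, -0.091)
  expect_equal(d$h, 1.45)
  expect_equal(d$Kt, convert_to_internal(40, "mN/m"))
  expect_equal(d$Ka, convert_to_internal(133, "mN/m"))
  expect_equal(d$KG, -5)
  expect_equal(d$Krot, 5)
  p <- preset_parameters("POPC_POPS_3to1")
  expect_equal(p$B, 11)
  expect_equal(p$Ka, convert_to_internal(117, "mN/m"))
  expect_equal(p$J0, 0)
  expect_equal(p$h, 1.46)
  thin <- preset_parameters("inclusion_thin")
  expect_equal(thin$h, 0.7)
  expect_equal(attr(thin, "geometry")$r_lip, 0.662)
  expect_equal(attr(preset_parameters("inclusion_common"), "geometry")$r_lip,
               0.5)
  expect_error(preset_parameters("DPPC"), "unknown preset")
})

test_that("parameter and spec constructors validate their invariants", {
  expect_error(monolayer_params(B = -1, Kt = 9, Ka = 30, h = 1.4), "B must")
  expect_error(monolayer_params(B = 10, Kt = 9, Ka = 30, h = 0), "h must")
  expect_error(amphipathic_spec(1, 0.65, -0.4), "l_p")
  expect_error(amphipathic_spec(5, 0.65, -1.2), "n0")
  expect_error(transmembrane_spec(0, 2.9, 0), "r_p")
  expect_error(transmembrane_spec(0.65, -1, 0), "h_p")
  p <- preset_parameters("inclusion_common")
  expect_error(lipid_inclusion_spec(-0.5, 1.4, p), "r_lip")
  sp <- lipid_inclusion_spec(0.5, 1.2, p)
  expect_equal(sp$params_inc$h, 1.2)   # h_inc overrides the preset h
})

test_that("energy density vanishes in the ground state and matches closed forms", {
  sys <- dopc_system()
  gs <- ground_state(sys)
  expect_equal(energy_density(gs, sys), 0)

  ## uniform in-plane director: only the upper tilt term survives
  st <- gs; st$nu <- c(0.1, 0)
  expect_equal(energy_density(st, sys), sys$upper$Kt / 2 * 0.01,
               tolerance = 1e-12)

  ## pure twist: rot n = -0.3 with div n = 0, zero Gaussian splay,
  ## thickness terms balanced
  st <- gs
  st$dnu <- matrix(c(0, 0.3, 0, 0), 2, 2, byrow = TRUE) # dn[1,2] = 0.3
  expect_equal(energy_density(st, sys, warn_negative = FALSE),
               sys$upper$Krot / 2 * 0.3^2, tolerance = 1e-12)
})

test_that("energy density is exactly quadratic for a zero-spontaneous-curvature lipid", {
  sys <- pops_system()   # J0 = 0: no linear splay source
  gs <- ground_state(sys)
  set.seed(7)
  for (i in 1:20) {
    st <- gs
    st$Hu <- sys$upper$h + runif(1, -0.3, 0.3)
    st$Hl <- -sys$lower$h + runif(1, -0.3, 0.3)
    st$M <- runif(1, -0.2, 0.2)
    st$nu <- runif(2, -0.3, 0.3); st$nl <- runif(2, -0.3, 0.3)
    st$dHu <- runif(2, -0.3, 0.3); st$dHl <- runif(2, -0.3, 0.3)
    st$dnu <- matrix(runif(4, -0.3, 0.3), 2)
    st$dnl <- matrix(runif(4, -0.3, 0.3), 2)
    w1 <- energy_density(st, sys, warn_negative = FALSE)
    st2 <- ground_state(sys)
    lam <- 0.5
    st2$Hu <- sys$upper$h + lam * (st$Hu - sys$upper$h)
    st2$Hl <- -sys$lower$h + lam * (st$Hl + sys$lower$h)
    st2$M <- lam * st$M
    for (f in c("nu", "nl", "dHu", "dHl", "dnu", "dnl"))
      st2[[f]] <- lam * st[[f]]
    w2 <- energy_density(st2, sys, warn_negative = FALSE)
    expect_equal(w2, lam^2 * w1, tolerance = 1e-12)
    expect_gte(w1, 0)   # positive semidefinite when J0 = 0
  }
})

test_that("a negative density (splay near nonzero spontaneous curvature) is flagged", {
  sys <- dopc_system()
  st <- ground_state(sys)
  ## div n close to -J0 makes the splay term negative; keep the
  ## compression residual balanced so nothing rescues it
  d <- -sys$upper$J0 / 2
  st$dnu <- diag(c(d, 0))
  st$Hu <- sys$upper$h - sys$upper$h^2 / 2 * d   # balances compression
  expect_warning(energy_density(st, sys), "negative elastic energy density")
})
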
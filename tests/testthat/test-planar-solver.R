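test_that("planar mesh is well formed for both outlines", {
  for (ol in c("ellipse", "stadium")) {
    m <- planar_mesh(5, 0.65, n_cap = 8, n_str = 12, d0 = 0.1, grow = 1.3,
                     n_inner = 2, outline = ol)
    expect_true(all(m$tri >= 1 & m$tri <= nrow(m$nodes)))
    ## positive orientation everywhere
    a2 <- (m$nodes[m$tri[, 2], 1] - m$nodes[m$tri[, 1], 1]) *
          (m$nodes[m$tri[, 3], 2] - m$nodes[m$tri[, 1], 2]) -
          (m$nodes[m$tri[, 3], 1] - m$nodes[m$tri[, 1], 1]) *
          (m$nodes[m$tri[, 2], 2] - m$nodes[m$tri[, 1], 2])
    expect_true(all(a2 > 0))
    ## both regions present; outline nodes carry unit normals
    expect_setequal(unique(m$region), c(1L, 2L))
    expect_equal(sqrt(m$gamma_nx^2 + m$gamma_ny^2),
                 rep(1, length(m$gamma)), tolerance = 1e-12)
    ## total area matches the annulus between footprint and far boundary
    expect_gt(sum(a2) / 2, pi * 30^2 * 0.9)
  }
  expect_error(planar_mesh(5, 0.65, L = 10), "at least 30")
})

test_that("a peptide imposing no director jump leaves the membrane flat", {
  res <- solve_amphipathic(dopc_system(), amphipathic_spec(5, 0.65, 0),
                           quadrant = TRUE)
  expect_lt(abs(res$W), 1e-10)
  expect_lt(abs(res$Delta), 1e-10)
})

test_that("a beneath-pointing director locally thins the membrane near the outline", {
  res <- solve_amphipathic(dopc_system(), amphipathic_spec(5, 0.65, -0.4))
  expect_lt(res$Delta, 0)
  th <- res$profile$thickness
  expect_lt(min(th, na.rm = TRUE), 2 * 1.45 - 0.05)   # local thinning
  ## thinning is adjacent to the outline: locate the minimum
  i <- which.min(th)
  d <- .footprint_distance(cbind(res$profile$x[i], res$profile$y[i]),
                           5, 0.65, "ellipse")
  expect_lt(d, 2.5)   # within the few-nm deformation zone of the outline
})

test_that("the thickness map respects the problem symmetry and the far field", {
  res <- solve_amphipathic(dopc_system(), amphipathic_spec(5, 0.65, -0.4))
  mp <- thickness_map(res, nx = 41, ny = 41, xlim = c(-12, 12),
                      ylim = c(-12, 12))
  z <- matrix(mp$thickness, nrow = 41)
  ## footprint masked
  expect_true(is.na(z[21, 21]))
  ## x -> -x and y -> -y symmetry (up to interpolation on the split quads)
  expect_equal(z, z[41:1, ], tolerance = 1e-3)
  expect_equal(z, z[, 41:1], tolerance = 1e-3)
  ## far corners at the unperturbed thickness
  expect_equal(z[1, 1], 2 * 1.45, tolerance = 1e-3)
})

test_that("quarter-domain symmetry reduction reproduces the full-plane result", {
  full <- solve_amphipathic(dopc_system(), amphipathic_spec(5, 0.65, -0.4))
  quad <- solve_amphipathic(dopc_system(), amphipathic_spec(5, 0.65, -0.4),
                            quadrant = TRUE)
  expect_equal(quad$Delta, full$Delta, tolerance = 5e-3)
  expect_equal(quad$W, full$W, tolerance = 5e-3)
})

test_that("Delta converges under mesh refinement and domain growth", {
  sp <- amphipathic_spec(5, 0.65, -0.4)
  d0 <- solve_amphipathic(dopc_system(), sp, quadrant = TRUE)$Delta
  d1 <- solve_amphipathic(dopc_system(), sp, quadrant = TRUE,
                          mesh = list(n_cap = 24, n_str = 36, d0 = 0.025,
                                      grow = 1.10, n_inner = 6, L = 60))$Delta
  expect_lt(abs(d0 - d1), 0.02 * abs(d1))
})

test_that("the footprint outline moves the response by a few percent", {
  sp <- amphipathic_spec(5, 0.65, -0.4)
  d_ell <- solve_amphipathic(dopc_system(), sp, quadrant = TRUE)$Delta
  d_std <- solve_amphipathic(dopc_system(), sp, quadrant = TRUE,
                             outline = "stadium")$Delta
  ## same sign; the stadium (longer outline) responds a few percent more
  expect_gt(abs(d_std), abs(d_ell))
  expect_lt(abs(d_std - d_ell), 0.1 * abs(d_ell))
})

test_that("elongated footprints approach the translationally invariant limit", {
  sys <- dopc_system()
  q1d <- long_peptide_oracle(sys, -0.4)
  expect_lt(q1d, 0)
  expect_equal(long_peptide_oracle(sys, 0), 0, tolerance = 1e-12)
  per_len <- sapply(c(5, 10, 20), function(lp)
    solve_amphipathic(sys, amphipathic_spec(lp, 0.65, -0.4),
                      quadrant = TRUE)$Delta / lp)
  ## same sign as the 1D limit, and monotone approach to it
  expect_true(all(sign(per_len) == sign(q1d)))
  gaps <- abs(per_len - q1d)
  expect_true(all(diff(gaps) < 0))
})
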
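test_that("a matched cylindrical peptide leaves the membrane unperturbed", {
  sys <- dopc_system()
  h <- sys$upper$h
  res <- solve_transmembrane(sys, transmembrane_spec(0.65, 2 * h, 0),
                             mesh = test_rmesh)
  expect_lt(abs(res$W), 1e-10)
  expect_lt(abs(res$Delta), 1e-10)
  expect_lt(max(abs(res$profile$thickness - 2 * h)), 1e-10)
})

test_that("transmembrane essential conditions hold and fields decay to the far field", {
  sys <- dopc_system()
  h <- sys$upper$h
  sp <- transmembrane_spec(0.65, 2.0, -0.3)
  res <- solve_transmembrane(sys, sp, mesh = test_rmesh)
  pr <- res$profile
  expect_equal(pr$thickness[1], 2.0, tolerance = 1e-10)  # H_u - H_l = h_p
  expect_equal(pr$n_u_r[1], -0.3, tolerance = 1e-12)
  expect_equal(pr$n_l_r[1], -0.3, tolerance = 1e-12)
  nn <- nrow(pr)
  expect_lt(abs(pr$thickness[nn] - 2 * h), 1e-8)          # far field
  expect_lt(abs(pr$H_u[nn] - h), 1e-8)
  ## symmetric spec: vertical position splits the thickness evenly
  expect_equal(pr$H_u[1], 1.0, tolerance = 1e-8)
  expect_equal(pr$H_l[1], -1.0, tolerance = 1e-8)
})

test_that("the deformation is antisymmetric in the boundary director", {
  sys <- dopc_system()
  h <- sys$upper$h
  rp <- solve_transmembrane(sys, transmembrane_spec(0.65, 2 * h, 0.2),
                            mesh = test_rmesh)
  rm <- solve_transmembrane(sys, transmembrane_spec(0.65, 2 * h, -0.2),
                            mesh = test_rmesh)
  expect_equal(rp$Delta, -rm$Delta, tolerance = 1e-9)
  expect_equal(rp$fields$hu, -rm$fields$hu, tolerance = 1e-9)
})

test_that("mirror-symmetric reduction agrees with the full bilayer solve", {
  sys <- dopc_system()
  sp <- transmembrane_spec(0.65, 2.2, -0.3)
  full <- solve_transmembrane(sys, sp, mesh = test_rmesh)
  half <- reduce_symmetric(sys, sp, mesh = test_rmesh)
  expect_equal(half$W, full$W, tolerance = 1e-9)
  expect_equal(half$Delta, full$Delta, tolerance = 1e-9)
  ## mirror symmetry of the full solution itself
  expect_lt(max(abs(full$fields$M)), 1e-9)
  expect_equal(full$profile$H_l, -full$profile$H_u, tolerance = 1e-9)
  expect_error(reduce_symmetric(sys, transmembrane_spec(0.65, 2.2, -0.3, 0.1)),
               "symmetric")
})

test_that("twist and Gaussian moduli do not move axisymmetric equilibria", {
  base <- preset_parameters("DOPC")
  sp <- transmembrane_spec(0.65, 2.4, -0.25)
  r1 <- solve_transmembrane(bilayer_system(base), sp, mesh = test_rmesh)
  ## twist never enters an axisymmetric configuration
  p2 <- base; p2$Krot <- 50
  r2 <- solve_transmembrane(bilayer_system(p2), sp, mesh = test_rmesh)
  expect_equal(r2$W, r1$W, tolerance = 1e-12)
  expect_equal(r2$fields$hu, r1$fields$hu, tolerance = 1e-12)
  ## with directors pinned at both boundaries the Gaussian term is pure
  ## boundary data: fields unchanged, energy shifted
  p3 <- base; p3$KG <- 0
  r3 <- solve_transmembrane(bilayer_system(p3), sp, mesh = test_rmesh)
  expect_equal(r3$fields$hu, r1$fields$hu, tolerance = 1e-9)
  expect_equal(r3$fields$nu, r1$fields$nu, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(r3$W, r1$W)))
  ## the shift equals the analytic boundary term -pi*KG*(n0u^2 + n0l^2)
  expect_equal(r1$W - r3$W, -pi * base$KG * 2 * 0.25^2, tolerance = 1e-6)
})

test_that("thickness disturbance is affine in the boundary data", {
  sys <- dopc_system()
  h <- sys$upper$h
  grid <- expand.grid(n0 = c(-0.4, 0, 0.4), hp = c(2.0, 2.9, 3.4))
  grid$Delta <- mapply(function(n0, hp)
    solve_transmembrane(sys, transmembrane_spec(0.65, hp, n0),
                        mesh = test_rmesh)$Delta, grid$n0, grid$hp)
  X <- cbind(grid$n0, grid$hp - 2 * h)
  cf <- stats::lm.fit(X, grid$Delta)$coefficients
  res <- grid$Delta - as.numeric(X %*% cf)
  expect_lt(max(abs(res)), 1e-6 * max(abs(grid$Delta)))
})

test_that("solution converges under mesh refinement and domain growth", {
  sys <- dopc_system()
  sp <- transmembrane_spec(0.65, 2.4, -0.3)
  d1 <- solve_transmembrane(sys, sp,
                            mesh = list(h0 = 0.02, grow = 1.10))$Delta
  d2 <- solve_transmembrane(sys, sp,
                            mesh = list(h0 = 0.01, grow = 1.05,
                                        R_max = 100))$Delta
  expect_lt(abs(d1 - d2), 0.01 * abs(d2))
  ## built-in convergence diagnostic passes on an adequate mesh
  expect_no_error(solve_transmembrane(sys, sp, refine_check = TRUE))
})

test_that("an unstable parameter set triggers the stability warning", {
  ## control: the physical parameter set raises no warning
  expect_no_warning(
    solve_lipid_inclusion(dopc_system(),
                          lipid_inclusion_spec(0.5, 1.45,
                                               inclusion_params(B = 10)),
                          mesh = test_rmesh))
  ## an ill-posed parameter set (negative tilt rigidity, bypassing the
  ## constructor checks) makes the quadratic form indefinite
  inc_bad <- inclusion_params(B = 10)
  inc_bad$Kt <- -inc_bad$Kt
  expect_warning(
    solve_lipid_inclusion(dopc_system(),
                          lipid_inclusion_spec(0.5, 1.45, inc_bad),
                          mesh = test_rmesh),
    "not positive definite")
})

test_that("a patch identical to the bulk lipid causes no deformation", {
  sys <- dopc_system()
  res <- solve_lipid_inclusion(sys,
                               lipid_inclusion_spec(0.5, 1.45,
                                                    preset_parameters("DOPC")),
                               mesh = test_rmesh)
  expect_lt(abs(res$W), 1e-10)
  expect_lt(abs(res$Delta), 1e-10)
})

test_that("zero thickness mismatch gives Delta = 0 with real local deformation", {
  sys <- dopc_system()
  res <- solve_lipid_inclusion(sys,
                               lipid_inclusion_spec(0.5, 1.45,
                                                    inclusion_params(J0 = 0)),
                               mesh = test_rmesh)
  expect_lt(abs(res$Delta), 0.01)
  expect_gt(max(abs(res$profile$thickness - 2.9)), 0.005)
})

test_that("thin and thick patches disturb the average thickness with opposite sign", {
  sys <- dopc_system()
  thin <- solve_lipid_inclusion(sys,
                                lipid_inclusion_spec(0.5, 1.35,
                                                     inclusion_params(J0 = 0)),
                                mesh = test_rmesh)
  thick <- solve_lipid_inclusion(sys,
                                 lipid_inclusion_spec(0.5, 1.55,
                                                      inclusion_params(J0 = 0)),
                                 mesh = test_rmesh)
  expect_lt(thin$Delta, 0)
  expect_gt(thick$Delta, 0)
})

test_that("patch fields are continuous across the patch edge", {
  sys <- dopc_system()
  res <- solve_lipid_inclusion(sys,
                               lipid_inclusion_spec(0.5, 1.35,
                                                    inclusion_params(J0 = -0.3)),
                               mesh = test_rmesh)
  pr <- res$profile
  i <- which(abs(pr$r - 0.5) < 1e-12)
  expect_length(i, 1)        # single node at the edge: continuity built in
  ## neighbouring values vary smoothly (no jump at the edge)
  expect_lt(abs(pr$H_u[i + 1] - pr$H_u[i - 1]), 0.05)
  expect_lt(abs(pr$n_u_r[i + 1] - pr$n_u_r[i - 1]), 0.05)
})
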
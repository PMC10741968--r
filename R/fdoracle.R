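## Independent oracle: dense-grid finite-difference minimizer of the
## axisymmetric bilayer energy for a transmembrane peptide. Deliberately
## written without any of the finite-element assembly machinery: uniform
## grid, midpoint-rule energy with difference/average operators built as
## sparse matrices, so it provides an independent numerical route to Delta.

#' Finite-difference oracle for the transmembrane problem
#'
#' Minimizes the same axisymmetric elastic energy as
#' [solve_transmembrane()] on a dense uniform radial grid using a
#' midpoint-rule finite-difference discretization assembled directly from
#' sparse difference and averaging operators. Used as an independent
#' cross-check of the finite-element solver.
#'
#' @inheritParams solve_transmembrane
#' @param R_max truncation radius, nm.
#' @param dr uniform grid spacing, nm.
#' @return list with `Delta` \[nm^3\] (including the peptide-disk
#'   contribution, as in [solve_transmembrane()]) and `W` \[kBT\].
#' @export
fd_transmembrane <- function(system, spec, R_max = 50, dr = 0.01) {
  stopifnot(inherits(system, "bilayer_system"),
            inherits(spec, "transmembrane_spec"))
  if (!.is_symmetric_bilayer(system))
    stop("bulk bilayer must be symmetric")
  p <- system$upper
  h <- p$h
  r <- seq(spec$r_p, R_max, by = dr)
  nn <- length(r)
  m <- nn - 1L
  rmid <- (r[-1] + r[-nn]) / 2
  w <- 2 * pi * rmid * dr

  D <- Matrix::sparseMatrix(i = rep(seq_len(m), 2), j = c(1:m, 2:nn),
                            x = rep(c(-1, 1) / dr, each = m),
                            dims = c(m, nn))
  Av <- Matrix::sparseMatrix(i = rep(seq_len(m), 2), j = c(1:m, 2:nn),
                             x = rep(0.5, 2 * m), dims = c(m, nn))
  Z <- Matrix::Matrix(0, m, nn, sparse = TRUE)
  ## unknowns U = (hu, hl, nu, nl), field-major blocks
  blk <- function(Bhu, Bhl, Bnu, Bnl) cbind(Bhu, Bhl, Bnu, Bnl)
  ndof <- 4L * nn

  Ldiv_u <- blk(Z, Z, D + Matrix::Diagonal(m, 1 / rmid) %*% Av, Z)
  Ldiv_l <- blk(Z, Z, Z, D + Matrix::Diagonal(m, 1 / rmid) %*% Av)
  Ltilt_u <- blk(-D, Z, Av, Z)
  Ltilt_l <- blk(Z, D, Z, Av)
  Lgrad_u <- blk(D, Z, Z, Z)
  Lgrad_l <- blk(Z, D, Z, Z)
  Lval_nu <- blk(Z, Z, Av, Z)
  Lval_nl <- blk(Z, Z, Z, Av)
  ## combined compression residual after eliminating the interface height M:
  ## sqrt(Ka/(2 h^2)) * ( -h^2/2 (div nu + div nl) - hu + hl )
  Lcomp <- -h^2 / 2 * (Ldiv_u + Ldiv_l) + blk(-Av, Av, Z, Z)

  Wd <- Matrix::Diagonal(m, w)
  A <- Matrix::Matrix(0, ndof, ndof, sparse = TRUE)
  b <- numeric(ndof)
  add_sq <- function(A, k, L) A + k * Matrix::crossprod(L, Wd %*% L)
  add_cross <- function(A, k, La, Lb) {
    Ct <- Matrix::crossprod(La, Wd %*% Lb)
    A + k * (Ct + Matrix::t(Ct))
  }
  for (Ld in list(Ldiv_u, Ldiv_l)) {
    A <- add_sq(A, p$B, Ld)
    b <- b + p$B * p$J0 * as.numeric(Matrix::crossprod(Ld, w))
  }
  A <- add_sq(A, p$Kt, Ltilt_u)
  A <- add_sq(A, p$Kt, Ltilt_l)
  A <- add_sq(A, p$sigma, Lgrad_u)
  A <- add_sq(A, p$sigma, Lgrad_l)
  ## Gaussian splay: KG * n * dn/dr / r per monolayer
  A <- add_cross(A, p$KG, Matrix::Diagonal(m, 1 / rmid) %*% Lval_nu,
                 blk(Z, Z, D, Z))
  A <- add_cross(A, p$KG, Matrix::Diagonal(m, 1 / rmid) %*% Lval_nl,
                 blk(Z, Z, Z, D))
  kc <- (p$Ka / h^2) / 2          # c_u c_l / (c_u + c_l) with c_u = c_l
  A <- add_sq(A, kc, Lcomp)
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)

  id <- function(field, node) (field - 1L) * nn + node
  fixed_idx <- c(id(1:4, nn), id(3, 1), id(4, 1))
  fixed_val <- c(rep(0, 4), spec$n0u, spec$n0l)
  E <- Matrix::sparseMatrix(i = c(1, 1), j = c(id(1, 1), id(2, 1)),
                            x = c(1, -1), dims = c(1, ndof))
  sol <- solve_quadratic(A, b, 0, fixed_idx, fixed_val,
                         E = E, f = spec$h_p - 2 * h,
                         stability_check = FALSE)
  U <- sol$U
  hu <- U[id(1, seq_len(nn))]
  hl <- U[id(2, seq_len(nn))]
  Delta <- sum(w * as.numeric(Av %*% (hu - hl))) +
    pi * spec$r_p^2 * (spec$h_p - 2 * h)
  list(Delta = Delta, W = sol$W)
}
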
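## Constrained minimization of 1/2 U'AU + b'U + c0 with sparse symmetric A.
## Dirichlet-type constraints are eliminated; a (small) set of general linear
## equality constraints E U = f is handled by a KKT system on the free block.

solve_quadratic <- function(A, b, c0, fixed_idx = integer(), fixed_val = numeric(),
                            E = NULL, f = NULL, stability_check = TRUE) {
  ndof <- length(b)
  if (anyDuplicated(fixed_idx)) {
    keep <- !duplicated(fixed_idx)
    dup <- fixed_idx[!keep]
    for (d in unique(dup)) {
      vals <- fixed_val[fixed_idx == d]
      if (max(abs(vals - vals[1])) > 1e-12)
        stop("conflicting Dirichlet constraints on dof ", d)
    }
    fixed_val <- fixed_val[keep]
    fixed_idx <- fixed_idx[keep]
  }
  free <- setdiff(seq_len(ndof), fixed_idx)
  uc <- fixed_val

  A_ff <- A[free, free, drop = FALSE]
  rhs <- -(b[free] + if (length(fixed_idx))
    as.numeric(A[free, fixed_idx, drop = FALSE] %*% uc) else 0)

  posdef <- TRUE
  if (stability_check) {
    ## LDL' factorization: the quadratic form is positive definite iff all
    ## pivots are positive (plain LL' can silently "succeed" when indefinite)
    posdef <- tryCatch({
      ch <- Matrix::Cholesky(Matrix::forceSymmetric(A_ff), perm = TRUE,
                             LDL = TRUE)
      all(Matrix::diag(ch) > 0)
    }, error = function(e) FALSE)
    if (!posdef)
      warning("elastic quadratic form is not positive definite on the free dofs; solution may not be a stable minimum")
  }

  if (is.null(E)) {
    x <- as.numeric(Matrix::solve(A_ff, rhs))
  } else {
    E_f <- E[, free, drop = FALSE]
    rhs_e <- f - if (length(fixed_idx))
      as.numeric(E[, fixed_idx, drop = FALSE] %*% uc) else 0
    nc <- nrow(E_f)
    K <- rbind(cbind(A_ff, Matrix::t(E_f)),
               cbind(E_f, Matrix::Matrix(0, nc, nc)))
    sol <- as.numeric(Matrix::solve(K, c(rhs, rhs_e)))
    x <- sol[seq_along(free)]
  }

  U <- numeric(ndof)
  U[free] <- x
  U[fixed_idx] <- uc
  W <- 0.5 * sum(U * as.numeric(A %*% U)) + sum(b * U) + c0
  list(U = U, W = W, posdef = posdef)
}
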
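## Machinery for compiling the elastic energy density of one mesh region into
## a quadratic form over field values and first derivatives ("z-slots"), and
## for accumulating finite-element contributions.
##
## 1D layout: field f occupies slots (2f-1, 2f) = (value, d/dr).
## Radial (cylindrical) measure introduces 1/r factors through
## div n = n' + n/r and the Gaussian term K = n n'/r, so affine expressions
## in z carry two coefficient vectors: a0 (constant) and a1 (times 1/r).
## The compiled region is Q(r) = Q0 + Q1/r + Q2/r^2 (with l(r), c0 alike),
## evaluated per quadrature point.

.expr0 <- function(nz) list(a0 = numeric(nz), a1 = numeric(nz), o = 0)

.expr_slot <- function(nz, slot, coef = 1, invr = FALSE) {
  e <- .expr0(nz)
  if (invr) e$a1[slot] <- coef else e$a0[slot] <- coef
  e
}

.expr_add <- function(...) {
  es <- list(...)
  out <- es[[1]]
  for (e in es[-1]) {
    out$a0 <- out$a0 + e$a0
    out$a1 <- out$a1 + e$a1
    out$o <- out$o + e$o
  }
  out
}

.expr_scale <- function(e, s) {
  e$a0 <- e$a0 * s; e$a1 <- e$a1 * s; e$o <- e$o * s
  e
}

.qf0 <- function(nz) {
  list(Q0 = matrix(0, nz, nz), Q1 = matrix(0, nz, nz), Q2 = matrix(0, nz, nz),
       l0 = numeric(nz), l1 = numeric(nz), c0 = 0, nz = nz)
}

## adds k/2 * (expr + offset)^2
.qf_sq <- function(qf, k, e) {
  qf$Q0 <- qf$Q0 + k * tcrossprod(e$a0)
  qf$Q1 <- qf$Q1 + k * (tcrossprod(e$a0, e$a1) + tcrossprod(e$a1, e$a0))
  qf$Q2 <- qf$Q2 + k * tcrossprod(e$a1)
  qf$l0 <- qf$l0 + k * e$o * e$a0
  qf$l1 <- qf$l1 + k * e$o * e$a1
  qf$c0 <- qf$c0 + k / 2 * e$o^2
  qf
}

## adds k * exprA * exprB
.qf_cross <- function(qf, k, ea, eb) {
  qf$Q0 <- qf$Q0 + k * (tcrossprod(ea$a0, eb$a0) + tcrossprod(eb$a0, ea$a0))
  qf$Q1 <- qf$Q1 + k * (tcrossprod(ea$a0, eb$a1) + tcrossprod(eb$a1, ea$a0) +
                          tcrossprod(ea$a1, eb$a0) + tcrossprod(eb$a0, ea$a1))
  qf$Q2 <- qf$Q2 + k * (tcrossprod(ea$a1, eb$a1) + tcrossprod(eb$a1, ea$a1))
  qf$l0 <- qf$l0 + k * (ea$o * eb$a0 + eb$o * ea$a0)
  qf$l1 <- qf$l1 + k * (ea$o * eb$a1 + eb$o * ea$a1)
  qf$c0 <- qf$c0 + k * ea$o * eb$o
  qf
}

## adds k * expr (linear contribution)
.qf_lin <- function(qf, k, e) {
  qf$l0 <- qf$l0 + k * e$a0
  qf$l1 <- qf$l1 + k * e$a1
  qf$c0 <- qf$c0 + k * e$o
  qf
}

## --- region models, 1D -----------------------------------------------------
##
## mode "bilayer": fields (hu, hl, nu, nl); M eliminated pointwise.
## mode "upper_only_M0": fields (hu, nu); mirror-symmetric half problem, M = 0.
## mode "lower_only": fields (hu, hl, nu, nl) but only lower-monolayer terms
##   (upper monolayer absent, compression annihilated by free M).
##
## pu/pl: monolayer_params; hrefu: local upper reference thickness (patch);
## delta_u = hrefu - bulk upper h. "cyl" metric adds the n/r part of div n
## and the Gaussian 1/r factor; "cart" (translationally invariant section)
## drops them.

.region_1d <- function(mode, pu, pl, hrefu, delta_u, metric = c("cyl", "cart")) {
  metric <- match.arg(metric)
  cyl <- metric == "cyl"
  if (mode == "upper_only_M0") {
    nf <- 2; f_hu <- 1; f_nu <- 2
  } else {
    nf <- 4; f_hu <- 1; f_hl <- 2; f_nu <- 3; f_nl <- 4
  }
  nz <- 2 * nf
  val <- function(f) 2 * f - 1
  der <- function(f) 2 * f

  qf <- .qf0(nz)

  e_div <- function(f) {
    e <- .expr_slot(nz, der(f))
    if (cyl) e$a1[val(f)] <- 1
    e
  }

  add_mono <- function(qf, p, f_h, f_n, upper, href, delta, compression) {
    eD <- e_div(f_n)
    ## splay: B/2 (div n + J0)^2 - B/2 J0^2 = B/2 (div n)^2 + B J0 div n
    qf <- .qf_sq(qf, p$B, eD)
    qf <- .qf_lin(qf, p$B * p$J0, eD)
    ## tilt: upper (n - H'), lower (n + H')
    et <- .expr_add(.expr_slot(nz, val(f_n)),
                    .expr_slot(nz, der(f_h), coef = if (upper) -1 else 1))
    qf <- .qf_sq(qf, p$Kt, et)
    ## tension
    qf <- .qf_sq(qf, p$sigma, .expr_slot(nz, der(f_h)))
    ## Gaussian splay (axisymmetric): KG * n * n' / r
    if (cyl)
      qf <- .qf_cross(qf, p$KG,
                      .expr_slot(nz, val(f_n), invr = TRUE),
                      .expr_slot(nz, der(f_n)))
    ## twist vanishes identically for axisymmetric / 1D sections
    qf
  }

  ## compression residual of one monolayer, as an affine expression:
  ## upper: (href - h_bulk) - href^2/2 div n - hhat + M
  ## lower:             0 - h^2/2 div n + hhat - M   (patch only in upper)
  comp_expr <- function(f_h, f_n, href, delta, upper) {
    e <- .expr_add(.expr_scale(e_div(f_n), -href^2 / 2),
                   .expr_slot(nz, val(f_h), coef = if (upper) -1 else 1))
    e$o <- delta
    e
  }

  if (mode == "bilayer") {
    qf <- add_mono(qf, pu, f_hu, f_nu, upper = TRUE, hrefu, delta_u)
    qf <- add_mono(qf, pl, f_hl, f_nl, upper = FALSE, pl$h, 0)
    cu <- pu$Ka / hrefu^2
    cl <- pl$Ka / pl$h^2
    kc <- cu * cl / (cu + cl)
    eP <- comp_expr(f_hu, f_nu, hrefu, delta_u, upper = TRUE)
    eQ <- comp_expr(f_hl, f_nl, pl$h, 0, upper = FALSE)
    qf <- .qf_sq(qf, kc, .expr_add(eP, eQ))
  } else if (mode == "upper_only_M0") {
    qf <- add_mono(qf, pu, f_hu, f_nu, upper = TRUE, hrefu, delta_u)
    cu <- pu$Ka / hrefu^2
    qf <- .qf_sq(qf, cu, comp_expr(f_hu, f_nu, hrefu, delta_u, upper = TRUE))
  } else if (mode == "lower_only") {
    qf <- add_mono(qf, pl, f_hl, f_nl, upper = FALSE, pl$h, 0)
  } else stop("unknown region mode: ", mode)

  qf$nf <- nf
  qf
}

## --- 1D assembly -----------------------------------------------------------
##
## mesh: list(r = strictly increasing node coordinates, region = integer per
## element). models: list of compiled region quadratic forms (same nf).
## delta_weights: per-region named numeric vector over field names giving the
## integrand of the linear "thickness disturbance" functional, e.g.
## c(hu = 1, hl = -1). fields: character names in slot order.

.gauss2 <- c(-1, 1) / sqrt(3)

assemble_1d <- function(mesh, models, fields, delta_weights,
                        metric = c("cyl", "cart")) {
  metric <- match.arg(metric)
  r <- mesh$r
  nn <- length(r)
  ne <- nn - 1
  nf <- models[[1]]$nf
  stopifnot(length(fields) == nf, length(mesh$region) == ne)
  nz <- 2 * nf
  ndof <- nn * nf
  idx <- function(node, f) (node - 1L) * nf + f

  ntrip <- ne * (2 * nf)^2
  ii <- integer(ntrip); jj <- integer(ntrip); xx <- numeric(ntrip)
  b <- numeric(ndof); dvec <- numeric(ndof); cc <- 0
  pos <- 0L

  ldof <- 2 * nf          # local dofs per element
  for (e in seq_len(ne)) {
    m <- models[[mesh$region[e]]]
    r1 <- r[e]; r2 <- r[e + 1]; le <- r2 - r1
    gdofs <- c(idx(e, seq_len(nf)), idx(e + 1, seq_len(nf)))
    Aloc <- matrix(0, ldof, ldof)
    bloc <- numeric(ldof)
    dloc <- numeric(ldof)
    dw <- delta_weights[[mesh$region[e]]]
    for (q in 1:2) {
      xi <- .gauss2[q]
      rq <- (r1 + r2) / 2 + xi * le / 2
      N <- c((1 - xi) / 2, (1 + xi) / 2)
      dN <- c(-1, 1) / le
      w <- le / 2 * (if (metric == "cyl") 2 * pi * rq else 1)
      ## z = G u ; u ordered (node1 fields..., node2 fields...)
      G <- matrix(0, nz, ldof)
      for (f in seq_len(nf)) {
        G[2 * f - 1, f] <- N[1];       G[2 * f - 1, nf + f] <- N[2]
        G[2 * f,     f] <- dN[1];      G[2 * f,     nf + f] <- dN[2]
      }
      Qr <- m$Q0 + m$Q1 / rq + m$Q2 / rq^2
      lr <- m$l0 + m$l1 / rq
      Aloc <- Aloc + w * crossprod(G, Qr %*% G)
      bloc <- bloc + w * drop(crossprod(G, lr))
      cc <- cc + w * m$c0
      if (!is.null(dw) && length(dw)) {
        for (fn in names(dw)) {
          f <- match(fn, fields)
          dloc[c(f, nf + f)] <- dloc[c(f, nf + f)] + w * dw[[fn]] * N
        }
      }
    }
    span <- pos + seq_len(ldof^2)
    ii[span] <- rep(gdofs, times = ldof)
    jj[span] <- rep(gdofs, each = ldof)
    xx[span] <- as.vector(Aloc)
    pos <- pos + ldof^2
    b[gdofs] <- b[gdofs] + bloc
    dvec[gdofs] <- dvec[gdofs] + dloc
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  list(A = A, b = b, c0 = cc, d = dvec, ndof = ndof, nf = nf,
       idx = function(node, f) (node - 1L) * nf + f, fields = fields)
}
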
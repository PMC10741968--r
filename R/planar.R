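## Planar (non-axisymmetric) solver for an amphipathic peptide lying in the
## upper monolayer. The peptide footprint is a stadium (rectangle of length
## l_p - 2 r_p and width 2 r_p capped by two semicircles); offset curves of a
## stadium are again stadiums, so the domain is meshed by a boundary-fitted
## structured ring mesh: rings of constant offset distance, quads split into
## triangles, degenerate inner rings (the footprint core) merged by node
## deduplication. The footprint interior is meshed too, because the lower
## monolayer and its director remain defined beneath the peptide.

## one closed ring at "radius" rho (rho = r_p on the outline Gamma, > r_p
## outside, < r_p inside; rho = 0 collapses to the core segment).
## Returns coordinates and outward normals (well defined: a stadium is C^1).
.stadium_ring <- function(a, rho, n_str, n_cap) {
  xs_top <- a - (0:(n_str - 1)) * (2 * a / n_str)
  th_l <- pi / 2 + pi * (0:(n_cap - 1)) / n_cap
  xs_bot <- -a + (0:(n_str - 1)) * (2 * a / n_str)
  th_r <- -pi / 2 + pi * (0:(n_cap - 1)) / n_cap
  x <- c(xs_top, -a + rho * cos(th_l), xs_bot, a + rho * cos(th_r))
  y <- c(rep(rho, n_str), rho * sin(th_l), rep(-rho, n_str), rho * sin(th_r))
  nx <- c(rep(0, n_str), cos(th_l), rep(0, n_str), cos(th_r))
  ny <- c(rep(1, n_str), sin(th_l), rep(-1, n_str), sin(th_r))
  list(x = x, y = y, nx = nx, ny = ny)
}

## open quarter ring (x >= 0, y >= 0): from the right-cap apex on y = 0,
## over the quarter cap, along the half straight side to x = 0.
.stadium_quarter_ring <- function(a, rho, n_str, n_cap) {
  m_cap <- n_cap / 2; m_str <- n_str / 2
  th <- pi / 2 * (0:m_cap) / m_cap
  xs <- a - (1:m_str) * (a / m_str)
  x <- c(a + rho * cos(th), xs)
  y <- c(rho * sin(th), rep(rho, m_str))
  nx <- c(cos(th), rep(0, m_str))
  ny <- c(sin(th), rep(1, m_str))
  list(x = x, y = y, nx = nx, ny = ny)
}

## elliptical outline rings (semi-axes aa = l_p/2, bb = r_p): interior rings
## (rho <= r_p) are scaled copies collapsing to the centre; exterior rings
## (rho > r_p) are offset curves along the outward normal (exact for a
## convex outline). "rho" plays the role of the minor semi-axis.
.ellipse_ring <- function(aa, bb, rho, n_str, n_cap, quadrant = FALSE) {
  if (quadrant) {
    m <- (n_str + n_cap) / 2
    t <- pi / 2 * (0:m) / m
  } else {
    ns <- 2 * (n_str + n_cap)
    t <- 2 * pi * (0:(ns - 1)) / ns
  }
  px <- aa * cos(t); py <- bb * sin(t)
  nx <- bb * cos(t); ny <- aa * sin(t)
  nrm <- sqrt(nx^2 + ny^2); nx <- nx / nrm; ny <- ny / nrm
  if (rho <= bb) {
    s <- rho / bb
    list(x = s * px, y = s * py, nx = nx, ny = ny)
  } else {
    d <- rho - bb
    list(x = px + d * nx, y = py + d * ny, nx = nx, ny = ny)
  }
}

#' Boundary-fitted planar mesh around a peptide footprint
#'
#' Structured triangulation of the membrane plane around (and under) the
#' peptide footprint, built from offset curves of the footprint outline
#' (an ellipse with semi-axes `l_p/2`, `r_p`, or a stadium of overall
#' length `l_p` and cap radius `r_p`). Element size grows geometrically
#' with distance from the outline; the outer boundary is the offset curve
#' at distance `L`, where far-field conditions are imposed. The footprint
#' interior is meshed as well (the lower monolayer persists beneath the
#' peptide).
#'
#' @param l_p,r_p footprint length and half-width (cap radius), nm.
#' @param L far-boundary offset distance, nm (>= 30).
#' @param n_cap,n_str boundary intervals per semicircular cap / straight
#'   side (even numbers; for the ellipse they only set the total number of
#'   outline points `2*(n_cap + n_str)`).
#' @param d0 first ring offset, nm.
#' @param grow geometric ring growth factor.
#' @param n_inner number of ring intervals inside the footprint.
#' @param quadrant mesh only the quarter `x >= 0, y >= 0` (for
#'   symmetry-reduced solves).
#' @param outline footprint outline shape, `"ellipse"` (default) or
#'   `"stadium"`.
#' @return list with `nodes` (n x 2), `tri` (ne x 3, positively oriented),
#'   `region` (1 = bilayer exterior, 2 = footprint interior), node index
#'   sets `gamma`, `outer`, `axis_x`, `axis_y`, and outward normals
#'   `gamma_nx`, `gamma_ny` on the outline nodes.
#' @export
planar_mesh <- function(l_p, r_p, L = 30, n_cap = 16, n_str = 24,
                        d0 = 0.05, grow = 1.18, n_inner = 4,
                        quadrant = FALSE,
                        outline = c("ellipse", "stadium")) {
  outline <- match.arg(outline)
  if (L < 30) stop("far boundary L must be at least 30 nm")
  if (n_cap %% 2 || n_str %% 2) stop("n_cap and n_str must be even")
  a <- l_p / 2 - r_p
  ## ring radii: footprint interior (0 .. r_p), outline, exterior offsets
  d <- d0; off <- 0
  while (off < L) { off <- min(off + d, L); d <- d * grow }
  ## rebuild exactly: geometric spacings rescaled to end at L
  nex <- 0; d <- d0; s <- 0
  while (s < L) { s <- s + d; d <- d * grow; nex <- nex + 1 }
  spac <- d0 * grow^(0:(nex - 1))
  spac <- spac * (L / sum(spac))
  rho <- c(r_p * (0:n_inner) / n_inner, r_p + cumsum(spac))
  nring <- length(rho)

  gen <- if (outline == "ellipse") {
    function(rr) .ellipse_ring(l_p / 2, r_p, rr, n_str, n_cap, quadrant)
  } else if (quadrant) {
    function(rr) .stadium_quarter_ring(a, rr, n_str, n_cap)
  } else {
    function(rr) .stadium_ring(a, rr, n_str, n_cap)
  }
  rings <- lapply(rho, gen)
  ns <- length(rings[[1]]$x)
  nodes <- cbind(unlist(lapply(rings, `[[`, "x")),
                 unlist(lapply(rings, `[[`, "y")))

  ## quads between consecutive rings -> two triangles
  tri <- vector("list", nring - 1)
  reg <- vector("list", nring - 1)
  for (i in seq_len(nring - 1)) {
    i0 <- (i - 1) * ns; i1 <- i * ns
    if (quadrant) {
      s1 <- 1:(ns - 1); s2 <- s1 + 1
    } else {
      s1 <- 1:ns; s2 <- c(2:ns, 1)
    }
    A <- i0 + s1; B <- i0 + s2; C <- i1 + s2; D <- i1 + s1
    tri[[i]] <- rbind(cbind(A, B, C), cbind(A, C, D))
    reg[[i]] <- rep(if (rho[i + 1] <= r_p + 1e-9) 2L else 1L,
                    2 * length(s1))
  }
  tri <- do.call(rbind, tri)
  region <- unlist(reg)

  ## merge coincident nodes (degenerate innermost ring), drop null triangles
  key <- paste(round(nodes[, 1], 8), round(nodes[, 2], 8))
  newid <- match(key, unique(key))
  unodes <- nodes[!duplicated(key), , drop = FALSE]
  tri <- matrix(newid[tri], ncol = 3)
  area2 <- (unodes[tri[, 2], 1] - unodes[tri[, 1], 1]) *
           (unodes[tri[, 3], 2] - unodes[tri[, 1], 2]) -
           (unodes[tri[, 3], 1] - unodes[tri[, 1], 1]) *
           (unodes[tri[, 2], 2] - unodes[tri[, 1], 2])
  keep <- abs(area2) > 1e-12
  tri <- tri[keep, , drop = FALSE]
  region <- region[keep]
  area2 <- area2[keep]
  flip <- area2 < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]

  ig <- n_inner + 1          # ring index of the outline
  gamma_old <- (ig - 1) * ns + seq_len(ns)
  gamma <- newid[gamma_old]
  outer <- unique(newid[(nring - 1) * ns + seq_len(ns)])
  g <- rings[[ig]]
  res <- list(nodes = unodes, tri = tri, region = region,
              gamma = gamma, gamma_nx = g$nx, gamma_ny = g$ny,
              outer = outer, l_p = l_p, r_p = r_p, L = L,
              quadrant = quadrant, outline = outline)
  if (quadrant) {
    res$axis_x <- which(abs(unodes[, 2]) < 1e-9)
    res$axis_y <- which(abs(unodes[, 1]) < 1e-9)
  }
  res
}

## --- 2D region energy models ----------------------------------------------
## z-slot layout: field f in (hu, nux, nuy, hl, nlx, nly), component c in
## (value, d/dx, d/dy): slot = 3*(f-1) + c; nz = 18.

.slot2 <- function(f, c) 3L * (f - 1L) + c

.region_2d <- function(mode, pu, pl, hrefu = pu$h, delta_u = 0) {
  nz <- 18L
  qf <- .qf0(nz)
  S <- .slot2
  e <- function(slot, coef = 1) .expr_slot(nz, slot, coef)

  mono2 <- function(qf, p, fh, fnx, fny, upper) {
    eD <- .expr_add(e(S(fnx, 2)), e(S(fny, 3)))
    qf <- .qf_sq(qf, p$B, eD)
    qf <- .qf_lin(qf, p$B * p$J0, eD)
    sgn <- if (upper) -1 else 1
    qf <- .qf_sq(qf, p$Kt, .expr_add(e(S(fnx, 1)), e(S(fh, 2), sgn)))
    qf <- .qf_sq(qf, p$Kt, .expr_add(e(S(fny, 1)), e(S(fh, 3), sgn)))
    qf <- .qf_sq(qf, p$sigma, e(S(fh, 2)))
    qf <- .qf_sq(qf, p$sigma, e(S(fh, 3)))
    qf <- .qf_cross(qf, p$KG, e(S(fnx, 2)), e(S(fny, 3)))
    qf <- .qf_cross(qf, -p$KG, e(S(fnx, 3)), e(S(fny, 2)))
    qf <- .qf_sq(qf, p$Krot, .expr_add(e(S(fny, 2)), e(S(fnx, 3), -1)))
    qf
  }
  comp2 <- function(fh, fnx, fny, href, delta, upper) {
    ee <- .expr_add(e(S(fnx, 2), -href^2 / 2), e(S(fny, 3), -href^2 / 2),
                    e(S(fh, 1), if (upper) -1 else 1))
    ee$o <- delta
    ee
  }

  if (mode == "bilayer") {
    qf <- mono2(qf, pu, 1, 2, 3, upper = TRUE)
    qf <- mono2(qf, pl, 4, 5, 6, upper = FALSE)
    cu <- pu$Ka / hrefu^2
    cl <- pl$Ka / pl$h^2
    kc <- cu * cl / (cu + cl)
    qf <- .qf_sq(qf, kc, .expr_add(comp2(1, 2, 3, hrefu, delta_u, TRUE),
                                   comp2(4, 5, 6, pl$h, 0, FALSE)))
  } else if (mode == "lower_only") {
    ## beneath the footprint: upper monolayer absent; the interface height M
    ## is free there and annihilates the lower compression term
    qf <- mono2(qf, pl, 4, 5, 6, upper = FALSE)
  } else stop("unknown 2D region mode: ", mode)
  qf$nf <- 6L
  qf
}

## --- vectorized P1 assembly ------------------------------------------------

assemble_planar <- function(mesh, models, delta_regions = 1L) {
  nodes <- mesh$nodes; tri <- mesh$tri; region <- mesh$region
  nn <- nrow(nodes); ne <- nrow(tri); nf <- 6L
  ndof <- nn * nf
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  a2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- a2 / 2
  ## P1 shape gradients: grad N_a = (b_a, c_a)
  bmat <- cbind(y2 - y3, y3 - y1, y1 - y2) / a2
  cmat <- cbind(x3 - x2, x1 - x3, x2 - x1) / a2

  ii <- list(); jj <- list(); xx <- list(); pos <- 0L
  bi <- list(); bv <- list(); bpos <- 0L
  di <- list(); dv <- list(); dpos <- 0L
  cc <- 0
  idx <- function(node, f) (node - 1L) * nf + f

  gslot <- function(el, s) {
    f <- (s - 1L) %/% 3L + 1L; c <- (s - 1L) %% 3L + 1L
    list(f = f, c = c,
         g = switch(c, NULL, bmat[el, , drop = FALSE],
                    cmat[el, , drop = FALSE]))
  }

  for (reg in seq_along(models)) {
    el <- which(region == reg)
    if (!length(el)) next
    m <- models[[reg]]
    Q <- m$Q0; l <- m$l0
    ar <- area[el]
    nzpairs <- which(Q != 0, arr.ind = TRUE)
    for (k in seq_len(nrow(nzpairs))) {
      s <- nzpairs[k, 1]; t <- nzpairs[k, 2]
      q <- Q[s, t]
      ss <- gslot(el, s); tt <- gslot(el, t)
      for (aa in 1:3) for (bb in 1:3) {
        ia <- idx(tri[el, aa], ss$f); ib <- idx(tri[el, bb], tt$f)
        v <- if (ss$c == 1 && tt$c == 1) {
          q * ar * (1 + (aa == bb)) / 12
        } else if (ss$c == 1) {
          q * (ar / 3) * tt$g[, bb]
        } else if (tt$c == 1) {
          q * (ar / 3) * ss$g[, aa]
        } else {
          q * ar * ss$g[, aa] * tt$g[, bb]
        }
        pos <- pos + 1L
        ii[[pos]] <- ia; jj[[pos]] <- ib; xx[[pos]] <- v
      }
    }
    for (s in which(l != 0)) {
      ss <- gslot(el, s)
      for (aa in 1:3) {
        bpos <- bpos + 1L
        bi[[bpos]] <- idx(tri[el, aa], ss$f)
        bv[[bpos]] <- if (ss$c == 1) l[s] * ar / 3 else l[s] * ar * ss$g[, aa]
      }
    }
    cc <- cc + m$c0 * sum(ar)
    if (reg %in% delta_regions) {
      for (aa in 1:3) {
        dpos <- dpos + 1L
        di[[dpos]] <- idx(tri[el, aa], 1L); dv[[dpos]] <- ar / 3
        dpos <- dpos + 1L
        di[[dpos]] <- idx(tri[el, aa], 4L); dv[[dpos]] <- -ar / 3
      }
    }
  }
  accum <- function(ix, vx) {
    out <- numeric(ndof)
    if (length(ix)) {
      agg <- rowsum(unlist(vx), unlist(ix))
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  b <- accum(bi, bv)
  dvec <- accum(di, dv)
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ndof, ndof))
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  list(A = A, b = b, c0 = cc, d = dvec, ndof = ndof, idx = idx)
}
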
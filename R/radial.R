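## Axisymmetric solvers: transmembrane peptide and lipid inclusion patch.

#' Graded radial mesh
#'
#' Node sequence from `r_in` to `R_max` with element size growing
#' geometrically away from the inner boundary (where the deformation
#' boundary layer lives), optionally forced to place a node at a break
#' radius (the patch edge).
#'
#' @param r_in inner radius, nm (0 for a patch domain including the origin).
#' @param R_max truncation radius, nm; the far-field ground state is imposed
#'   there. Must exceed `r_in` by at least 20 nm (several decay lengths).
#' @param h0 first element size, nm.
#' @param grow geometric growth factor of element sizes.
#' @param r_break optional radius that must be a mesh node; spacing restarts
#'   at `h0` there (used for the patch edge).
#' @return object of class `radial_mesh`: list with nodes `r` and element
#'   `region` placeholder (filled by the solvers).
#' @export
radial_mesh <- function(r_in, R_max, h0 = 0.005, grow = 1.05, r_break = NULL) {
  if (R_max < r_in + 20)
    stop("R_max must be at least r_in + 20 nm (several decay lengths)")
  seg <- function(a, b, h0, grow) {
    x <- a; h <- h0; out <- a
    while (x + h < b - 0.25 * h) {
      x <- x + h
      out <- c(out, x)
      h <- h * grow
    }
    c(out, b)
  }
  r <- if (!is.null(r_break) && r_break > r_in && r_break < R_max) {
    c(seg(r_in, r_break, h0, 1), seg(r_break, R_max, h0, grow)[-1])
  } else {
    seg(r_in, R_max, h0, grow)
  }
  structure(list(r = r, region = rep(1L, length(r) - 1L)),
            class = "radial_mesh")
}

.mesh_control_radial <- function(mesh) {
  defaults <- list(R_max = 50, h0 = 0.005, grow = 1.05)
  utils::modifyList(defaults, as.list(mesh))
}

.new_deformation <- function(kind, W, Delta, profile, fields, mesh, spec,
                             system, solver = list()) {
  structure(list(kind = kind, W = W, Delta = Delta, profile = profile,
                 fields = fields, mesh = mesh, spec = spec, system = system,
                 solver = solver),
            class = "deformation")
}

## nodal M reconstruction for bilayer radial solutions (M eliminated in the
## energy): M = (c_l * Q - c_u * P) / (c_u + c_l) with P, Q the two
## compression residuals; div n evaluated element-wise then averaged.
.reconstruct_M_radial <- function(r, hu, hl, nu, nl, pu_of_r, system) {
  nn <- length(r)
  mid_div <- function(nvals) {
    dn <- diff(nvals) / diff(r)
    nmid <- (nvals[-1] + nvals[-nn]) / 2
    rmid <- (r[-1] + r[-nn]) / 2
    dn + nmid / pmax(rmid, 1e-9)
  }
  to_nodes <- function(v) {
    out <- numeric(nn)
    out[1] <- v[1]; out[nn] <- v[length(v)]
    if (nn > 2) out[2:(nn - 1)] <- (v[-1] + v[-length(v)]) / 2
    out
  }
  Du <- to_nodes(mid_div(nu)); Dl <- to_nodes(mid_div(nl))
  hl_b <- system$lower$h
  M <- numeric(nn)
  for (i in seq_len(nn)) {
    p <- pu_of_r(r[i])
    cu <- p$Ka / p$h^2
    cl <- system$lower$Ka / hl_b^2
    P <- (p$h - system$upper$h) - p$h^2 / 2 * Du[i] - hu[i]
    Q <- -hl_b^2 / 2 * Dl[i] + hl[i]
    M[i] <- (cl * Q - cu * P) / (cu + cl)
  }
  M
}

#' Solve the axisymmetric transmembrane-peptide problem
#'
#' Minimizes the bilayer elastic energy on the annulus `r_p <= r <= R_max`
#' subject to the essential conditions at the peptide boundary: the radial
#' director projections equal `n0u`/`n0l` on the two neutral surfaces, and
#' the local bilayer thickness equals the peptide hydrophobic length,
#' `H_u(r_p) - H_l(r_p) = h_p`. The rigid peptide's vertical position is
#' free: only the thickness difference is constrained and the mean height at
#' the boundary is determined variationally. The far field is pinned to the
#' unperturbed ground state at `R_max`.
#'
#' @param system a symmetric [bilayer_system()] (same lipid both leaflets).
#' @param spec a [transmembrane_spec()].
#' @param mesh optional list overriding mesh controls `R_max`, `h0`, `grow`.
#' @param refine_check if `TRUE`, re-solve on a mesh with halved `h0` and
#'   doubled `R_max` and fail with a diagnostic error if the thickness
#'   disturbance changes by more than 1\%.
#' @return a `deformation` object with the equilibrium energy `W` \[kBT\],
#'   the thickness disturbance `Delta` \[nm^3\], nodal fields and a radial
#'   thickness profile. `Delta` integrates the thickness deviation over the
#'   total membrane area: the lipid annulus `r > r_p` plus the peptide disk
#'   itself, where the rigid peptide pins the local thickness to `h_p`
#'   (contribution `pi * r_p^2 * (h_p - 2h)`).
#' @examples
#' dopc <- preset_parameters("DOPC")
#' res <- solve_transmembrane(bilayer_system(dopc),
#'                            transmembrane_spec(0.65, 2.9, -0.4))
#' res$Delta
#' @export
solve_transmembrane <- function(system, spec, mesh = list(),
                                refine_check = FALSE) {
  stopifnot(inherits(system, "bilayer_system"),
            inherits(spec, "transmembrane_spec"))
  if (!.is_symmetric_bilayer(system))
    stop("bulk bilayer must be symmetric (upper == lower parameters)")
  mc <- .mesh_control_radial(mesh)
  msh <- radial_mesh(spec$r_p, mc$R_max, mc$h0, mc$grow)
  res <- .solve_tm_on_mesh(system, spec, msh)
  if (refine_check) {
    msh2 <- radial_mesh(spec$r_p, 2 * mc$R_max, mc$h0 / 2, sqrt(mc$grow))
    res2 <- .solve_tm_on_mesh(system, spec, msh2)
    ref <- max(abs(res2$Delta), 1e-8)
    if (abs(res$Delta - res2$Delta) > 0.01 * ref)
      stop(sprintf(
        "mesh convergence failure: Delta = %.6g vs %.6g on refined mesh",
        res$Delta, res2$Delta))
  }
  res
}

.solve_tm_on_mesh <- function(system, spec, msh) {
  h <- system$upper$h
  model <- .region_1d("bilayer", system$upper, system$lower,
                      hrefu = h, delta_u = 0, metric = "cyl")
  fields <- c("hu", "hl", "nu", "nl")
  asm <- assemble_1d(msh, list(model), fields,
                     delta_weights = list(c(hu = 1, hl = -1)))
  nn <- length(msh$r)
  id <- asm$idx
  fixed_idx <- c(id(nn, 1:4), id(1, 3), id(1, 4))
  fixed_val <- c(rep(0, 4), spec$n0u, spec$n0l)
  E <- Matrix::sparseMatrix(i = c(1, 1), j = c(id(1, 1), id(1, 2)),
                            x = c(1, -1), dims = c(1, asm$ndof))
  sol <- solve_quadratic(asm$A, asm$b, asm$c0, fixed_idx, fixed_val,
                         E = E, f = spec$h_p - 2 * h)
  res <- .finish_radial(sol, asm, msh, system, spec, "transmembrane",
                        pu_of_r = function(r) system$upper)
  ## peptide disk: thickness pinned at h_p over the footprint area
  res$Delta <- res$Delta + pi * spec$r_p^2 * (spec$h_p - 2 * h)
  res
}

.finish_radial <- function(sol, asm, msh, system, spec, kind, pu_of_r) {
  nn <- length(msh$r)
  U <- sol$U
  get <- function(f) U[asm$idx(seq_len(nn), f)]
  hu <- get(1); hl <- get(2); nu <- get(3); nl <- get(4)
  h_u <- system$upper$h; h_l <- system$lower$h
  M <- .reconstruct_M_radial(msh$r, hu, hl, nu, nl, pu_of_r, system)
  profile <- data.frame(r = msh$r,
                        H_u = h_u + hu, H_l = -h_l + hl, M = M,
                        n_u_r = nu, n_l_r = nl,
                        thickness = (h_u + h_l) + hu - hl)
  Delta <- sum(asm$d * U)
  fields <- list(r = msh$r, hu = hu, hl = hl, nu = nu, nl = nl, M = M)
  .new_deformation(kind, sol$W, Delta, profile, fields, msh, spec, system,
                   solver = list(posdef = sol$posdef, nodes = nn))
}

#' Solve the axisymmetric lipid-inclusion (monolayer patch) problem
#'
#' A circular patch of a different lipid occupies the upper monolayer for
#' `r < r_lip`; there the upper monolayer uses the patch elastic parameters
#' and its own reference thickness in the compression term. No essential
#' boundary conditions are imposed at the patch edge: the neutral surface
#' and director are continuous there and the natural (variational) matching
#' arises from assembling a single energy with piecewise coefficients. At
#' the origin the radial director components vanish by regularity; the far
#' field is pinned to the ground state at `R_max`.
#'
#' @inheritParams solve_transmembrane
#' @param spec a [lipid_inclusion_spec()].
#' @return a `deformation` object; `Delta` integrates the thickness
#'   deviation over the full plane including the patch disk.
#' @examples
#' dopc <- preset_parameters("DOPC")
#' inc <- preset_parameters("inclusion_common")
#' sp <- lipid_inclusion_spec(0.5, 1.35, inc)
#' solve_lipid_inclusion(bilayer_system(dopc), sp)$Delta
#' @export
solve_lipid_inclusion <- function(system, spec, mesh = list(),
                                  refine_check = FALSE) {
  stopifnot(inherits(system, "bilayer_system"),
            inherits(spec, "lipid_inclusion_spec"))
  if (!.is_symmetric_bilayer(system))
    stop("bulk bilayer must be symmetric (upper == lower parameters)")
  mc <- .mesh_control_radial(mesh)
  solve1 <- function(h0, grow, R_max) {
    msh <- radial_mesh(0, R_max, h0, grow, r_break = spec$r_lip)
    rmid <- (msh$r[-1] + msh$r[-length(msh$r)]) / 2
    msh$region <- ifelse(rmid < spec$r_lip, 2L, 1L)
    h <- system$upper$h
    bulk <- .region_1d("bilayer", system$upper, system$lower,
                       hrefu = h, delta_u = 0, metric = "cyl")
    patch <- .region_1d("bilayer", spec$params_inc, system$lower,
                        hrefu = spec$h_inc, delta_u = spec$h_inc - h,
                        metric = "cyl")
    fields <- c("hu", "hl", "nu", "nl")
    dw <- c(hu = 1, hl = -1)
    asm <- assemble_1d(msh, list(bulk, patch), fields,
                       delta_weights = list(dw, dw))
    nn <- length(msh$r)
    id <- asm$idx
    fixed_idx <- c(id(nn, 1:4), id(1, 3), id(1, 4))
    fixed_val <- rep(0, 6)
    sol <- solve_quadratic(asm$A, asm$b, asm$c0, fixed_idx, fixed_val)
    .finish_radial(sol, asm, msh, system, spec, "lipid_inclusion",
                   pu_of_r = function(r)
                     if (r < spec$r_lip) spec$params_inc else system$upper)
  }
  res <- solve1(mc$h0, mc$grow, mc$R_max)
  if (refine_check) {
    res2 <- solve1(mc$h0 / 2, sqrt(mc$grow), 2 * mc$R_max)
    ref <- max(abs(res2$Delta), 1e-4)
    if (abs(res$Delta - res2$Delta) > 0.01 * ref)
      stop(sprintf(
        "mesh convergence failure: Delta = %.6g vs %.6g on refined mesh",
        res$Delta, res2$Delta))
  }
  res
}

#' Mirror-symmetric reduction of the transmembrane problem
#'
#' For a symmetric peptide (`n0u == n0l`) in a symmetric bilayer the
#' solution is mirror-symmetric about the monolayer interface:
#' `H_l = -H_u`, `M = 0`. This solves the upper-monolayer half problem with
#' `M = 0` and `H_u(r_p) = h_p/2` and doubles the energy, providing an
#' internal consistency oracle for the full two-monolayer solve.
#'
#' @inheritParams solve_transmembrane
#' @return a `deformation` object (kind `"transmembrane_half"`).
#' @export
reduce_symmetric <- function(system, spec, mesh = list()) {
  stopifnot(inherits(system, "bilayer_system"),
            inherits(spec, "transmembrane_spec"))
  if (!.is_symmetric_tm(spec))
    stop("reduce_symmetric requires a mirror-symmetric spec (n0u == n0l)")
  if (!.is_symmetric_bilayer(system))
    stop("bulk bilayer must be symmetric (upper == lower parameters)")
  mc <- .mesh_control_radial(mesh)
  msh <- radial_mesh(spec$r_p, mc$R_max, mc$h0, mc$grow)
  h <- system$upper$h
  model <- .region_1d("upper_only_M0", system$upper, system$lower,
                      hrefu = h, delta_u = 0, metric = "cyl")
  asm <- assemble_1d(msh, list(model), c("hu", "nu"),
                     delta_weights = list(c(hu = 2)))
  nn <- length(msh$r)
  id <- asm$idx
  fixed_idx <- c(id(nn, 1:2), id(1, 1), id(1, 2))
  fixed_val <- c(0, 0, (spec$h_p - 2 * h) / 2, spec$n0u)
  sol <- solve_quadratic(asm$A, asm$b, asm$c0, fixed_idx, fixed_val)
  U <- sol$U
  hu <- U[id(seq_len(nn), 1)]; nu <- U[id(seq_len(nn), 2)]
  profile <- data.frame(r = msh$r, H_u = h + hu, H_l = -h - hu, M = 0,
                        n_u_r = nu, n_l_r = nu,
                        thickness = 2 * h + 2 * hu)
  Delta <- sum(asm$d * U) + pi * spec$r_p^2 * (spec$h_p - 2 * h)
  .new_deformation("transmembrane_half", 2 * sol$W, Delta,
                   profile, list(r = msh$r, hu = hu, nu = nu),
                   msh, spec, system,
                   solver = list(posdef = sol$posdef, nodes = nn))
}

#' Radial thickness profile of a solved deformation
#'
#' @param result a `deformation` object from one of the axisymmetric
#'   solvers.
#' @return data frame with columns `r` \[nm\] and `thickness`
#'   (`H_u - H_l`) \[nm\], monotone in `r`.
#' @export
thickness_profile <- function(result) {
  stopifnot(inherits(result, "deformation"))
  if (is.null(result$profile$r))
    stop("thickness_profile requires an axisymmetric result; use thickness_map for planar solves")
  result$profile[, c("r", "thickness")]
}
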
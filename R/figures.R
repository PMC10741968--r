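#' Regenerate the package's validation figures
#'
#' Produces the standard validation plots of the model as PNG files:
#' the planar thickness map around an amphipathic peptide; radial
#' thickness profiles near a transmembrane peptide for several boundary
#' directors and lengths; lipid-patch thickness profiles for several patch
#' thicknesses; the thickness disturbance of a "common" lipid patch as a
#' function of patch thickness and spontaneous curvature at several patch
#' splay moduli; and the thin-patch disturbance versus splay modulus.
#' These are validation surfaces (values computed by the solvers), not
#' reproductions of any published artwork.
#'
#' @param dir output directory.
#' @param which subset of figures to produce.
#' @param mesh optional solver mesh controls (passed to the radial
#'   solvers).
#' @param coarse use coarser probe grids (faster; used by the test suite).
#' @return invisibly, a list of the data frames underlying each figure.
#' @export
reproduce_figures <- function(dir,
                              which = c("amphipathic", "transmembrane",
                                        "lipid_profiles", "delta_common",
                                        "delta_thin"),
                              mesh = list(), coarse = FALSE) {
  which <- match.arg(which, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dopc <- preset_parameters("DOPC")
  sys <- bilayer_system(dopc)
  h <- dopc$h
  out <- list()

  png_open <- function(name) grDevices::png(file.path(dir, name),
                                            width = 900, height = 700,
                                            res = 120)

  if ("amphipathic" %in% which) {
    res <- solve_amphipathic(sys, amphipathic_spec(5, 0.65, -0.4),
                             mesh = if (coarse) list(n_cap = 8, n_str = 12,
                                                     d0 = 0.1, grow = 1.3,
                                                     n_inner = 2) else list())
    mp <- thickness_map(res, nx = if (coarse) 41 else 81,
                        ny = if (coarse) 41 else 81,
                        xlim = c(-8, 8), ylim = c(-8, 8))
    png_open("amphipathic_thickness_map.png")
    z <- matrix(mp$thickness, nrow = length(unique(mp$x)))
    graphics::image(unique(mp$x), unique(mp$y), z,
                    xlab = "x [nm]", ylab = "y [nm]",
                    main = "Bilayer thickness around an amphipathic peptide (n0 = -0.4)")
    grDevices::dev.off()
    out$amphipathic <- mp
  }

  if ("transmembrane" %in% which) {
    grid <- expand.grid(n0 = c(-0.4, 0, 0.4), h_p = c(2, 2 * h))
    profs <- lapply(seq_len(nrow(grid)), function(i) {
      r <- solve_transmembrane(sys, transmembrane_spec(0.65, grid$h_p[i],
                                                       grid$n0[i]),
                               mesh = mesh)
      cbind(thickness_profile(r), n0 = grid$n0[i], h_p = grid$h_p[i])
    })
    df <- do.call(rbind, profs)
    png_open("transmembrane_profiles.png")
    graphics::par(mfrow = c(1, 2))
    for (hp in unique(df$h_p)) {
      sub <- df[df$h_p == hp & df$r <= 10, ]
      graphics::plot(NULL, xlim = c(0.65, 10), ylim = range(sub$thickness),
                     xlab = "r [nm]", ylab = "thickness [nm]",
                     main = sprintf("h_p = %.2g nm", hp))
      cols <- c("darkgreen", "blue", "red")
      for (k in seq_along(unique(sub$n0))) {
        s2 <- sub[sub$n0 == unique(sub$n0)[k], ]
        graphics::lines(s2$r, s2$thickness, col = cols[k])
      }
      graphics::abline(h = 2 * h, lty = 3)
    }
    grDevices::dev.off()
    out$transmembrane <- df
  }

  if ("lipid_profiles" %in% which) {
    pin <- preset_parameters("inclusion_common")
    pin$J0 <- 0
    profs <- lapply(c(1.35, 1.45, 1.55), function(hi) {
      r <- solve_lipid_inclusion(sys, lipid_inclusion_spec(0.5, hi, pin),
                                 mesh = mesh)
      cbind(thickness_profile(r), h_inc = hi)
    })
    df <- do.call(rbind, profs)
    png_open("lipid_patch_profiles.png")
    sub <- df[df$r <= 10, ]
    graphics::plot(NULL, xlim = c(0, 10), ylim = range(sub$thickness),
                   xlab = "r [nm]", ylab = "thickness [nm]",
                   main = "Lipid patch, B_inc = 10 kBT, J0inc = 0")
    cols <- c(red = 1.35, blue = 1.45, darkgreen = 1.55)
    for (k in seq_along(cols)) {
      s2 <- sub[sub$h_inc == cols[k], ]
      graphics::lines(s2$r, s2$thickness, col = names(cols)[k])
    }
    graphics::abline(h = 2 * h, lty = 3)
    grDevices::dev.off()
    out$lipid_profiles <- df
  }

  if ("delta_common" %in% which) {
    h_incs <- if (coarse) c(1.2, 1.45, 1.7) else seq(1.2, 1.7, by = 0.1)
    J0s <- if (coarse) c(-0.6, 0, 0.2) else seq(-0.6, 0.2, by = 0.2)
    Bs <- c(5, 10, 20)
    grid <- expand.grid(h_inc = h_incs, J0inc = J0s, B_inc = Bs)
    pin0 <- preset_parameters("inclusion_common")
    grid$Delta <- mapply(function(hi, j0, bb) {
      p <- pin0; p$B <- bb; p$J0 <- j0
      solve_lipid_inclusion(sys, lipid_inclusion_spec(0.5, hi, p),
                            mesh = mesh)$Delta
    }, grid$h_inc, grid$J0inc, grid$B_inc)
    png_open("lipid_patch_delta.png")
    graphics::par(mfrow = c(1, 3))
    for (bb in Bs) {
      sub <- grid[grid$B_inc == bb, ]
      graphics::plot(NULL, xlim = range(h_incs), ylim = range(grid$Delta),
                     xlab = "h_inc [nm]", ylab = "Delta [nm^3]",
                     main = sprintf("B_inc = %g kBT", bb))
      for (j0 in J0s) {
        s2 <- sub[sub$J0inc == j0, ]
        graphics::lines(s2$h_inc, s2$Delta, type = "b", pch = 19,
                        col = grDevices::hcl.colors(length(J0s))[match(j0, J0s)])
      }
      graphics::abline(h = 0, v = h, lty = 3)
    }
    grDevices::dev.off()
    out$delta_common <- grid
  }

  if ("delta_thin" %in% which) {
    pin0 <- preset_parameters("inclusion_thin")
    Bs <- if (coarse) c(5, 10, 20) else seq(4, 20, by = 2)
    J0s <- c(-0.6, -0.4, -0.2, 0, 0.2)
    grid <- expand.grid(B_inc = Bs, J0inc = J0s)
    grid$Delta <- mapply(function(bb, j0) {
      p <- pin0; p$B <- bb; p$J0 <- j0
      solve_lipid_inclusion(sys, lipid_inclusion_spec(0.662, 0.7, p),
                            mesh = mesh)$Delta
    }, grid$B_inc, grid$J0inc)
    png_open("thin_patch_delta.png")
    graphics::plot(NULL, xlim = range(Bs), ylim = range(grid$Delta),
                   xlab = "B_inc [kBT]", ylab = "Delta [nm^3]",
                   main = "Thin lipid patch (h_inc = 0.7 nm)")
    for (j0 in J0s) {
      s2 <- grid[grid$J0inc == j0, ]
      graphics::lines(s2$B_inc, s2$Delta, type = "b", pch = 19,
                      col = grDevices::hcl.colors(length(J0s))[match(j0, J0s)])
    }
    grDevices::dev.off()
    out$delta_thin <- grid
  }

  invisible(out)
}
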
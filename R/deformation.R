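## S3 methods for solved deformation states.

#' @export
print.deformation <- function(x, ...) {
  cat(sprintf("Membrane deformation (%s inclusion)\n", x$kind))
  cat(sprintf("  W     = %10.5f kBT   (elastic energy)\n", x$W))
  cat(sprintf("  Delta = %10.5f nm^3  (thickness disturbance)\n", x$Delta))
  cat(sprintf("  nodes = %d%s\n", x$solver$nodes,
              if (isTRUE(x$solver$quadrant)) " (quadrant solve)" else ""))
  invisible(x)
}

#' @export
summary.deformation <- function(object, ...) {
  print(object)
  h2 <- object$system$upper$h + object$system$lower$h
  th <- object$profile$thickness
  th <- th[is.finite(th)]
  cat(sprintf("  thickness range: [%.4f, %.4f] nm (unperturbed %.3f nm)\n",
              min(th), max(th), h2))
  if (!is.null(object$profile$r))
    cat(sprintf("  profile: %d radial nodes, r in [%.3g, %.3g] nm\n",
                nrow(object$profile), min(object$profile$r),
                max(object$profile$r)))
  invisible(object)
}

#' Plot a solved deformation
#'
#' Axisymmetric results plot the radial thickness profile
#' `H_u - H_l` versus `r`; planar results plot thickness along the two
#' symmetry axes.
#'
#' @param x a `deformation` object.
#' @param rmax largest radius / coordinate to show, nm.
#' @param ... passed to [graphics::plot()].
#' @export
plot.deformation <- function(x, rmax = 10, ...) {
  h2 <- x$system$upper$h + x$system$lower$h
  if (!is.null(x$profile$r)) {
    keep <- x$profile$r <= rmax
    graphics::plot(x$profile$r[keep], x$profile$thickness[keep], type = "l",
                   xlab = "r [nm]", ylab = "bilayer thickness [nm]", ...)
  } else {
    f <- x$fields
    on_x <- which(abs(f$y) < 1e-9 & f$exterior & abs(f$x) <= rmax)
    on_x <- on_x[order(f$x[on_x])]
    graphics::plot(f$x[on_x], 2 * x$system$upper$h + f$hu[on_x] - f$hl[on_x],
                   type = "l", xlab = "x (along helix) [nm]",
                   ylab = "bilayer thickness [nm]", ...)
  }
  graphics::abline(h = h2, lty = 3)
  invisible(x)
}
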
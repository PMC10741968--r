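#' Generate a synthetic average-thickness versus concentration series
#'
#' Emulates an experimental dilute-regime thickness measurement: points
#' follow the affine law `<d>_i = 2h + C_i * eta * n0_true` with additive
#' i.i.d. Gaussian noise of standard deviation `noise_sd`. Reproducible for
#' a fixed seed.
#'
#' @param n0_true true boundary director projection of the generating
#'   peptide.
#' @param eta amphipathic response coefficient, nm^3.
#' @param h monolayer hydrophobic thickness, nm.
#' @param C surface concentration grid, 1/nm^2 (non-negative, increasing).
#' @param noise_sd thickness noise standard deviation, nm (>= 0).
#' @param seed integer seed; mandatory when `noise_sd > 0`.
#' @return a `thickness_series` data frame (columns `concentration`
#'   \[1/nm^2\], `thickness` \[nm\], `sd` \[nm\]) with the generating
#'   parameters in attributes.
#' @examples
#' generate_series(-0.42, eta = 9.16, h = 1.45,
#'                 C = seq(0.002, 0.016, by = 0.002),
#'                 noise_sd = 0.01, seed = 7)
#' @export
generate_series <- function(n0_true, eta, h, C, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is mandatory for stochastic generation")
  if (any(C < 0) || is.unsorted(C)) stop("C must be non-negative, increasing")
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise_sd > 0) stats::rnorm(length(C), 0, noise_sd) else 0
  structure(data.frame(concentration = C,
                       thickness = 2 * h + C * eta * n0_true + eps,
                       sd = rep(noise_sd, length(C))),
            class = c("thickness_series", "data.frame"),
            h = h, eta = eta, n0_true = n0_true, noise_sd = noise_sd,
            seed = seed)
}

#' @export
print.thickness_series <- function(x, ...) {
  cat(sprintf("Thickness series: %d points, C in [%.4g, %.4g] 1/nm^2", nrow(x),
              min(x$concentration), max(x$concentration)))
  ns <- attr(x, "noise_sd")
  if (!is.null(ns)) cat(sprintf(", noise sd %.3g nm", ns))
  cat("\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.thickness_series <- function(x, ...) {
  graphics::plot(x$concentration, x$thickness,
                 xlab = "surface concentration C [1/nm^2]",
                 ylab = "average thickness <d> [nm]",
                 pch = 19, ...)
  if (!is.null(attr(x, "h")) && !is.null(attr(x, "eta")) &&
      !is.null(attr(x, "n0_true")))
    graphics::abline(2 * attr(x, "h"), attr(x, "eta") * attr(x, "n0_true"),
                     lty = 2)
  invisible(x)
}

#' Read / write thickness series as CSV
#'
#' Plain-text exchange format: a header row then one line per point with
#' columns `concentration_or_molefraction`, `thickness_nm` and optional
#' `sd_nm`. `kind` declares how the first column is to be interpreted.
#'
#' @param path file path.
#' @param kind `"concentration"` (1/nm^2) or `"molefraction"`.
#' @return `read_thickness_series`: a `thickness_series` data frame.
#' @export
read_thickness_series <- function(path, kind = c("concentration", "molefraction")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  out <- data.frame(thickness = df$thickness_nm)
  out[[kind]] <- df$concentration_or_molefraction
  if ("sd_nm" %in% names(df)) out$sd <- df$sd_nm
  structure(out[, c(kind, "thickness",
                    intersect("sd", names(out))), drop = FALSE],
            class = c("thickness_series", "data.frame"))
}

#' @rdname read_thickness_series
#' @param series a `thickness_series`.
#' @export
write_thickness_series <- function(series, path) {
  df <- as.data.frame(series)
  cc <- if ("concentration" %in% names(df)) df$concentration else df$molefraction
  out <- data.frame(concentration_or_molefraction = cc,
                    thickness_nm = df$thickness)
  if ("sd" %in% names(df)) out$sd_nm <- df$sd
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
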
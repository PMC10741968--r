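## Linear-response analysis: extraction of the thickness-disturbance
## coefficients from repeated solves, the forward thickness-concentration
## relation, and the inverse fit of the boundary director.

.new_response <- function(coefs, fit, probes, what) {
  structure(list(coefficients = coefs, fit = fit, probes = probes,
                 what = what), class = "delta_response")
}

#' @export
print.delta_response <- function(x, ...) {
  cat(sprintf("Thickness-disturbance response (%s):\n", x$what))
  print(round(x$coefficients, 4))
  cat(sprintf("  max |fit residual| = %.3g, intercept = %.3g\n",
              max(abs(x$fit$residuals)), x$fit$intercept))
  invisible(x)
}

#' @export
coef.delta_response <- function(object, ...) object$coefficients

## common linearity diagnostics: refit with free intercept and flag
## departures from the expected exact linearity of a quadratic model
.lin_diag <- function(X, y, coefs, rel_tol = 1e-3) {
  pred <- as.numeric(X %*% coefs)
  res <- y - pred
  fit2 <- stats::lm.fit(cbind(1, X), y)
  scale <- max(abs(y), 1e-12)
  if (max(abs(res)) > rel_tol * scale)
    warning(sprintf(
      "linear-response fit residuals (%.3g) exceed %.1g of the response scale; solver may be misconfigured",
      max(abs(res)), rel_tol))
  list(residuals = res, intercept = unname(fit2$coefficients[1]))
}

#' Extract the amphipathic-peptide response coefficient
#'
#' Solves the planar problem at several probe values of the boundary
#' director `n0` and returns the zero-intercept slope `eta` of the
#' thickness disturbance, `Delta = eta * n0` \[nm^3\]. The quadratic energy
#' makes the dependence exactly linear; a nonzero intercept or large
#' residuals indicate a solver misconfiguration and are flagged.
#'
#' @param system a symmetric [bilayer_system()].
#' @param l_p,r_p footprint geometry, nm.
#' @param n0_probes at least two distinct probe values.
#' @param ... further arguments passed to [solve_amphipathic()] (e.g.
#'   `mesh`, `quadrant`, `outline`).
#' @return a `delta_response` object with coefficient `eta` and fit
#'   diagnostics (free intercept, residuals).
#' @examples
#' \donttest{
#' eta <- extract_eta(bilayer_system(preset_parameters("DOPC")),
#'                    quadrant = TRUE)
#' coef(eta)      # ~ 10 nm^3
#' }
#' @export
extract_eta <- function(system, l_p = 5, r_p = 0.65,
                        n0_probes = c(-0.4, -0.2, 0.2, 0.4), ...) {
  if (length(unique(n0_probes)) < 2)
    stop("need at least two distinct n0 probe values")
  Delta <- vapply(n0_probes, function(n0)
    solve_amphipathic(system, amphipathic_spec(l_p, r_p, n0), ...)$Delta,
    numeric(1))
  eta <- sum(Delta * n0_probes) / sum(n0_probes^2)
  diag <- .lin_diag(matrix(n0_probes), Delta, eta)
  .new_response(c(eta = eta), diag, data.frame(n0 = n0_probes, Delta = Delta),
                "amphipathic peptide, Delta = eta * n0")
}

#' Extract the transmembrane-peptide response coefficients
#'
#' Solves the axisymmetric transmembrane problem over a probe grid of
#' boundary director `n0` and hydrophobic length `h_p`, and fits the
#' bilinear zero-intercept law `Delta = beta * n0 + gamma * (h_p - 2h)`.
#'
#' @param system a symmetric [bilayer_system()].
#' @param r_p peptide radius, nm.
#' @param n0_probes,h_p_probes probe values spanning both axes.
#' @param ... passed to [solve_transmembrane()].
#' @return a `delta_response` with coefficients `beta` \[nm^3\] and `gamma`
#'   \[nm^2\].
#' @examples
#' bg <- extract_beta_gamma(bilayer_system(preset_parameters("DOPC")))
#' coef(bg)       # beta ~ 10.7 nm^3, gamma ~ 3.9 nm^2
#' @export
extract_beta_gamma <- function(system, r_p = 0.65,
                               n0_probes = c(-0.4, 0, 0.4),
                               h_p_probes = c(2.0, 2.9, 3.4), ...) {
  grid <- expand.grid(n0 = n0_probes, h_p = h_p_probes)
  X <- cbind(n0 = grid$n0, mismatch = grid$h_p - 2 * system$upper$h)
  ## a grid restricted to one axis still identifies that axis' coefficient;
  ## a grid spanning neither (or collinear in both) is rejected
  active <- c(any(X[, 1] != 0), any(X[, 2] != 0))
  if (qr(X[, active, drop = FALSE])$rank < sum(active) || !any(active))
    stop("probe grid is rank deficient: span both n0 and h_p axes")
  grid$Delta <- mapply(function(n0, h_p)
    solve_transmembrane(system, transmembrane_spec(r_p, h_p, n0), ...)$Delta,
    grid$n0, grid$h_p)
  cf <- c(n0 = NA_real_, mismatch = NA_real_)
  cf[active] <- stats::lm.fit(X[, active, drop = FALSE],
                              grid$Delta)$coefficients
  diag <- .lin_diag(X[, active, drop = FALSE], grid$Delta, cf[active])
  .new_response(c(beta = unname(cf[1]), gamma = unname(cf[2])), diag, grid,
                "transmembrane peptide, Delta = beta*n0 + gamma*(h_p - 2h)")
}

#' Extract the lipid-inclusion affinity in the spontaneous curvature
#'
#' Solves the lipid-patch problem at several spontaneous curvatures of the
#' patch lipid (all else fixed) and fits the affine law
#' `Delta = k * J0inc + b`.
#'
#' @param system a symmetric [bilayer_system()].
#' @param r_lip patch radius, nm.
#' @param h_inc patch monolayer thickness, nm.
#' @param params_inc patch [monolayer_params()]; its `J0` is replaced by
#'   each probe in turn.
#' @param J0inc_probes at least two distinct probe curvatures, 1/nm.
#' @param ... passed to [solve_lipid_inclusion()].
#' @return a `delta_response` with coefficients `k` \[nm^4\] and `b`
#'   \[nm^3\].
#' @export
extract_k_b <- function(system, r_lip = 0.5, h_inc, params_inc,
                        J0inc_probes = c(-0.4, 0, 0.2), ...) {
  if (length(unique(J0inc_probes)) < 2)
    stop("need at least two distinct J0inc probe values")
  Delta <- vapply(J0inc_probes, function(j) {
    p <- params_inc; p$J0 <- j
    solve_lipid_inclusion(system, lipid_inclusion_spec(r_lip, h_inc, p),
                          ...)$Delta
  }, numeric(1))
  X <- cbind(1, J0inc_probes)
  cf <- stats::lm.fit(X, Delta)$coefficients
  res <- Delta - as.numeric(X %*% cf)
  scale <- max(abs(Delta), 1e-12)
  if (max(abs(res)) > 1e-3 * scale)
    warning("affine fit residuals unexpectedly large for a quadratic model")
  .new_response(c(k = unname(cf[2]), b = unname(cf[1])),
                list(residuals = res, intercept = unname(cf[1])),
                data.frame(J0inc = J0inc_probes, Delta = Delta),
                "lipid inclusion, Delta = k*J0inc + b")
}

#' Forward average-thickness versus concentration relation
#'
#' In the dilute regime the average bilayer thickness is affine in the
#' inclusion surface concentration: `<d> = 2h + C * Delta`. Warns when the
#' requested concentrations leave the linear regime (above about 1/65
#' inclusion per lipid, deformation zones overlap).
#'
#' @param C_values surface concentrations, 1/nm^2 (non-negative,
#'   increasing).
#' @param Delta single-inclusion thickness disturbance, nm^3.
#' @param h monolayer hydrophobic thickness, nm.
#' @param A_L area per lipid, nm^2, used only for the linear-regime check
#'   (mole fraction x = C*A_L/2 per leaflet-pair); default 0.65 nm^2.
#' @return a `thickness_series` data frame with columns `concentration`
#'   \[1/nm^2\] and `thickness` \[nm\].
#' @export
forward_thickness <- function(C_values, Delta, h, A_L = 0.65) {
  if (any(C_values < 0)) stop("concentrations must be non-negative")
  if (is.unsorted(C_values, strictly = FALSE))
    stop("concentrations must be increasing")
  x <- C_values * A_L / 2
  if (any(x > 1 / 65))
    warning("concentrations exceed the linear regime (~1/65 inclusion per lipid); the affine law overestimates additivity")
  structure(data.frame(concentration = C_values,
                       thickness = 2 * h + C_values * Delta),
            class = c("thickness_series", "data.frame"),
            h = h, Delta = Delta, noise_sd = 0)
}

#' Fit the boundary director from a thickness-concentration series
#'
#' Inverse analysis of experimental-style data: weighted least squares of
#' average thickness `<d>` on inclusion surface concentration `C` gives a
#' slope `s = eta * n0`, from which the boundary director is `n0 = s/eta`
#' with a confidence interval propagated from the fit covariance. Series
#' given per mole fraction are converted with `C = 2 x / A_L` (inclusions
#' per bilayer area, lipids counted in both leaflets; use
#' `leaflets = "one"` for per-leaflet mole fractions, `C = x / A_L`).
#'
#' @param series a `thickness_series` (see [generate_series()],
#'   [read_thickness_series()]) or a data frame with columns
#'   `concentration` (or `molefraction`) and `thickness`, optionally `sd`.
#' @param eta amphipathic response coefficient, nm^3 (from
#'   [extract_eta()]).
#' @param h monolayer hydrophobic thickness, nm (fixes the intercept
#'   diagnostic; the intercept itself is fitted freely).
#' @param A_L area per lipid, nm^2; required when the series is given per
#'   mole fraction.
#' @param leaflets `"both"` (default) or `"one"`: whether mole fractions
#'   count lipids of both leaflets or one.
#' @param level confidence level for the interval.
#' @return an object of class `n0_fit` with `coef`, `confint`, `print`,
#'   `summary` methods.
#' @examples
#' s <- generate_series(n0_true = -0.4, eta = 9.16, h = 1.45,
#'                      C = seq(0.001, 0.015, length.out = 8),
#'                      noise_sd = 0, seed = 1)
#' coef(fit_n0(s, eta = 9.16, h = 1.45))   # -0.4
#' @export
fit_n0 <- function(series, eta, h, A_L = NULL,
                   leaflets = c("both", "one"), level = 0.95) {
  leaflets <- match.arg(leaflets)
  df <- as.data.frame(series)
  if ("molefraction" %in% names(df)) {
    if (is.null(A_L))
      stop("A_L (area per lipid, nm^2) is required to convert mole fractions")
    df$concentration <- df$molefraction * (if (leaflets == "both") 2 else 1) / A_L
  }
  if (!all(c("concentration", "thickness") %in% names(df)))
    stop("series must have 'concentration' (or 'molefraction') and 'thickness' columns")
  if (nrow(df) < 3)
    stop("insufficient points: need at least 3 for fitting")
  if (diff(range(df$concentration)) <= 0)
    stop("degenerate design: zero concentration span")
  if (!is.numeric(eta) || eta == 0) stop("eta must be nonzero")
  w <- if ("sd" %in% names(df) && all(df$sd > 0)) 1 / df$sd^2 else NULL
  fit <- stats::lm(thickness ~ concentration, data = df, weights = w)
  s <- stats::coef(fit)["concentration"]
  ## noiseless series give an exact fit; the zero-variance warning from the
  ## interval computation is expected there
  ci_s <- suppressWarnings(stats::confint(fit, "concentration", level = level))
  n0 <- unname(s / eta)
  ci <- sort(as.numeric(ci_s) / eta)
  structure(list(n0 = n0, ci = ci, level = level, slope = unname(s),
                 eta = eta, h = h, lm = fit, n = nrow(df)),
            class = "n0_fit")
}

#' @export
coef.n0_fit <- function(object, ...) c(n0 = object$n0)

#' @export
confint.n0_fit <- function(object, parm, level, ...) {
  ci <- matrix(object$ci, nrow = 1,
               dimnames = list("n0", paste0(
                 format(100 * c((1 - object$level) / 2,
                                1 - (1 - object$level) / 2)), " %")))
  ci
}

#' @export
print.n0_fit <- function(x, ...) {
  cat(sprintf(
    "Boundary director fit: n0 = %.4f  [%.4f, %.4f] (%d%% CI, %d points)\n",
    x$n0, x$ci[1], x$ci[2], round(100 * x$level), x$n))
  cat(sprintf("  slope d<d>/dC = %.4f nm^3, eta = %.3f nm^3\n", x$slope, x$eta))
  invisible(x)
}

#' @export
summary.n0_fit <- function(object, ...) {
  cat("Inverse fit of the boundary director from <d>(C)\n")
  print(object)
  cat(sprintf("  fitted intercept 2h = %.4f nm (expected %.4f nm)\n",
              stats::coef(object$lm)[1], 2 * object$h))
  cat("\nUnderlying weighted linear fit:\n")
  print(summary(object$lm))
  invisible(object)
}

#' @export
residuals.n0_fit <- function(object, ...) stats::residuals(object$lm)

#' Geometric estimate of the boundary-director magnitude
#'
#' For an alpha-helix of radius `r_p` half-embedded at the level of the
#' polar heads of a monolayer of hydrophobic thickness `h`, the director of
#' the adjacent lipid connects the displaced head to the chain ends,
#' giving the estimate `|n0| = r_p / sqrt(r_p^2 + h^2)`. The sign is
#' applied by the caller (negative for the beneath-peptide orientation).
#'
#' @param r_p helix radius, nm (>= 0).
#' @param h monolayer hydrophobic thickness, nm (> 0).
#' @return the magnitude `|n0|` (dimensionless).
#' @examples
#' estimate_boundary_director(0.65, 1.45)   # ~ 0.409
#' @export
estimate_boundary_director <- function(r_p, h) {
  if (!is.numeric(r_p) || r_p < 0) stop("r_p must be non-negative")
  if (!is.numeric(h) || h <= 0) stop("h must be positive")
  r_p / sqrt(r_p^2 + h^2)
}
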
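#' Monolayer elastic parameter set
#'
#' Bundles the elastic moduli of one lipid monolayer in internal units
#' (`kBT`, nm): splay modulus `B` \[kBT\], tilt modulus `Kt` \[kBT/nm^2\],
#' lateral compression modulus `Ka` \[kBT/nm^2\], Gaussian splay modulus
#' `KG` \[kBT\], twist modulus `Krot` \[kBT\], monolayer spontaneous
#' curvature `J0` \[1/nm\], lateral tension `sigma` \[kBT/nm^2\] and the
#' monolayer hydrophobic thickness `h` \[nm\] (distance from the monolayer
#' interface to the neutral surface).
#'
#' @param B splay (bending) modulus, kBT. Must be > 0.
#' @param Kt tilt modulus, kBT/nm^2. Must be > 0.
#' @param Ka lateral compression modulus, kBT/nm^2. Must be > 0.
#' @param KG Gaussian splay modulus, kBT. Default `-B/2`.
#' @param Krot twist modulus, kBT. Must be >= 0. Default `B/2`.
#' @param J0 monolayer spontaneous curvature, 1/nm.
#' @param sigma lateral tension, kBT/nm^2. Must be >= 0.
#' @param h monolayer hydrophobic thickness, nm. Must be > 0.
#' @return object of class `monolayer_params`.
#' @seealso [preset_parameters()] for the packaged lipid parameter sets.
#' @export
monolayer_params <- function(B, Kt, Ka, KG = -B / 2, Krot = B / 2,
                             J0 = 0, sigma = 0, h) {
  p <- list(B = B, Kt = Kt, Ka = Ka, KG = KG, Krot = Krot,
            J0 = J0, sigma = sigma, h = h)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    stop("all monolayer parameters must be finite scalars")
  if (B <= 0) stop("splay modulus B must be positive")
  if (Kt <= 0) stop("tilt modulus Kt must be positive")
  if (Ka <= 0) stop("compression modulus Ka must be positive")
  if (Krot < 0) stop("twist modulus Krot must be non-negative")
  if (sigma < 0) stop("lateral tension sigma must be non-negative")
  if (h <= 0) stop("monolayer thickness h must be positive")
  structure(p, class = "monolayer_params")
}

#' @export
print.monolayer_params <- function(x, ...) {
  cat("Monolayer elastic parameters (kBT, nm units):\n")
  cat(sprintf("  B    = %7.3f kBT       Kt   = %7.3f kBT/nm^2\n", x$B, x$Kt))
  cat(sprintf("  Ka   = %7.3f kBT/nm^2  KG   = %7.3f kBT\n", x$Ka, x$KG))
  cat(sprintf("  Krot = %7.3f kBT       J0   = %7.3f 1/nm\n", x$Krot, x$J0))
  cat(sprintf("  sigma= %7.4f kBT/nm^2  h    = %7.3f nm\n", x$sigma, x$h))
  invisible(x)
}

#' Bilayer system description
#'
#' Pairs the parameter sets of the two monolayers. For a pure (one-lipid)
#' membrane the two monolayers are identical, which is the only case the
#' solvers accept for the bulk membrane; an inclusion lipid patch is
#' described separately by [lipid_inclusion_spec()] and occupies the upper
#' monolayer.
#'
#' @param upper `monolayer_params` of the upper monolayer.
#' @param lower `monolayer_params` of the lower monolayer. Default: same as
#'   `upper`.
#' @return object of class `bilayer_system`.
#' @export
bilayer_system <- function(upper, lower = upper) {
  stopifnot(inherits(upper, "monolayer_params"),
            inherits(lower, "monolayer_params"))
  structure(list(upper = upper, lower = lower), class = "bilayer_system")
}

#' @export
print.bilayer_system <- function(x, ...) {
  sym <- isTRUE(all.equal(unclass(x$upper), unclass(x$lower)))
  cat(sprintf("Bilayer system (%s)\n",
              if (sym) "symmetric" else "asymmetric"))
  cat("Upper monolayer:\n"); print(x$upper)
  if (!sym) { cat("Lower monolayer:\n"); print(x$lower) }
  invisible(x)
}

.is_symmetric_bilayer <- function(system, tol = 1e-12) {
  u <- unlist(unclass(system$upper)); l <- unlist(unclass(system$lower))
  all(abs(u - l) <= tol * pmax(1, abs(u)))
}

#' Packaged lipid parameter presets
#'
#' Returns the elastic parameter sets shipped with the package, converted to
#' internal units (kBT, nm) at the requested temperature. Available presets:
#' \describe{
#'   \item{`"DOPC"`}{dioleoylphosphatidylcholine bulk monolayer.}
#'   \item{`"POPC_POPS_3to1"`}{POPC:POPS 3:1 mixture bulk monolayer.}
#'   \item{`"inclusion_common"`}{a "common" lipid patch (DOPC-like tilt,
#'     compression, tension, twist and Gaussian moduli); its splay modulus,
#'     spontaneous curvature and thickness are meant to be varied by the
#'     caller. Geometry default: patch radius 0.5 nm.}
#'   \item{`"inclusion_thin"`}{a "thin" photoswitchable-like lipid patch with
#'     monolayer thickness 0.7 nm; geometry default: patch radius 0.662 nm.}
#' }
#' Geometry defaults (peptide length/radius or patch radius) are attached as
#' the `"geometry"` attribute.
#'
#' @param name preset name (see above).
#' @param temperature_K temperature used to convert moduli quoted in mN/m.
#' @return `monolayer_params` with a `"geometry"` attribute.
#' @examples
#' preset_parameters("DOPC")$J0     # -0.091 1/nm
#' attr(preset_parameters("inclusion_thin"), "geometry")$r_lip
#' @export
preset_parameters <- function(name, temperature_K = 300) {
  path <- system.file("extdata", "presets.yaml", package = "memdeform",
                      mustWork = TRUE)
  presets <- yaml::read_yaml(path)
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s' (available: %s)", name,
                 paste(names(presets), collapse = ", ")))
  entry <- presets[[name]]
  vals <- lapply(entry$params, function(e)
    convert_to_internal(e$value, e$unit, temperature_K))
  p <- monolayer_params(B = vals$B, Kt = vals$Kt, Ka = vals$Ka, KG = vals$KG,
                        Krot = vals$Krot, J0 = vals$J0, sigma = vals$sigma,
                        h = vals$h)
  attr(p, "geometry") <- entry$geometry
  attr(p, "preset") <- name
  p
}
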
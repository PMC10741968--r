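#' Amphipathic peptide specification
#'
#' An alpha-helical amphipathic peptide lying in the upper monolayer, with a
#' stadium-shaped footprint of overall length `l_p` and width `2*r_p`
#' (a rectangle of length `l_p - 2*r_p` capped by two semicircles of radius
#' `r_p`). The peptide imposes a director boundary condition on its outline:
#' the outward-normal projection of the upper-monolayer director equals `n0`
#' and the tangential projection vanishes. Negative `n0` means the director
#' points beneath the peptide.
#'
#' @param l_p peptide length, nm. Must satisfy `l_p >= 2*r_p`.
#' @param r_p helix radius, nm.
#' @param n0 signed normal projection of the boundary director, `|n0| < 1`.
#' @return object of class `amphipathic_spec`.
#' @export
amphipathic_spec <- function(l_p, r_p, n0) {
  stopifnot(is.numeric(l_p), is.numeric(r_p), is.numeric(n0),
            length(l_p) == 1, length(r_p) == 1, length(n0) == 1)
  if (r_p <= 0) stop("helix radius r_p must be positive")
  if (l_p < 2 * r_p) stop("peptide length l_p must be at least 2*r_p")
  if (abs(n0) >= 1) stop("|n0| must be < 1 (in-plane director projection)")
  structure(list(l_p = l_p, r_p = r_p, n0 = n0), class = "amphipathic_spec")
}

#' Transmembrane peptide specification
#'
#' A rigid cylindrical transmembrane peptide of radius `r_p` whose boundary
#' outlines on the two neutral surfaces are identical circles. It fixes the
#' radial director projection on each monolayer (`n0u`, `n0l`) and the local
#' bilayer thickness `H_u - H_l = h_p` at its boundary; the vertical
#' position of the rigid peptide is left free. Positive `n0` corresponds to
#' a barrel-like shape (directors splayed outward), negative to
#' hourglass-like.
#'
#' @param r_p peptide radius, nm.
#' @param h_p hydrophobic (transmembrane) length, nm.
#' @param n0u,n0l boundary director projections at the upper and lower
#'   neutral surface; a symmetric peptide has `n0u == n0l`.
#' @return object of class `transmembrane_spec`.
#' @export
transmembrane_spec <- function(r_p, h_p, n0u, n0l = n0u) {
  stopifnot(is.numeric(r_p), is.numeric(h_p), is.numeric(n0u), is.numeric(n0l))
  if (r_p <= 0) stop("peptide radius r_p must be positive")
  if (h_p <= 0) stop("transmembrane length h_p must be positive")
  if (max(abs(c(n0u, n0l))) >= 1) stop("|n0| must be < 1")
  structure(list(r_p = r_p, h_p = h_p, n0u = n0u, n0l = n0l),
            class = "transmembrane_spec")
}

.is_symmetric_tm <- function(spec) isTRUE(all.equal(spec$n0u, spec$n0l))

#' Lipid inclusion (monolayer patch) specification
#'
#' A circular patch of a different lipid of radius `r_lip` occupying the
#' upper monolayer. Unlike rigid peptides it imposes no essential boundary
#' conditions, only continuity of the neutral surface and director; its own
#' elastic parameters (`params_inc`, holding in particular the patch splay
#' modulus and spontaneous curvature) and monolayer thickness `h_inc` apply
#' inside the patch.
#'
#' @param r_lip patch radius, nm.
#' @param h_inc patch monolayer hydrophobic thickness, nm.
#' @param params_inc `monolayer_params` of the patch lipid. Its `h` entry is
#'   overridden by `h_inc`.
#' @return object of class `lipid_inclusion_spec`.
#' @export
lipid_inclusion_spec <- function(r_lip, h_inc, params_inc) {
  stopifnot(inherits(params_inc, "monolayer_params"))
  if (!is.numeric(r_lip) || r_lip <= 0) stop("patch radius r_lip must be positive")
  if (!is.numeric(h_inc) || h_inc <= 0) stop("patch thickness h_inc must be positive")
  params_inc$h <- h_inc
  structure(list(r_lip = r_lip, h_inc = h_inc, params_inc = params_inc),
            class = "lipid_inclusion_spec")
}

#' @export
print.amphipathic_spec <- function(x, ...) {
  cat(sprintf("Amphipathic peptide: l_p = %.3g nm, r_p = %.3g nm, n0 = %.3g\n",
              x$l_p, x$r_p, x$n0))
  invisible(x)
}

#' @export
print.transmembrane_spec <- function(x, ...) {
  cat(sprintf(
    "Transmembrane peptide: r_p = %.3g nm, h_p = %.3g nm, n0u = %.3g, n0l = %.3g%s\n",
    x$r_p, x$h_p, x$n0u, x$n0l,
    if (.is_symmetric_tm(x)) " (symmetric)" else ""))
  invisible(x)
}

#' @export
print.lipid_inclusion_spec <- function(x, ...) {
  cat(sprintf(
    "Lipid inclusion patch: r_lip = %.3g nm, h_inc = %.3g nm, B_inc = %.3g kBT, J0inc = %.3g 1/nm\n",
    x$r_lip, x$h_inc, x$params_inc$B, x$params_inc$J0))
  invisible(x)
}
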
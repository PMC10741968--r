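#' Pointwise elastic energy density of the deformed bilayer
#'
#' Evaluates the surface density of the bilayer elastic energy at one point
#' of the membrane plane, given the local values of the five deformation
#' fields and their first in-plane derivatives. The density is the sum over
#' both monolayers of splay (with the spontaneous-curvature reference
#' subtracted so the flat unperturbed state has zero density), tilt, lateral
#' tension, lateral compression (with the volumetric-incompressibility
#' substitution), Gaussian splay and twist contributions. Directors are
#' linearized: only their in-plane components enter.
#'
#' @param state a list with entries
#'   `Hu`, `Hl`, `M` (heights, nm), `nu`, `nl` (in-plane director components,
#'   length-2 numeric), `dHu`, `dHl` (in-plane gradients, length-2), and
#'   `dnu`, `dnl` (2x2 Jacobians, `dn[i, j] = d n_i / d x_j`).
#' @param system a [bilayer_system()].
#' @param patch optional [lipid_inclusion_spec()]; if supplied the point is
#'   taken to lie inside the patch, so the upper monolayer uses the patch
#'   parameters and reference thickness.
#' @param warn_negative warn if the density is negative. A locally negative
#'   density is possible when the local splay is close to a nonzero
#'   spontaneous curvature; a warning flags it rather than letting it pass
#'   silently.
#' @return energy density in kBT/nm^2.
#' @export
energy_density <- function(state, system, patch = NULL, warn_negative = TRUE) {
  need <- c("Hu", "Hl", "M", "nu", "nl", "dHu", "dHl", "dnu", "dnl")
  if (!all(need %in% names(state)))
    stop("state must contain ", paste(need, collapse = ", "))
  pu <- system$upper
  pl <- system$lower
  href_u <- pu$h
  if (!is.null(patch)) {
    pu <- patch$params_inc
    href_u <- patch$h_inc
  }

  mono <- function(p, href, h_bulk, n, dn, H, dH, M, upper) {
    divn <- dn[1, 1] + dn[2, 2]
    splay <- p$B / 2 * (divn + p$J0)^2 - p$B / 2 * p$J0^2
    tilt_vec <- if (upper) n - dH else n + dH
    tilt <- p$Kt / 2 * sum(tilt_vec^2)
    tension <- p$sigma / 2 * sum(dH^2)
    comp_arg <- if (upper) href - href^2 / 2 * divn + M - H
                else       href - href^2 / 2 * divn - M + H
    comp <- p$Ka / (2 * href^2) * comp_arg^2
    gauss <- p$KG * (dn[1, 1] * dn[2, 2] - dn[1, 2] * dn[2, 1])
    twist <- p$Krot / 2 * (dn[2, 1] - dn[1, 2])^2
    splay + tilt + tension + comp + gauss + twist
  }

  w <- mono(pu, href_u, system$upper$h, state$nu, state$dnu,
            state$Hu, state$dHu, state$M, upper = TRUE) +
       mono(pl, pl$h, system$lower$h, state$nl, state$dnl,
            state$Hl, state$dHl, state$M, upper = FALSE)
  if (warn_negative && w < 0)
    warning(sprintf(
      "negative elastic energy density (%.3g kBT/nm^2): local splay near the spontaneous curvature",
      w))
  w
}

#' Ground-state field values of the unperturbed bilayer
#'
#' Convenience constructor of the `state` list accepted by
#' [energy_density()], filled with the far-field ground-state values
#' (`Hu = h`, `Hl = -h`, `M = 0`, zero in-plane directors and derivatives).
#'
#' @param system a [bilayer_system()].
#' @return a state list.
#' @export
ground_state <- function(system) {
  list(Hu = system$upper$h, Hl = -system$lower$h, M = 0,
       nu = c(0, 0), nl = c(0, 0),
       dHu = c(0, 0), dHl = c(0, 0),
       dnu = matrix(0, 2, 2), dnl = matrix(0, 2, 2))
}
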
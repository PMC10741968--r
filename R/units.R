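#' @keywords internal
.kB_J <- 1.380649e-23

#' Convert a physical quantity to internal units (kBT, nm)
#'
#' The package works internally in thermal energy units (`kBT`) and nanometres.
#' Elastic moduli quoted in mN/m (i.e. mJ/m^2) are converted to `kBT/nm^2`
#' using the Boltzmann constant at a given absolute temperature; quantities
#' already expressed in `kBT`, `nm` or `1/nm` pass through unchanged.
#'
#' @param value numeric, finite. The quantity to convert.
#' @param unit one of `"mN/m"`, `"kBT"`, `"1/nm"`, `"nm"`.
#' @param temperature_K absolute temperature in kelvin used for the
#'   `mN/m` to `kBT/nm^2` bridge. Default 300 K.
#' @return numeric value in internal units.
#' @examples
#' convert_to_internal(40, "mN/m")   # ~ 9.66 kBT/nm^2 at 300 K
#' convert_to_internal(10, "kBT")    # 10
#' @export
convert_to_internal <- function(value, unit, temperature_K = 300) {
  if (!is.numeric(value) || any(!is.finite(value)))
    stop("'value' must be finite numeric")
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    stop("'temperature_K' must be a positive number")
  switch(unit,
    "mN/m" = value * 1e-21 / (.kB_J * temperature_K),
    "kBT"  = value,
    "1/nm" = value,
    "nm"   = value,
    stop(sprintf("unsupported unit '%s' (use one of mN/m, kBT, 1/nm, nm)", unit))
  )
}

## conversion factor actually used, for logging
.mNm_to_kBT_nm2 <- function(temperature_K = 300) 1e-21 / (.kB_J * temperature_K)
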
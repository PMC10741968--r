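## Plain-text input/output: parameter files with unit tags, result
## summaries as JSON, profiles and maps as CSV.

#' Read / write monolayer parameters with explicit unit tags
#'
#' Parameter files are YAML mappings with one entry per parameter, each an
#' explicit `{value, unit}` pair (units as in [convert_to_internal()]).
#' Reading converts everything to internal units (kBT, nm).
#'
#' @param path file path.
#' @param temperature_K temperature for the mN/m conversion.
#' @return `read_monolayer_params`: a [monolayer_params()] object.
#' @export
read_monolayer_params <- function(path, temperature_K = 300) {
  y <- yaml::read_yaml(path)
  entries <- if (!is.null(y$params)) y$params else y
  vals <- lapply(entries, function(e)
    convert_to_internal(e$value, e$unit, temperature_K))
  monolayer_params(B = vals$B, Kt = vals$Kt, Ka = vals$Ka, KG = vals$KG,
                   Krot = vals$Krot, J0 = vals$J0, sigma = vals$sigma,
                   h = vals$h)
}

#' @rdname read_monolayer_params
#' @param params a [monolayer_params()] object (internal units).
#' @export
write_monolayer_params <- function(params, path) {
  units <- c(B = "kBT", Kt = "kBT", Ka = "kBT", KG = "kBT", Krot = "kBT",
             J0 = "1/nm", sigma = "kBT", h = "nm")
  ## kBT/nm^2 quantities are already internal; tag them kBT for round-trip
  out <- lapply(names(units), function(nm)
    list(value = params[[nm]], unit = unname(units[[nm]])))
  names(out) <- names(units)
  yaml::write_yaml(list(params = out), path, precision = 15)
  invisible(path)
}

#' Write a solved deformation to disk
#'
#' Writes the result summary (energy, thickness disturbance, solver
#' metadata) as JSON and the profile (radial table or planar nodal table)
#' as CSV.
#'
#' @param result a `deformation` object.
#' @param dir output directory (created if needed).
#' @param name base file name.
#' @return invisibly, the paths written.
#' @export
write_deformation <- function(result, dir, name = result$kind) {
  stopifnot(inherits(result, "deformation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(dir, paste0(name, "_summary.json"))
  profile_path <- file.path(dir, paste0(name, "_profile.csv"))
  jsonlite::write_json(
    list(kind = result$kind, W_kBT = result$W, Delta_nm3 = result$Delta,
         solver = result$solver),
    summary_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$profile, profile_path, row.names = FALSE)
  invisible(c(summary = summary_path, profile = profile_path))
}
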
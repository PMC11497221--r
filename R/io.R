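#' Write / read a spectrum as CSV plus JSON sidecar
#'
#' The spectrum file format used throughout: a two-column CSV (`x`, `y`)
#' next to a JSON sidecar (same path with `.json` extension) holding
#' `{modality, timestamp_min, units}`.
#'
#' @param spec a [spectrum()].
#' @param path CSV path (the sidecar path is derived from it).
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum`
#'   returns a [spectrum()].
#' @export
write_spectrum <- function(spec, path) {
  if (!inherits(spec, "spectrum")) stop("'spec' must be a spectrum")
  utils::write.csv(data.frame(x = spec$x, y = spec$y), path,
                   row.names = FALSE)
  units <- if (spec$modality == "nmr") list(x = "ppm", y = "intensity")
           else list(x = "nm", y = "AU")
  jsonlite::write_json(list(modality = spec$modality,
                            timestamp_min = spec$timestamp,
                            units = units),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    sub("\\.csv$", ".json", path, ignore.case = TRUE)
  else paste0(path, ".json")
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("spectrum CSV must have columns 'x' and 'y'")
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  spectrum(df$x, df$y, modality = meta$modality,
           timestamp = meta$timestamp_min)
}

#' Write / read a reaction network as YAML
#'
#' @param network a [reaction_network()].
#' @param path YAML file path.
#' @return `write_network_yaml` returns `path` invisibly;
#'   `read_network_yaml` returns a [reaction_network()].
#' @export
write_network_yaml <- function(network, path) {
  if (!inherits(network, "reaction_network"))
    stop("'network' must be a reaction_network")
  doc <- list(
    species = as.list(network$species),
    reactions = lapply(network$reactions, function(r) {
      out <- list(reactants = as.list(r$reactants),
                  products = as.list(r$products), k = r$k)
      if (!is.null(r$orders)) out$orders <- as.list(r$orders)
      out
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_network_yaml
#' @export
read_network_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  rxns <- lapply(doc$reactions, function(r) {
    reaction(unlist(r$reactants), unlist(r$products), r$k,
             orders = if (!is.null(r$orders)) unlist(r$orders))
  })
  reaction_network(rxns, species = unlist(doc$species))
}

#' Write / read a spectral signature as YAML
#'
#' @param signature a [spectral_signature()].
#' @param path YAML file path.
#' @export
write_signature_yaml <- function(signature, path) {
  if (!inherits(signature, "spectral_signature"))
    stop("'signature' must be a spectral_signature")
  doc <- list(modality = signature$modality,
              peaks = lapply(signature$peaks, function(p)
                lapply(seq_len(nrow(p)), function(i)
                  list(center = p$center[i], width = p$width[i],
                       response = p$response[i]))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_signature_yaml
#' @export
read_signature_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  peaks <- lapply(doc$peaks, function(rows) {
    peak_table(vapply(rows, `[[`, numeric(1), "center"),
               vapply(rows, `[[`, numeric(1), "width"),
               vapply(rows, `[[`, numeric(1), "response"))
  })
  spectral_signature(peaks, doc$modality)
}

#' Write / read a conversion series as CSV
#'
#' Two columns: `time_min`, `conversion`.
#'
#' @param series a `conversion_series` data frame.
#' @param path CSV path.
#' @export
write_conversion_csv <- function(series, path) {
  if (!all(c("time_min", "conversion") %in% names(series)))
    stop("'series' must have columns time_min and conversion")
  utils::write.csv(series[c("time_min", "conversion")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_conversion_csv
#' @export
read_conversion_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "conversion") %in% names(df)))
    stop("conversion CSV must have columns time_min and conversion")
  structure(df[c("time_min", "conversion")],
            class = c("conversion_series", "data.frame"))
}

#' Hammett substituent constants
#'
#' `hansch_sigma()` returns the package's built-in table of standard
#' Hansch sigma_para / sigma_meta substituent constants (dimensionless;
#' H = 0 by definition). `read_sigma_table()` loads a user-editable YAML
#' table with the same validation: a value for `H` equal to 0 must be
#' present and all values must lie in \[-1, 1.5\]. An editable copy of
#' the built-in table ships at
#' `system.file("extdata", "hansch_sigma.yaml", package = "rxnkinetics")`.
#'
#' @return a named numeric vector of class `sigma_table`.
#' @examples
#' hansch_sigma()[c("H", "p-OMe", "p-Me")]
#' @export
hansch_sigma <- function() {
  as_sigma_table(c(
    "H" = 0, "p-OMe" = -0.27, "p-Me" = -0.17, "m-Me" = -0.07,
    "p-F" = 0.06, "m-OMe" = 0.12, "p-Cl" = 0.23, "p-Br" = 0.23,
    "m-Cl" = 0.37, "p-CF3" = 0.54, "m-NO2" = 0.71, "p-NO2" = 0.78))
}

as_sigma_table <- function(x) {
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("a sigma table must be a named numeric vector")
  if (!"H" %in% names(x) || x[["H"]] != 0)
    stop("a sigma table must contain the reference 'H' with sigma = 0")
  if (any(x < -1) || any(x > 1.5))
    stop("sigma values must lie in [-1, 1.5]")
  structure(x, class = "sigma_table")
}

#' @rdname hansch_sigma
#' @param path YAML file mapping substituent labels to sigma values.
#' @export
read_sigma_table <- function(path) {
  doc <- yaml::read_yaml(path)
  as_sigma_table(unlist(doc))
}

#' @rdname hansch_sigma
#' @param sigmas a `sigma_table` (or named numeric vector) to write.
#' @export
write_sigma_table <- function(sigmas, path) {
  sigmas <- as_sigma_table(sigmas)
  yaml::write_yaml(as.list(unclass(sigmas)), path)
  invisible(path)
}
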
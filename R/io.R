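# CSV matrix + JSON sidecar interchange. Doubles are written with 17
# significant digits so a write/read round trip is bit exact.

write_num_csv <- function(m, path) {
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(txt, path)
}

read_num_csv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

#' Persist channel data
#'
#' Writes `<prefix>.csv` (the M x T signal matrix) and `<prefix>.json`
#' (sampling step, pulse alignment, antenna positions, provenance). The
#' round trip through [read_channels()] is bit exact.
#'
#' @param channels a `channel_data`.
#' @param prefix file path without extension.
#' @return `prefix`, invisibly.
#' @export
write_channels <- function(channels, prefix) {
  stopifnot(inherits(channels, "channel_data"))
  write_num_csv(channels$signals, paste0(prefix, ".csv"))
  meta <- list(dt = sprintf("%.17g", channels$dt),
               t0 = sprintf("%.17g", channels$t0),
               antennas = channels$antennas,
               provenance = channels$provenance)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(prefix)
}

#' @rdname write_channels
#' @export
read_channels <- function(prefix) {
  sig <- read_num_csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(list(signals = sig, dt = as.numeric(meta$dt),
                 t0 = as.numeric(meta$t0),
                 antennas = as.data.frame(meta$antennas),
                 provenance = meta$provenance),
            class = "channel_data")
}

#' Persist an energy map
#'
#' Writes `<prefix>.csv` (the pixel grid, rows = depth) and `<prefix>.json`
#' (pixel coordinates, pitch, beamformer, provenance).
#'
#' @param map an `energy_map`.
#' @param prefix file path without extension.
#' @return `prefix`, invisibly.
#' @export
write_energy_map <- function(map, prefix) {
  stopifnot(inherits(map, "energy_map"))
  write_num_csv(map$energy, paste0(prefix, ".csv"))
  meta <- list(depth_first = map$depth[1],
               lateral_first = map$lateral[1],
               pitch = map$pitch, method = map$method,
               provenance = map$provenance)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(prefix)
}

#' @rdname write_energy_map
#' @export
read_energy_map <- function(prefix) {
  e <- read_num_csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(list(energy = e,
                 depth = meta$depth_first + (seq_len(nrow(e)) - 1) * meta$pitch,
                 lateral = meta$lateral_first + (seq_len(ncol(e)) - 1) * meta$pitch,
                 pitch = meta$pitch, method = meta$method,
                 provenance = meta$provenance),
            class = "energy_map")
}

#' Read or write a phantom configuration as YAML
#'
#' @param config a [phantom_config()].
#' @param path file path.
#' @return `write_phantom_config` returns `path` invisibly;
#'   `read_phantom_config` returns a validated `phantom_config`.
#' @export
write_phantom_config <- function(config, path) {
  stopifnot(inherits(config, "phantom_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$alns <- lapply(raw$alns, function(a)
    aln(a$depth, a$offset, a$long_axis, a$orientation, a$status))
  do.call(phantom_config, raw[setdiff(names(raw), character(0))])
}
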
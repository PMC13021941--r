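#' Read and write track tables
#'
#' Track CSVs use comma separation, UTF-8, a mandatory header row, µm
#' coordinates (origin at the top-left pixel center) and 0-based frames:
#' columns `track_id`, `frame`, `t_s`, `x_um`, `y_um`, `intensity`
#' (ground-truth columns such as `state` are preserved when present).
#'
#' @param tracks Track tibble.
#' @param path File path.
#' @return `read_tracks_csv()` returns a tibble; the writers return the
#'   path invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  req <- c("track_id", "frame", "t_s", "x_um", "y_um", "intensity")
  stopifnot(all(req %in% names(tracks)))
  readr::write_csv(tracks, path)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read and write chronoamperometry traces
#'
#' Trace CSVs carry `t_s`, `current_nA`, `light_on`.
#'
#' @param trace Trace tibble.
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(all(c("t_s", "current_nA", "light_on") %in% names(trace)))
  readr::write_csv(trace, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  out$light_on <- as.logical(out$light_on)
  class(out) <- c("current_trace", class(out))
  out
}

#' Read and write images as TIFF
#'
#' 32-bit float TIFF round trip for rendered images and super-resolution
#' reconstructions; label masks round-trip losslessly for small integer
#' labels.
#'
#' @param image Numeric matrix.
#' @param path File path.
#' @param scale Values are stored as `image / scale` (the tiff writer
#'   stores floats; intensities are rescaled into a unit-friendly range
#'   and restored on read via the stored sample format).
#' @export
write_image_tiff <- function(image, path, scale = NULL) {
  if (is.null(scale)) scale <- max(abs(image), 1)
  tiff::writeTIFF(image / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  # store the scale in a sidecar so the round trip is exact
  jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    img <- img * meta$scale
  }
  img
}

#' Write an analysis result as JSON
#'
#' Serializes fit summaries (via their `glance()` when available) with a
#' schema version field.
#'
#' @param x A fit object or list.
#' @param path File path.
#' @export
write_result_json <- function(x, path) {
  payload <- if (inherits(x, c("sigmoid_fit", "diffusion_fit",
                               "kinetics_result"))) {
    as.list(glance(x))
  } else {
    x
  }
  jsonlite::write_json(c(list(schema_version = "1.0"), payload), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
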
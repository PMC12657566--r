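#' Write an optical recording to a plain-text JSON file
#'
#' A diffable text interchange format mirroring the structure of the
#' community standard for continuous-wave NIRS acquisitions: intensity data
#' per channel and wavelength, wavelengths, sampling rate, optode geometry,
#' channel table, and annotations.
#'
#' @param rec an `optical_recording`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path) {
  d <- dim(rec$intensities)
  payload <- list(
    format = "nirsconnect-recording",
    version = 1L,
    stage = rec$stage,
    sampling_rate = rec$sampling_rate,
    wavelengths = rec$wavelengths,
    optodes = rec$montage$optodes,
    channels = rec$montage$channels,
    head_radius = rec$montage$head_radius,
    annotations = rec$annotations,
    bad_channels = rec$bad_channels,
    n_samples = d[1],
    intensities = setNames(lapply(seq_len(d[3]), function(wl) {
      m <- rec$intensities[, , wl, drop = TRUE]
      dim(m) <- c(d[1], d[2])
      m
    }), paste0("wavelength_", rec$wavelengths))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' Read an optical recording written by [write_recording()]
#'
#' @param path file path
#' @return an `optical_recording`
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_format(paste0("no such file: ", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "nirsconnect-recording"))
    stop_format("not a nirsconnect recording (missing/wrong 'format' field)")
  for (field in c("optodes", "channels", "intensities", "sampling_rate", "wavelengths")) {
    if (is.null(x[[field]]))
      stop_format(paste0("malformed recording: missing field '", field, "'"))
  }
  n <- x$n_samples
  C <- nrow(as.data.frame(x$channels))
  ints <- array(0, dim = c(n, C, length(x$wavelengths)))
  for (wl in seq_along(x$intensities)) ints[, , wl] <- as.matrix(x$intensities[[wl]])
  montage <- structure(list(
    optodes = as_tibble(x$optodes),
    channels = as_tibble(x$channels),
    head_radius = x$head_radius
  ), class = "nirs_montage")
  dimnames(ints) <- list(NULL, montage$channels$channel, as.character(x$wavelengths))
  ann <- as_tibble(x$annotations)
  if (nrow(ann) == 0) ann <- empty_annotations()
  new_optical_recording(
    ints, x$wavelengths, x$sampling_rate, montage,
    annotations = ann, stage = x$stage %||% "raw",
    bad_channels = unlist(x$bad_channels) %||% character()
  )
}

#' Read/write annotations as 3-column TSV (onset, duration, label)
#' @param path TSV path
#' @return tibble(onset, duration, label)
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    onset = readr::col_double(), duration = readr::col_double(),
    label = readr::col_character()
  ))
  ann
}

#' @rdname read_annotations
#' @param annotations tibble(onset, duration, label)
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path)
  invisible(path)
}

#' Read/write a long-format degree table as headered CSV
#'
#' Columns: participant, group, session, channel, degree.
#' @param path CSV path
#' @return tibble with group/session as factors
#' @export
read_degree_table <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_character(), group = readr::col_character(),
    session = readr::col_character(), channel = readr::col_character(),
    degree = readr::col_integer()
  ))
  validate_degree_table(d)
}

#' @rdname read_degree_table
#' @param data a degree table
#' @export
write_degree_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Write a connectivity matrix as square CSV with channel-name headers
#' @param conn a `connectivity_result`
#' @param path CSV path
#' @param which `"weighted"` or `"binary"`
#' @export
write_connectivity_matrix <- function(conn, path, which = c("weighted", "binary")) {
  which <- match.arg(which)
  m <- conn[[which]]
  if (is.null(m)) stop_param(paste0("connectivity result has no ", which, " matrix"))
  d <- as.data.frame(m)
  names(d) <- conn$channels
  d <- cbind(channel = conn$channels, d)
  readr::write_csv(as_tibble(d), path)
  invisible(path)
}
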
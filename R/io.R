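#' Write / read a probe layout as JSON
#'
#' Plain JSON with `sources`, `detectors` (arrays of [x, y, z] in mm),
#' `units` and per-probe `arrays` membership; channels are re-enumerated
#' on read so the file stays minimal.
#'
#' @param layout a [probe_layout()].
#' @param path file path.
#' @export
write_probe_layout <- function(layout, path) {
  jsonlite::write_json(
    list(units = "mm",
         sources = unname(layout$sources),
         detectors = unname(layout$detectors),
         source_arrays = layout$source_arrays,
         detector_arrays = layout$detector_arrays,
         short_sep = layout$short_sep, long_sep = layout$long_sep,
         tol = layout$tol),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_probe_layout
#' @export
read_probe_layout <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("sources", "detectors")) {
    if (is.null(j[[f]])) stop("layout JSON missing field `", f, "`")
  }
  probe_layout(list(
    sources = as.matrix(j$sources),
    detectors = as.matrix(j$detectors),
    source_arrays = j$source_arrays, detector_arrays = j$detector_arrays,
    short_sep = j$short_sep %||% 13,
    long_sep = j$long_sep %||% (sqrt(5) * 13),
    tol = j$tol %||% 1))
}

#' Write / read channel time series as CSV
#'
#' One CSV per wavelength (`<prefix>_wl<nm>.csv`, header row = channel
#' ids, one column per channel, '.' decimal, full double precision) plus
#' a JSON sidecar (`<prefix>_meta.json`) carrying the sampling rate,
#' wavelengths, units and channel metadata. The round trip preserves
#' samples to double precision.
#'
#' @param cts a `channel_ts`.
#' @param prefix path prefix for the files.
#' @export
write_channels <- function(cts, prefix) {
  stopifnot(inherits(cts, "channel_ts"))
  for (w in seq_along(cts$wavelengths)) {
    M <- cts$data[[w]]
    colnames(M) <- paste0("ch", seq_len(ncol(M)))
    utils::write.table(
      format(as.data.frame(M), digits = 17, scientific = TRUE, trim = TRUE),
      sprintf("%s_wl%d.csv", prefix, cts$wavelengths[w]),
      sep = ",", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(fs = cts$fs, wavelengths = cts$wavelengths, units = cts$units,
         channels = cts$channels, bad_channels = cts$bad_channels,
         retained = cts$retained),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(prefix)
}

#' @rdname write_channels
#' @export
read_channels <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(meta_path)) {
    stop("missing sidecar ", meta_path,
         "; expected <prefix>_meta.json plus <prefix>_wl<nm>.csv files")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (length(meta$wavelengths) < 2) {
    warning("fewer than 2 wavelengths; Hb unmixing will not be possible")
  }
  data <- lapply(meta$wavelengths, function(wl) {
    f <- sprintf("%s_wl%d.csv", prefix, wl)
    if (!file.exists(f)) stop("missing data file ", f)
    M <- utils::read.csv(f, check.names = FALSE)
    if (is.null(names(M)) || !all(grepl("^ch", names(M)))) {
      stop("CSV ", f, " lacks the channel-id header row (ch1, ch2, ...)")
    }
    as.matrix(M)
  })
  cts <- channel_timeseries(data, fs = meta$fs,
                            channels = if (!is.null(meta$channels))
                              as.data.frame(meta$channels) else NULL,
                            wavelengths = meta$wavelengths,
                            units = meta$units)
  cts$bad_channels <- meta$bad_channels
  cts$retained <- meta$retained
  cts
}

#' Write / read a connectivity matrix as CSV with ROI names
#'
#' @param C ROI x ROI matrix with dimnames.
#' @param path CSV path; a JSON sidecar with metadata may be added via
#'   `meta`.
#' @param meta optional list written next to the CSV.
#' @export
write_connectivity <- function(C, path, meta = NULL) {
  utils::write.csv(as.data.frame(C), path, row.names = TRUE)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

# resolve a pipeline configuration from YAML or JSON
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml or .json file")
  }
}
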
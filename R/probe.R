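#' Default high-density probe layout configuration
#'
#' Describes square checkerboard optode arrays: sources and detectors
#' alternate on a regular lattice so that first-nearest source-detector
#' pairs sit one pitch apart (13 mm, "short" channels, mostly sensitive to
#' scalp) and second-nearest pairs sit sqrt(5) x pitch apart (about 29 mm,
#' "long" channels, reaching cortex).
#'
#' @param n_arrays number of 4 x 4 arrays (default 4: bilateral frontal and
#'   parietal pads).
#' @param pitch lattice pitch in mm (default 13).
#' @param shape per-array grid shape, rows x columns (default `c(4, 4)`).
#' @param spacing distance between neighbouring array centers in mm.
#' @return a layout configuration list consumed by [probe_layout()].
#' @export
default_layout_config <- function(n_arrays = 4, pitch = 13, shape = c(4, 4),
                                  spacing = 120) {
  centers <- cbind(x = (seq_len(n_arrays) - (n_arrays + 1) / 2) * spacing,
                   y = rep(0, n_arrays))
  arrays <- lapply(seq_len(n_arrays), function(k) {
    list(shape = shape, pitch = pitch,
         center = centers[k, ],
         first = if (k %% 2 == 1) "source" else "detector")
  })
  list(arrays = arrays, short_sep = pitch, long_sep = sqrt(5) * pitch,
       tol = 1)
}

#' Build a probe layout and enumerate measurement channels
#'
#' Accepts either checkerboard array descriptions (`config$arrays`) or
#' explicit optode coordinates (`config$sources`, `config$detectors`,
#' n x 3 matrices in mm with z = 0 on the scalp surface). All
#' source-detector pairs whose separation falls within `tol` (default
#' 1 mm) of the short or long nominal separation become channels; other
#' pairs are not measured.
#'
#' @param config layout configuration, see [default_layout_config()].
#' @return object of class `probe_layout`: list with `sources`,
#'   `detectors` (n x 3 matrices), `channels` (data frame with `channel`,
#'   `source`, `detector`, `separation`, `class`, `array`) and the nominal
#'   separations used.
#' @examples
#' lay <- probe_layout(default_layout_config(n_arrays = 1))
#' table(lay$channels$class)
#' @export
probe_layout <- function(config) {
  short_sep <- config$short_sep %||% 13
  long_sep <- config$long_sep %||% (sqrt(5) * 13)
  tol <- config$tol %||% 1

  if (!is.null(config$arrays)) {
    src <- det <- NULL
    src_arr <- det_arr <- integer(0)
    for (k in seq_along(config$arrays)) {
      a <- config$arrays[[k]]
      nr <- a$shape[1]; nc <- a$shape[2]
      pitch <- a$pitch %||% 13
      first <- a$first %||% "source"
      for (i in seq_len(nr)) {
        for (j in seq_len(nc)) {
          p <- c(a$center[1] + (j - (nc + 1) / 2) * pitch,
                 a$center[2] + (i - (nr + 1) / 2) * pitch,
                 0)
          is_src <- ((i + j) %% 2 == 0) == (first == "source")
          if (is_src) {
            src <- rbind(src, p); src_arr <- c(src_arr, k)
          } else {
            det <- rbind(det, p); det_arr <- c(det_arr, k)
          }
        }
      }
    }
  } else {
    src <- as.matrix(config$sources)
    det <- as.matrix(config$detectors)
    if (ncol(src) == 2) src <- cbind(src, 0)
    if (ncol(det) == 2) det <- cbind(det, 0)
    src_arr <- config$source_arrays %||% rep(1L, nrow(src))
    det_arr <- config$detector_arrays %||% rep(1L, nrow(det))
  }
  colnames(src) <- colnames(det) <- c("x", "y", "z")
  rownames(src) <- rownames(det) <- NULL

  all_pos <- rbind(src, det)
  if (anyDuplicated(round(all_pos, 6))) {
    stop("duplicate probe coordinates in layout")
  }

  # enumerate all source-detector pairs, classify by separation
  ds <- sqrt(outer(rowSums(src^2), rowSums(det^2), "+") -
               2 * src %*% t(det))
  ch <- NULL
  for (s in seq_len(nrow(src))) {
    for (d in seq_len(nrow(det))) {
      sep <- ds[s, d]
      cls <- NA_character_
      if (abs(sep - short_sep) <= tol) {
        cls <- "short"
      } else if (abs(sep - long_sep) <= tol) {
        cls <- "long"
      }
      if (!is.na(cls)) {
        ch <- rbind(ch, data.frame(
          source = s, detector = d, separation = sep, class = cls,
          array = if (src_arr[s] == det_arr[d]) src_arr[s] else NA_integer_,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(ch)) stop("layout configuration yields no channels")
  ch <- ch[order(ch$class == "long", ch$array, ch$source, ch$detector), ]
  ch <- data.frame(channel = seq_len(nrow(ch)), ch, row.names = NULL)
  for (cls in c("short", "long")) {
    if (!any(ch$class == cls)) {
      warning("layout has zero ", cls, " channels")
    }
  }

  structure(
    list(sources = src, detectors = det, channels = ch,
         short_sep = short_sep, long_sep = long_sep, tol = tol,
         source_arrays = src_arr, detector_arrays = det_arr),
    class = "probe_layout"
  )
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf(
    "<probe_layout> %d sources, %d detectors, %d channels (%d short / %d long)\n",
    nrow(x$sources), nrow(x$detectors), nrow(x$channels),
    sum(x$channels$class == "short"), sum(x$channels$class == "long")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
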
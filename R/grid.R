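#' Voxelize the reconstruction region beneath a probe layout
#'
#' The reconstruction region is a cuboid slab under each optode array: the
#' array's probe square, extended laterally along its diagonals by
#' `diagonal_extension` (default 1.5), and extending from the scalp surface
#' (z = 0) down to `depth` mm. The slab is cut into isotropic voxels
#' (default 4 mm) and every voxel center is labelled with a tissue layer
#' (from `layer_depths`, a named vector of increasing layer bottom depths
#' partitioning [0, depth]) and with a compartment: `scalp` for the
#' scalp/skull layer and `cortex` for everything below it.
#'
#' Region extents that are not multiples of the voxel size are rounded
#' outward (with a warning); overlapping array regions are merged.
#'
#' @param layout a [probe_layout()].
#' @param voxel_size isotropic voxel edge in mm.
#' @param depth slab depth below the scalp surface in mm.
#' @param diagonal_extension lateral extension factor of the probe square.
#' @param layer_depths named numeric vector of layer bottom depths (mm),
#'   increasing, last value >= `depth`.
#' @return object of class `voxel_grid`: list with `centers` (V x 3, mm),
#'   `size`, `depth` (voxel center depth below scalp), `layer`,
#'   `compartment`, and `array` membership.
#' @examples
#' g <- build_voxel_grid(probe_layout(default_layout_config(n_arrays = 1)))
#' table(g$compartment)
#' @export
build_voxel_grid <- function(layout, voxel_size = 4, depth = 28,
                             diagonal_extension = 1.5,
                             layer_depths = c(scalp_skull = 11, CSF = 13,
                                              gray = 28)) {
  stopifnot(voxel_size > 0, depth > 0, diagonal_extension > 0)
  layer_depths[length(layer_depths)] <-
    min(layer_depths[length(layer_depths)], depth)
  if (is.unsorted(layer_depths, strictly = FALSE) ||
      layer_depths[length(layer_depths)] < depth) {
    stop("`layer_depths` must be increasing bottom depths partitioning ",
         "[0, depth]")
  }

  probes <- rbind(layout$sources, layout$detectors)
  arr <- c(layout$source_arrays, layout$detector_arrays)
  nz <- depth / voxel_size
  if (abs(nz - round(nz)) > 1e-9) {
    warning("depth is not a multiple of the voxel size; region rounded ",
            "outward")
  }
  nz <- ceiling(nz - 1e-9)
  zc <- (seq_len(nz) - 0.5) * voxel_size

  centers <- NULL
  varr <- integer(0)
  for (k in sort(unique(arr))) {
    p <- probes[arr == k, , drop = FALSE]
    cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2]))
    half <- diagonal_extension *
      max(diff(range(p[, 1])), diff(range(p[, 2]))) / 2
    nv <- 2 * half / voxel_size
    if (abs(nv - round(nv)) > 1e-9) {
      warning("lateral extent of array ", k, " is not a multiple of the ",
              "voxel size; region rounded outward")
    }
    nv <- ceiling(nv - 1e-9)
    off <- (seq_len(nv) - (nv + 1) / 2) * voxel_size
    lat <- expand.grid(x = cx + off, y = cy + off)
    cent <- cbind(x = rep(lat$x, times = nz),
                  y = rep(lat$y, times = nz),
                  z = rep(zc, each = nrow(lat)))
    centers <- rbind(centers, cent)
    varr <- c(varr, rep(k, nrow(cent)))
  }
  # merge overlapping array regions: drop duplicated voxel centers
  dup <- duplicated(round(centers, 6))
  centers <- centers[!dup, , drop = FALSE]
  varr <- varr[!dup]

  bottoms <- c(0, layer_depths)
  li <- findInterval(centers[, 3], bottoms, rightmost.closed = FALSE,
                     left.open = TRUE)
  layer <- names(layer_depths)[pmin(li, length(layer_depths))]
  compartment <- ifelse(layer == names(layer_depths)[1], "scalp", "cortex")

  structure(
    list(centers = centers, size = voxel_size, depth = centers[, 3],
         max_depth = depth, layer = layer, compartment = compartment,
         array = varr, n = nrow(centers),
         layer_depths = layer_depths,
         diagonal_extension = diagonal_extension),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d voxels of %.1f mm (%d scalp / %d cortex), depth <= %.0f mm\n",
    x$n, x$size, sum(x$compartment == "scalp"),
    sum(x$compartment == "cortex"), x$max_depth))
  invisible(x)
}
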
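#' Unmix per-wavelength absorption images into hemoglobin species
#'
#' Per-voxel least squares through the extinction matrix:
#' \eqn{(\hat c_{oxy}, \hat c_{deoxy})^T = (E^T E)^{-1} E^T \Delta\mu_a},
#' exact whenever \eqn{\Delta\mu_a} lies in the column space of `E`.
#'
#' @param images list of voxels x time \eqn{\Delta\mu_a} matrices (or
#'   `dot_image` objects), one per wavelength, same grid.
#' @param ext an [extinction_matrix()].
#' @return list with `oxy` and `deoxy` voxels x time matrices.
#' @export
unmix_hemoglobin <- function(images, ext) {
  stopifnot(inherits(ext, "extinction_table"))
  vals <- lapply(images, function(im) {
    if (inherits(im, "dot_image")) im$values else as.matrix(im)
  })
  if (length(vals) != nrow(ext$E)) {
    stop("need one image per wavelength (", nrow(ext$E), ")")
  }
  P <- solve(crossprod(ext$E), t(ext$E))  # 2 x W unmixing operator
  oxy <- P[1, 1] * vals[[1]]
  deoxy <- P[2, 1] * vals[[1]]
  for (w in seq_along(vals)[-1]) {
    oxy <- oxy + P[1, w] * vals[[w]]
    deoxy <- deoxy + P[2, w] * vals[[w]]
  }
  list(oxy = oxy, deoxy = deoxy)
}

#' Gaussian spatial smoothing of a voxel image
#'
#' Separable isotropic Gaussian with \eqn{\sigma = FWHM / \sqrt{8 \ln 2}}
#' mm, implemented as a sparse normalized kernel over voxel centers.
#' Smoothing never mixes compartments: scalp and cortex are smoothed
#' independently (the relevant case is the cortical image entering the
#' connectivity analysis). Kernel weights are truncated beyond
#' 2.5 sigma and renormalized, so a constant image is unchanged.
#'
#' @param values voxels x time matrix (or `dot_image`).
#' @param grid the matching [build_voxel_grid()] (taken from a
#'   `dot_image` automatically).
#' @param fwhm kernel full width at half maximum in mm (default 8).
#' @return smoothed matrix of the same shape.
#' @export
smooth_image <- function(values, grid = NULL, fwhm = 8) {
  if (inherits(values, "dot_image")) {
    grid <- grid %||% values$grid
    values <- values$values
  }
  stopifnot(!is.null(grid), fwhm > 0)
  if (fwhm < grid$size) {
    warning("FWHM (", fwhm, " mm) below voxel size (", grid$size,
            " mm); smoothing has little effect")
  }
  sigma <- fwhm / sqrt(8 * log(2))
  cutoff <- 2.5 * sigma
  out <- values
  for (comp in unique(grid$compartment)) {
    idx <- which(grid$compartment == comp)
    pos <- grid$centers[idx, , drop = FALSE]
    d2 <- outer(pos[, 1], pos[, 1], "-")^2 +
      outer(pos[, 2], pos[, 2], "-")^2 +
      outer(pos[, 3], pos[, 3], "-")^2
    W <- exp(-d2 / (2 * sigma^2))
    W[d2 > cutoff^2] <- 0
    W <- W / rowSums(W)
    W <- Matrix::Matrix(W, sparse = TRUE)
    out[idx, ] <- as.matrix(W %*% values[idx, , drop = FALSE])
  }
  out
}
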
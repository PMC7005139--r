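#' Sensitive-voxel mask across subjects
#'
#' A voxel is *sensitive* when its normalized sensitivity strictly exceeds
#' the threshold (default 0.5) in every subject; the mask is the
#' intersection over subjects.
#'
#' @param sens per-subject normalized sensitivities
#'   ([normalized_sensitivity()]): a list of vectors, or a subjects x
#'   voxels matrix (a single vector is treated as one subject).
#' @param threshold strict threshold in [0, 1].
#' @return object of class `sensitivity_mask`: logical vector with the
#'   threshold attached as attribute.
#' @export
sensitive_mask <- function(sens, threshold = 0.5) {
  if (is.list(sens)) sens <- do.call(rbind, sens)
  if (is.null(dim(sens))) sens <- matrix(sens, nrow = 1)
  mask <- apply(sens > threshold, 2, all)
  if (!any(mask)) {
    stop("no sensitive voxels at threshold ", threshold,
         "; review the threshold or the montage")
  }
  structure(mask, threshold = threshold, class = "sensitivity_mask")
}

#' Fabricate a parcellation over the sensitive cortical sheet
#'
#' Synthetic stand-in for a functional atlas. Two methods:
#' `"balanced"` (default) sorts the sensitive cortical voxels spatially
#' (array, then x, then y, then depth) and chops them into `n_rois`
#' contiguous, nearly equal-sized regions -- deterministic and
#' guaranteeing every region a fair sensitive-voxel count; `"kmeans"`
#' clusters voxel coordinates into compact patches (deterministic under
#' the seed). Voxels outside the mask stay unassigned (label 0).
#'
#' @param grid a [build_voxel_grid()].
#' @param mask sensitive-voxel mask over the grid.
#' @param n_rois number of regions (default 19).
#' @param method `"balanced"` or `"kmeans"`.
#' @param seed RNG seed for the k-means initialization.
#' @return object of class `parcellation`: list with `labels` (integer
#'   per voxel, 0 = unassigned), `names`, `n`.
#' @export
make_parcellation <- function(grid, mask, n_rois = 19,
                              method = c("balanced", "kmeans"), seed = 1) {
  method <- match.arg(method)
  idx <- which(as.logical(mask) & grid$compartment == "cortex")
  if (length(idx) < n_rois) {
    stop("fewer sensitive cortical voxels (", length(idx),
         ") than requested ROIs (", n_rois, ")")
  }
  pos <- grid$centers[idx, , drop = FALSE]
  labels <- integer(grid$n)
  if (method == "balanced") {
    # compact 2-d patches: distribute regions over arrays, split each
    # array's sheet into x-bands, then chop bands along y
    arr <- grid$array[idx]
    arrays <- sort(unique(arr))
    counts <- vapply(arrays, function(a) sum(arr == a), 1L)
    n_per <- diff(round(cumsum(c(0, counts)) / sum(counts) * n_rois))
    while (any(n_per == 0) && any(n_per > 1)) {  # every array >= 1 region
      n_per[which.max(n_per)] <- max(n_per) - 1
      n_per[which.min(n_per)] <- min(n_per) + 1
    }
    lab <- integer(length(idx))
    next_lab <- 0
    for (ai in seq_along(arrays)) {
      sel <- which(arr == arrays[ai])
      na <- n_per[ai]
      if (na == 0) next
      nx <- max(1, round(sqrt(na)))
      per_band <- diff(round(seq(0, na, length.out = nx + 1)))
      ordx <- sel[order(pos[sel, 1], pos[sel, 2], pos[sel, 3])]
      # band widths proportional to the regions they must hold, so all
      # regions end up nearly equal-sized
      band_cuts <- round(cumsum(c(0, per_band)) / na * length(sel))
      for (b in seq_len(nx)) {
        band <- ordx[(band_cuts[b] + 1):band_cuts[b + 1]]
        nb <- per_band[b]
        if (nb == 0) next
        ordy <- band[order(pos[band, 2], pos[band, 3])]
        cc <- round(seq(0, length(band), length.out = nb + 1))
        for (r in seq_len(nb)) {
          lab[ordy[(cc[r] + 1):cc[r + 1]]] <- next_lab + r
        }
        next_lab <- next_lab + nb
      }
    }
    labels[idx] <- lab
  } else {
    set.seed(seed)
    fit <- stats::kmeans(pos[, 1:2], centers = n_rois, nstart = 10,
                         iter.max = 100)
    ord <- order(fit$centers[, 1], fit$centers[, 2])
    relab <- integer(n_rois); relab[ord] <- seq_len(n_rois)
    labels[idx] <- relab[fit$cluster]
  }
  structure(
    list(labels = labels, names = sprintf("ROI_%02d", seq_len(n_rois)),
         n = n_rois),
    class = "parcellation"
  )
}

#' Available ROIs
#'
#' An ROI is *available* when it contains at least `min_voxels` sensitive
#' voxels (default 10).
#'
#' @param parcellation a [make_parcellation()] (or any list with integer
#'   `labels` and `names`).
#' @param mask sensitive-voxel mask on the same grid.
#' @param min_voxels minimum sensitive-voxel count.
#' @return integer vector of available ROI labels (named).
#' @export
available_rois <- function(parcellation, mask, min_voxels = 10) {
  labs <- parcellation$labels[as.logical(mask)]
  counts <- tabulate(labs[labs > 0], nbins = parcellation$n)
  keep <- which(counts >= min_voxels)
  if (!length(keep)) stop("no available ROIs (all below ", min_voxels,
                          " sensitive voxels)")
  names(keep) <- parcellation$names[keep]
  keep
}

#' ROI-averaged time series
#'
#' For each available ROI, the unweighted mean over its sensitive member
#' voxels.
#'
#' @param values voxels x time image matrix (or `dot_image`).
#' @param parcellation a [make_parcellation()].
#' @param mask sensitive-voxel mask.
#' @param rois ROI labels to extract (default [available_rois()]).
#' @return time x ROI matrix with ROI names as columns.
#' @export
roi_timeseries <- function(values, parcellation, mask,
                           rois = available_rois(parcellation, mask)) {
  if (inherits(values, "dot_image")) values <- values$values
  mask <- as.logical(mask)
  out <- vapply(rois, function(r) {
    v <- which(parcellation$labels == r & mask)
    colMeans(values[v, , drop = FALSE])
  }, numeric(ncol(values)))
  colnames(out) <- names(rois) %||% parcellation$names[rois]
  out
}

#' ROI partial-correlation connectivity matrix
#'
#' Partial correlations from the inverse sample covariance:
#' \eqn{pc_{ij} = -P_{ij} / \sqrt{P_{ii} P_{jj}}} with
#' \eqn{P = \hat\Sigma^{-1}}; equivalently the correlation of residuals
#' after regressing out all other ROIs. Conditioning on all remaining
#' ROIs suppresses shared extra-neural components (slow systemic
#' oscillations) that plain correlation would absorb. For short segments
#' (fewer than `3 R` samples) a ridge is added to the covariance
#' diagonal.
#'
#' @param ts time x ROI matrix.
#' @param shrinkage ridge fraction of the mean diagonal (`NULL`: 0 when
#'   `T >= 3 R`, else 0.1).
#' @return symmetric ROI x ROI matrix with unit diagonal and the ROI
#'   names preserved; the shrinkage used is attached as attribute.
#' @export
partial_correlation <- function(ts, shrinkage = NULL) {
  ts <- as.matrix(ts)
  R <- ncol(ts); Tn <- nrow(ts)
  if (is.null(shrinkage)) shrinkage <- if (Tn >= 3 * R) 0 else 0.1
  Cv <- stats::cov(ts)
  if (shrinkage > 0) {
    diag(Cv) <- diag(Cv) + shrinkage * mean(diag(Cv))
  }
  P <- tryCatch(solve(Cv), error = function(e) {
    qrC <- qr(Cv)
    dep <- colnames(ts)[qrC$pivot[-seq_len(qrC$rank)]] %||% "unknown"
    stop("singular ROI covariance without shrinkage; collinear ROI(s): ",
         paste(dep, collapse = ", "))
  })
  d <- sqrt(diag(P))
  pc <- -P / tcrossprod(d)
  diag(pc) <- 1
  pc <- pmin(pmax((pc + t(pc)) / 2, -1), 1)
  dimnames(pc) <- list(colnames(ts), colnames(ts))
  attr(pc, "shrinkage") <- shrinkage
  pc
}
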
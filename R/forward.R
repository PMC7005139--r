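#' Photon-fluence Green's function in a semi-infinite medium
#'
#' Continuous-wave Green's function of the photon-diffusion equation for a
#' homogeneous semi-infinite medium occupying z >= 0, with the
#' extrapolated-boundary (image-source) treatment of the free surface:
#' \deqn{G(a, b) = \frac{1}{4\pi D}\left(\frac{e^{-\mu_{eff} r_1}}{r_1} -
#'   \frac{e^{-\mu_{eff} r_2}}{r_2}\right)}
#' where \eqn{r_1 = |a - b|}, \eqn{r_2} is the distance from `a` to the
#' mirror image of `b` across the extrapolated boundary at
#' \eqn{z = -z_b}, \eqn{D = 1/(3(\mu_a + \mu_s'))} and
#' \eqn{z_b = 2 D (1 + R_{eff}) / (1 - R_{eff})}. The kernel is symmetric
#' in its two arguments, strictly positive inside the medium, and strictly
#' decreasing with distance. Coincident points are handled by clamping the
#' source-point distance at `clamp` mm (half a voxel by default).
#'
#' This analytic kernel stands in for a voxel-wise photon-transport
#' simulation: it is deterministic and preserves the characteristic
#' banana-shaped sensitivity geometry that the inverse solvers rely on.
#'
#' @param a,b points in mm, length-3 vectors or n x 3 matrices (paired by
#'   row; one may be a single point).
#' @param medium single-row data frame from [optical_parameters()].
#' @param clamp minimum source-point distance in mm.
#' @return fluence values (1/mm, relative units).
#' @examples
#' m <- optical_parameters("gray")
#' fluence_green(c(0, 0, 1), c(20, 0, 1), m)
#' @export
fluence_green <- function(a, b, medium, clamp = 2) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b), medium$mua > 0, medium$musp > 0)
  D <- 1 / (3 * (medium$mua + medium$musp))
  mueff <- mu_eff(medium)
  reff <- reflection_eff(medium$n)
  zb <- 2 * D * (1 + reff) / (1 - reff)

  r1 <- pmax(sqrt(rowSums((a - b)^2)), clamp)
  bi <- b
  bi[, 3] <- -b[, 3] - 2 * zb
  r2 <- pmax(sqrt(rowSums((a - bi)^2)), r1)
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
}

#' Build the Rytov sensitivity matrix
#'
#' Channels x voxels linear operator mapping absorption changes
#' \eqn{\Delta\mu_a} (1/mm) to optical-density changes (base-10 OD, the
#' convention of the log-ratio preprocessing step):
#' \deqn{S(ch, v) = \frac{G(r_s, r_v)\, G(r_v, r_d)}{G(r_s, r_d)}
#'   \times V_{vox} / \ln 10.}
#' Optode points are placed one transport mean free path
#' (\eqn{z_0 = 1/\mu_s'}) below the surface, the standard diffusion-theory
#' representation of a collimated surface source; by reciprocity the same
#' treatment applies to detectors, which makes every sensitivity row
#' invariant under a source/detector swap.
#'
#' Under the default optics the tissue parameters are common to the three
#' wavelengths, so a single matrix is stored and shared by all wavelengths
#' (recorded in `provenance`).
#'
#' @param layout a [probe_layout()].
#' @param grid a [build_voxel_grid()] in the same coordinate frame.
#' @param medium single-row data frame from [optical_parameters()];
#'   the default models the whole half-space with scalp/skull optics.
#' @param wavelengths wavelengths (nm) the matrix applies to.
#' @return object of class `sensitivity_matrix`: list with `S` (channels x
#'   voxels), `col_norm` (column norms \eqn{\rho_v}), `rho2` (squared
#'   column norms normalized by their maximum, in [0, 1]), `channels`,
#'   `grid`, `wavelengths`, `provenance`.
#' @export
build_sensitivity <- function(layout, grid,
                              medium = optical_parameters("scalp_skull"),
                              wavelengths = c(780, 805, 830)) {
  z0 <- 1 / medium$musp
  src <- layout$sources; src[, 3] <- pmax(src[, 3], z0)
  det <- layout$detectors; det[, 3] <- pmax(det[, 3], z0)
  ch <- layout$channels
  V <- grid$n

  gs <- matrix(0, nrow(src), V)  # source -> voxel fluence
  for (s in seq_len(nrow(src))) {
    gs[s, ] <- fluence_green(src[s, ], grid$centers, medium,
                             clamp = grid$size / 2)
  }
  gd <- matrix(0, nrow(det), V)
  for (d in seq_len(nrow(det))) {
    gd[d, ] <- fluence_green(det[d, ], grid$centers, medium,
                             clamp = grid$size / 2)
  }
  gsd <- fluence_green(src[ch$source, , drop = FALSE],
                       det[ch$detector, , drop = FALSE], medium,
                       clamp = grid$size / 2)
  if (any(gsd <= 0)) {
    stop("non-positive source-detector fluence for channel(s) ",
         paste(ch$channel[gsd <= 0], collapse = ", "))
  }

  S <- (gs[ch$source, , drop = FALSE] * gd[ch$detector, , drop = FALSE]) /
    gsd * grid$size^3 / log(10)
  rownames(S) <- ch$channel

  cn2 <- colSums(S^2)
  structure(
    list(S = S, col_norm = sqrt(cn2), rho2 = cn2 / max(cn2),
         channels = ch, grid = grid, wavelengths = wavelengths,
         medium = medium,
         provenance = list(
           kernel = "semi-infinite diffusion Green's function, extrapolated boundary",
           od_convention = "base-10 (factor 1/ln 10)",
           shared_across_wavelengths = TRUE,
           source_depth_mm = z0)),
    class = "sensitivity_matrix"
  )
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("<sensitivity_matrix> %d channels x %d voxels (%s)\n",
              nrow(x$S), ncol(x$S),
              paste(x$wavelengths, collapse = "/")))
  invisible(x)
}

#' Normalized voxel sensitivity within a compartment
#'
#' Per-voxel sensitivity value in [0, 1] against which the
#' sensitive-voxel threshold is applied; voxels outside the compartment
#' are returned as 0. Two conventions are offered:
#'
#' * `"compensated"` (default): column norms of the depth-compensated
#'   operator \eqn{S L^{-1}} with \eqn{L = \sqrt{\rho^2 + \beta}},
#'   `beta = 0.1` -- the sensitivity of the operator the minimum-norm
#'   reconstruction actually applies, which flattens the steep raw depth
#'   decay and makes the 0.5 threshold select the well-sensed cortical
#'   sheet rather than only the single best voxel column.
#' * `"raw"`: raw column norms divided by their compartment maximum.
#'
#' @param sm a [build_sensitivity()] object.
#' @param compartment `"cortex"` (default) or `"scalp"`.
#' @param method `"compensated"` or `"raw"`.
#' @param beta depth-compensation floor for `"compensated"`.
#' @return numeric vector of length V.
#' @export
normalized_sensitivity <- function(sm, compartment = "cortex",
                                   method = c("compensated", "raw"),
                                   beta = 0.1) {
  method <- match.arg(method)
  idx <- sm$grid$compartment == compartment
  if (!any(idx)) stop("grid has no ", compartment, " voxels")
  out <- numeric(length(idx))
  v <- if (method == "raw") {
    sm$col_norm[idx]
  } else {
    # squared column norms relative to the compartment maximum
    r2 <- (sm$col_norm[idx] / max(sm$col_norm[idx]))^2
    sqrt(r2 / (r2 + beta))
  }
  out[idx] <- v / max(v)
  out
}
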
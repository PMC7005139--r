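# Shared small fixtures, built once per test run.

# single 4x4 array over a 10x10x5-voxel slab (500 voxels: 200 scalp,
# 300 cortex) -- the standard small reconstruction test bed
small_layout <- probe_layout(default_layout_config(n_arrays = 1))
small_grid <- suppressWarnings(
  build_voxel_grid(small_layout, voxel_size = 4, depth = 20,
                   diagonal_extension = 1.0,
                   layer_depths = c(scalp_skull = 8, gray = 20)))
small_sm <- build_sensitivity(small_layout, small_grid)

# a two-layer phantom: two active cortical voxels + inhomogeneous smooth
# scalp field, amplitudes calibrated at channel level
make_phantom <- function(seed, Tn = 1000, cortex_amp = 1, scalp_amp = 2,
                         noise_sd = 0.2) {
  set.seed(seed)
  g <- small_grid; sm <- small_sm
  cortex <- which(g$compartment == "cortex")
  scalp <- which(g$compartment == "scalp")
  cand <- cortex[g$depth[cortex] == 10]
  pos <- g$centers[cand, ]
  a1 <- cand[which.min((pos[, 1] + 10)^2 + (pos[, 2] + 10)^2)]
  a2 <- cand[which.min((pos[, 1] - 12)^2 + (pos[, 2] - 8)^2)]
  ar1 <- function(n) {
    v <- stats::filter(rnorm(n), 0.9, method = "recursive")
    as.numeric(v) / sd(v)
  }
  act <- rbind(ar1(Tn), ar1(Tn))
  sp <- g$centers[scalp, ]
  cen <- cbind(runif(3, min(sp[, 1]), max(sp[, 1])),
               runif(3, min(sp[, 2]), max(sp[, 2])))
  Phi <- exp(-(outer(sp[, 1], cen[, 1], "-")^2 +
                 outer(sp[, 2], cen[, 2], "-")^2) / (2 * 15^2))
  Fts <- rbind(ar1(Tn), ar1(Tn), ar1(Tn))
  Xc <- matrix(0, g$n, Tn); Xc[c(a1, a2), ] <- act
  Xs <- matrix(0, g$n, Tn); Xs[scalp, ] <- Phi %*% Fts
  Yc <- sm$S %*% Xc; Ys <- sm$S %*% Xs
  if (cortex_amp > 0) Yc <- cortex_amp * Yc / sd(Yc) else Yc <- 0 * Yc
  Ys <- scalp_amp * Ys / sd(Ys)
  Y <- Yc + Ys + matrix(rnorm(nrow(sm$S) * Tn, sd = noise_sd), nrow(sm$S))
  list(Y = Y, sm = sm, grid = g, cortex = cortex, scalp = scalp,
       active = c(a1, a2), Tn = Tn)
}

# distance from the strongest cortical voxel of an image to the nearest
# truly active voxel
peak_location_error <- function(values, phantom) {
  v <- rowMeans(values^2)
  v[-phantom$cortex] <- 0
  pk <- which.max(v)
  min(sqrt(colSums((t(phantom$grid$centers[phantom$active, , drop = FALSE]) -
                      phantom$grid$centers[pk, ])^2)))
}

# HB on a phantom, seeded by its own MN first step
phantom_hb <- function(ph, gamma0_factor = 0.1, max_iter = 200) {
  mn <- mn_reconstruct(ph$Y, ph$sm, config = list(mode = "MN"))
  lam0 <- compute_lambda0(mn)
  hb <- suppressWarnings(hb_reconstruct(
    ph$Y, ph$sm,
    prior = list(lambda0 = lam0[ph$cortex],
                 scalp_var = 10 * mean(lam0[ph$scalp])),
    config = hb_config(gamma0 = gamma0_factor * ph$Tn,
                       max_iter = max_iter, tol = 1e-3)))
  list(mn = mn, hb = hb)
}

popsd_ <- function(x) sqrt(mean((x - mean(x))^2))
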
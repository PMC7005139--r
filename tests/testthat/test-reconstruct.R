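test_that("depth weights follow sqrt(rho2 + beta) with the mode rules", {
  S <- diag(6)
  dw <- depth_weights(S, mode = "MN_WU")
  expect_equal(dw$beta, 0.1)
  expect_equal(dw$L, rep(sqrt(1.1), 6))
  dw2 <- depth_weights(small_sm, mode = "MN")
  in_band <- small_sm$grid$depth >= 18 & small_sm$grid$depth <= 22
  expect_equal(dw2$beta, mean(small_sm$rho2[in_band]))
  expect_lt(dw2$beta, 0.1)  # deep-voxel rho2 is small
  # deeper voxel with smaller rho2 gets a smaller weight
  o <- order(small_sm$grid$depth)
  expect_lt(dw2$L[o[length(o)]], dw2$L[o[1]])
  expect_error(depth_weights(small_sm, mode = "MN",
                             depth_band = c(100, 120)),
               "no voxels")
  expect_error(depth_weights(matrix(rnorm(20), 4), mode = "MN"),
               "needs voxel depths")
})

test_that("evidence maximization recovers the generating alpha", {
  set.seed(7)
  N <- 96; V <- 300; Tn <- 2000
  St <- matrix(rnorm(N * V), N) / sqrt(V)
  s_true <- 2
  X <- matrix(rnorm(V * Tn, sd = sqrt(s_true)), V)
  Y <- St %*% X + matrix(rnorm(N * Tn, sd = sqrt(s_true * 1e-2)), N)
  ev <- evidence_alpha(Y, St)
  step <- 10 / 60  # log10 spacing of the default grid
  expect_lt(abs(log10(ev$alpha) - (-2)), step + 1e-9)
  # argmax contract
  expect_true(all(ev$evidence$log_evidence <=
                    ev$evidence$log_evidence[
                      which(ev$evidence$alpha == ev$alpha)] + 1e-9))
  # pure noise pushes alpha to the heavy-regularization end
  Y0 <- matrix(rnorm(N * Tn), N)
  expect_gte(evidence_alpha(Y0, St)$alpha, 10)
  expect_error(evidence_alpha(matrix(0, N, 10), St), "all zeros")
})

test_that("minimum norm equals the closed-form Tikhonov solution", {
  # identity system: x = y / (1 + alpha)
  y <- matrix(rnorm(5 * 3), 5)
  img <- mn_reconstruct(y, diag(5),
                        config = list(alpha = 1, L = rep(1, 5)))
  expect_equal(img$values, y / 2, tolerance = 1e-12)

  # random rectangular systems vs the normal-equation oracle
  set.seed(8)
  for (i in 1:5) {
    S <- matrix(rnorm(10 * 50), 10)
    L <- sqrt(colSums(S^2) / max(colSums(S^2)) + 0.1)
    Y <- matrix(rnorm(10 * 7), 10)
    img <- mn_reconstruct(Y, S, config = list(alpha = 0.1, L = L))
    St <- sweep(S, 2, L, "/")
    oracle <- diag(1 / L) %*%
      solve(crossprod(St) + 0.1 * diag(50), crossprod(St, Y))
    expect_lt(max(abs(img$values - oracle)) / max(abs(oracle)), 1e-8)
  }

  # residual norm is non-decreasing along the regularization path
  set.seed(9)
  S <- matrix(rnorm(12 * 40), 12)
  Y <- matrix(rnorm(12 * 5), 12)
  res <- vapply(10^seq(-4, 2, by = 1), function(a) {
    img <- mn_reconstruct(Y, S, config = list(alpha = a,
                                              L = rep(1, 40)))
    sqrt(sum((Y - S %*% img$values)^2))
  }, numeric(1))
  expect_true(all(diff(res) >= -1e-10))
})

test_that("lambda0 is the temporal mean square with a floor", {
  expect_equal(compute_lambda0(matrix(2, 4, 10)), rep(4, 4))
  expect_equal(compute_lambda0(matrix(0, 3, 5)), rep(1e-12, 3))
  set.seed(10)
  X <- matrix(rnorm(60), 6)
  oracle <- vapply(1:6, function(v) mean(X[v, ]^2), numeric(1))
  expect_equal(compute_lambda0(X), pmax(oracle, 1e-12), tolerance = 1e-12)
})

test_that("HB reduces to the fixed-prior ridge at infinite confidence and
           to pure ARD at zero confidence", {
  set.seed(11)
  N <- 20; V <- 50; Tn <- 40
  S <- matrix(rnorm(N * V), N)
  lam0 <- runif(V, 0.5, 2)
  Y <- S %*% matrix(rnorm(V * Tn, sd = 0.5), V) +
    matrix(rnorm(N * Tn, sd = 0.3), N)
  sig2 <- 0.09
  hb <- hb_reconstruct(Y, S, compartments = rep("cortex", V),
                       prior = list(lambda0 = lam0),
                       config = hb_config(gamma0 = 1e12 * Tn,
                                          sigma2 = sig2,
                                          update_noise = FALSE,
                                          max_iter = 5, tol = 1e-10))
  ridge <- diag(lam0) %*% t(S) %*%
    solve(S %*% diag(lam0) %*% t(S) + sig2 * diag(N), Y)
  expect_lt(max(abs(hb$values - ridge)) / max(abs(ridge)), 1e-6)

  # gamma0 = 0: one M-step is the pure data-driven ARD rule
  stat2 <- runif(V, 0.1, 3)
  expect_equal(hbdot:::hb_ard_update(stat2, Tn, 0, lam0), stat2 / Tn)
  # and the general update interpolates between the two
  g <- 7
  expect_equal(hbdot:::hb_ard_update(stat2, Tn, g, lam0),
               (stat2 + 2 * g * lam0) / (Tn + 2 * g))
})

test_that("ARD shrinks truly silent voxels monotonically", {
  set.seed(12)
  N <- 30; V <- 60; Tn <- 200
  S <- matrix(rnorm(N * V), N)
  active <- c(5, 40)
  X <- matrix(0, V, Tn)
  X[active, ] <- rnorm(2 * Tn)
  Y <- S %*% X  # noise-free sparse phantom
  hb <- suppressWarnings(
    hb_reconstruct(Y, S, compartments = rep("cortex", V),
                   prior = list(lambda0 = rep(1, V)),
                   config = hb_config(gamma0 = 0, sigma2 = 1e-2,
                                      update_noise = FALSE,
                                      max_iter = 20, tol = 0,
                                      track_lambda = TRUE)))
  path <- do.call(rbind, hb$diagnostics$lambda_path)
  silent <- setdiff(seq_len(V), active)
  drops <- apply(path[, silent, drop = FALSE], 2, function(v) all(diff(v) <= 1e-12))
  expect_true(all(drops))
  # active voxels keep far larger variances than silent ones
  expect_gt(min(hb$diagnostics$lambda[active]),
            100 * max(hb$diagnostics$lambda[silent]))
})

test_that("gamma0 sweep values are accepted and change the solution smoothly", {
  ph <- make_phantom(13, Tn = 300)
  outs <- lapply(c(0.1, 0.01, 0.001, 1e-4), function(f) {
    phantom_hb(ph, gamma0_factor = f, max_iter = 40)$hb
  })
  for (o in outs) expect_s3_class(o, "dot_image")
  g <- vapply(outs, function(o) o$diagnostics$gamma0, numeric(1))
  expect_equal(g, c(0.1, 0.01, 0.001, 1e-4) * ph$Tn)
})

test_that("hemoglobin unmixing inverts the extinction mixture", {
  et <- extinction_matrix()
  V <- 20; Tn <- 15
  set.seed(14)
  oxy <- matrix(rnorm(V * Tn), V); deoxy <- matrix(rnorm(V * Tn), V)
  imgs <- lapply(1:3, function(w) {
    et$E[w, 1] * oxy + et$E[w, 2] * deoxy
  })
  un <- unmix_hemoglobin(imgs, et)
  expect_lt(max(abs(un$oxy - oxy)), 1e-12)
  expect_lt(max(abs(un$deoxy - deoxy)), 1e-12)
  # overdetermined noisy fixture vs normal-equation oracle
  imgs2 <- lapply(imgs, function(m) m + 0.1)
  un2 <- unmix_hemoglobin(imgs2, et)
  stacked <- do.call(rbind, lapply(imgs2, function(m) as.numeric(m)))
  oracle <- solve(crossprod(et$E), crossprod(et$E, stacked))
  expect_lt(max(abs(un2$oxy - matrix(oracle[1, ], V))), 1e-12)
  # zero in, zero out
  z <- unmix_hemoglobin(lapply(1:3, function(i) matrix(0, 2, 2)), et)
  expect_equal(z$oxy, matrix(0, 2, 2))
})

test_that("Gaussian smoothing has the right kernel width and unit mass", {
  g <- small_grid
  delta <- matrix(0, g$n, 1)
  # an interior cortical voxel
  cx <- which(g$compartment == "cortex" & g$depth == 14 &
                abs(g$centers[, 1]) < 3 & abs(g$centers[, 2]) < 3)[1]
  delta[cx, 1] <- 1
  sm8 <- smooth_image(delta, g, fwhm = 8)
  d <- sqrt(colSums((t(g$centers) - g$centers[cx, ])^2))
  same_layer <- g$depth == g$depth[cx] & g$compartment == "cortex"
  prof <- sm8[same_layer, 1] / max(sm8[same_layer, 1])
  dd <- d[same_layer]
  # half maximum reached at 4 mm (one voxel step tolerance)
  at4 <- prof[abs(dd - 4) < 1e-9]
  expect_true(all(abs(at4 - 0.5) < 0.2))
  # constant image unchanged (unit-sum kernel)
  const <- matrix(3, g$n, 2)
  smc <- smooth_image(const, g, fwhm = 8)
  expect_equal(smc, const, tolerance = 1e-12)
  expect_warning(smooth_image(delta, g, fwhm = 2), "below voxel size")
})
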
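test_that("tissue optical parameters carry the standard head values", {
  tab <- optical_parameters()
  expect_equal(tab$tissue, c("scalp_skull", "CSF", "gray", "white"))
  expect_equal(tab$mua, c(0.019, 0.004, 0.02, 0.08))
  expect_equal(tab$mus, c(7.8, 0.009, 9.0, 40.9))
  expect_equal(tab$g, c(0.89, 0.89, 0.89, 0.84))
  expect_equal(tab$n, rep(1.37, 4))
  expect_equal(tab$musp, tab$mus * (1 - tab$g))
  expect_error(optical_parameters("bone"), "unknown tissue")
})

test_that("extinction matrix unmixes hemoglobin and rejects degeneracy", {
  et <- extinction_matrix()
  expect_equal(et$wavelengths, c(780, 805, 830))
  expect_equal(qr(et$E)$rank, 2)
  conc <- c(oxy = 0.7, deoxy = -0.3)
  dmua <- et$E %*% conc
  back <- solve(crossprod(et$E), crossprod(et$E, dmua))
  expect_equal(as.numeric(back), as.numeric(conc), tolerance = 1e-12)
  dup <- matrix(c(0.07, 0.11, 0.07, 0.11), 2, 2, byrow = TRUE)
  expect_error(extinction_matrix(c(780, 781), dup), "rank deficient")
  expect_error(extinction_matrix(780), "at least two")
})

test_that("checkerboard arrays yield 13-mm short and sqrt(5)*13-mm long channels", {
  lay <- probe_layout(default_layout_config(n_arrays = 4))
  seps <- sort(unique(round(lay$channels$separation, 2)))
  expect_equal(seps, c(13, 29.07))
  expect_true(all(lay$channels$class[abs(lay$channels$separation - 13) < 1]
                  == "short"))
  # every channel within 1 mm of its class nominal
  nom <- ifelse(lay$channels$class == "short", 13, sqrt(5) * 13)
  expect_true(all(abs(lay$channels$separation - nom) <= 1))
  # per 4x4 array: 24 first-nearest and 24 second-nearest pairs
  expect_equal(sum(lay$channels$class == "short"), 4 * 24)
  expect_equal(sum(lay$channels$class == "long"), 4 * 24)
})

test_that("a single 2x2 checkerboard yields 4 short and no long channels", {
  cfg <- list(arrays = list(list(shape = c(2, 2), pitch = 13,
                                 center = c(0, 0), first = "source")))
  expect_warning(lay <- probe_layout(cfg), "zero long")
  expect_equal(sum(lay$channels$class == "short"), 4)
  expect_equal(sum(lay$channels$class == "long"), 0)
})

test_that("duplicate probe coordinates are rejected", {
  cfg <- list(sources = rbind(c(0, 0, 0), c(13, 0, 0)),
              detectors = rbind(c(0, 0, 0)))
  expect_error(probe_layout(cfg), "duplicate probe")
})

test_that("voxel grid partitions layers and honors the default geometry", {
  g <- suppressWarnings(build_voxel_grid(
    probe_layout(default_layout_config(n_arrays = 1))))
  expect_equal(g$size, 4)
  expect_equal(max(g$depth), 26)  # deepest 4-mm voxel center in 28 mm
  expect_true(all(g$depth >= 0 & g$depth <= 28))
  # every voxel center in exactly one layer
  expect_true(all(g$layer %in% c("scalp_skull", "CSF", "gray")))
  expect_true(all((g$depth <= 11) == (g$layer == "scalp_skull")))
  expect_true(all((g$depth > 13) == (g$layer == "gray")))
  # compartments: scalp above, cortex below
  expect_setequal(unique(g$compartment), c("scalp", "cortex"))
  for (z in unique(g$depth[g$compartment == "cortex"])) {
    expect_true(all(z > g$depth[g$compartment == "scalp"]))
  }
})

test_that("lateral footprint area scales with the square of the extension", {
  lay <- probe_layout(default_layout_config(n_arrays = 1))
  g10 <- suppressWarnings(build_voxel_grid(lay, diagonal_extension = 1.0))
  g15 <- suppressWarnings(build_voxel_grid(lay, diagonal_extension = 1.5))
  per_layer10 <- sum(g10$depth == 2)
  per_layer15 <- sum(g15$depth == 2)
  expect_equal(per_layer15 / per_layer10, 2.25)
})

test_that("diffusion Green's function is symmetric, decaying, and uses the
           Table-derived attenuation", {
  gray <- optical_parameters("gray")
  expect_equal(mu_eff(gray), sqrt(3 * 0.02 * (0.02 + 9.0 * 0.11)),
               tolerance = 1e-12)
  expect_equal(round(mu_eff(gray), 4), 0.2462)
  set.seed(1)
  a <- cbind(runif(100, -30, 30), runif(100, -30, 30), runif(100, 0, 25))
  b <- cbind(runif(100, -30, 30), runif(100, -30, 30), runif(100, 0, 25))
  expect_equal(fluence_green(a, b, gray), fluence_green(b, a, gray),
               tolerance = 1e-14)
  f20 <- fluence_green(c(0, 0, 5), c(20, 0, 5), gray)
  f30 <- fluence_green(c(0, 0, 5), c(30, 0, 5), gray)
  expect_lt(f30, f20)
  expect_gt(f30, 0)
})

test_that("sensitivity matrix is nonnegative, reciprocal, and linear", {
  expect_true(all(small_sm$S >= 0))
  expect_true(all(small_sm$rho2 >= 0 & small_sm$rho2 <= 1))

  # reciprocity: exchanging source and detector reproduces the row
  p1 <- c(-6.5, -6.5, 0); p2 <- c(6.5, 6.5, 0)
  cfg_a <- list(sources = rbind(p1), detectors = rbind(p2))
  cfg_b <- list(sources = rbind(p2), detectors = rbind(p1))
  la <- suppressWarnings(probe_layout(c(cfg_a, short_sep = 13,
                                        long_sep = sqrt(2) * 13)))
  lb <- suppressWarnings(probe_layout(c(cfg_b, short_sep = 13,
                                        long_sep = sqrt(2) * 13)))
  sa <- build_sensitivity(la, small_grid)
  sb <- build_sensitivity(lb, small_grid)
  expect_equal(max(abs(sa$S - sb$S)), 0)

  # linearity: forward projection equals explicit per-voxel summation
  set.seed(2)
  dmua <- runif(small_grid$n)
  proj <- as.numeric(small_sm$S %*% dmua)
  byhand <- rowSums(sweep(small_sm$S, 2, dmua, "*"))
  expect_lt(max(abs(proj - byhand)), 1e-10)
})

test_that("long channels sample deeper tissue than short channels", {
  ch <- small_sm$channels
  wdepth <- function(cls) {
    rows <- small_sm$S[ch$class == cls, , drop = FALSE]
    sum(sweep(rows, 2, small_sm$grid$depth, "*")) / sum(rows)
  }
  expect_gt(wdepth("long"), wdepth("short"))
})

test_that("normalized sensitivity lies in [0,1] and thresholding behaves", {
  ns <- normalized_sensitivity(small_sm)
  expect_true(all(ns >= 0 & ns <= 1))
  expect_true(all(ns[small_sm$grid$compartment == "scalp"] == 0))
  nr <- normalized_sensitivity(small_sm, method = "raw")
  expect_equal(max(nr), 1)
})
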
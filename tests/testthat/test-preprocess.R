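test_that("optical density is the -log10 ratio to the channel mean", {
  V <- cbind(rep(1, 10),                      # constant channel
             c(2, 2, rep(0.75, 8)))           # mean exactly 1
  od <- to_optical_density(V)
  expect_equal(od[, 1], rep(0, 10))
  expect_equal(od[1:2, 2], rep(-log10(2), 2), tolerance = 1e-12)
  # non-positive sample invalidates the channel, not the container
  V2 <- cbind(rep(1, 10), c(rep(1, 9), 0))
  od2 <- to_optical_density(V2)
  expect_true(attr(od2, "invalid")[2])
  expect_false(attr(od2, "invalid")[1])
  expect_true(all(is.na(od2[, 2])))
})

test_that("channel CV follows 100 * sigma / mu with population SD", {
  V <- cbind(rep(3, 20),
             rep(c(0.9, 1.1), 10),
             rep(c(1.7, 2.3), 10))            # mean 2, popsd 0.3
  cv <- channel_cv(V)
  expect_equal(cv[1], 0)
  expect_equal(cv[2], 10, tolerance = 1e-12)
  expect_equal(cv[3], 15, tolerance = 1e-12)
  # zero mean reports infinite CV
  expect_equal(channel_cv(cbind(c(-1, 1)))[1], Inf)
})

test_that("channel rejection is strict in CV and includes saturation", {
  cv <- rbind(c(14, 14, 16),
              c(15, 15, 15),
              c(1, 1, 1),
              c(2, 2, 2))
  sat <- c(FALSE, FALSE, TRUE, FALSE)
  bad <- reject_bad_channels(cv, sat, threshold = 15)
  expect_equal(bad, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(reject_bad_channels(rbind(c(99, 99, 99)), FALSE),
               "all channels rejected")
})

test_that("saturation detection uses the ceiling fraction", {
  V <- matrix(1, 200, 2)
  V[1:3, 2] <- 5                              # 1.5% at ceiling
  expect_equal(detect_saturation(V, ceiling = 5, frac = 0.01),
               c(FALSE, TRUE))
})

test_that("band-pass blocks DC and matches the analytic Butterworth gains", {
  fs <- 18.5
  cfg <- preprocess_config()
  # the 0.009-Hz high-pass has a ~2-min settling time; judge DC
  # rejection well inside a long record
  x <- rep(1, 60000)
  y <- bandpass(x, fs, cfg)
  expect_lt(max(abs(y[20000:40000])), 1e-6)

  gain_single <- function(f) {
    t <- (0:60000) / fs
    x <- sin(2 * pi * f * t)
    y <- bandpass(x, fs, cfg, mode = "single_pass")
    n <- length(y)
    seg <- y[(n - round(20 / f * fs)):n]
    (max(seg) - min(seg)) / 2
  }
  h_analytic <- function(f) {
    (1 + (0.009 / f)^6)^-0.5 * (1 + (f / 0.08)^14)^-0.5
  }
  g04 <- gain_single(0.04)
  expect_gt(g04, 0.98)
  expect_equal(g04, h_analytic(0.04), tolerance = 0.01)
  expect_equal(gain_single(0.2), h_analytic(0.2), tolerance = 0.1)

  # linearity of the filter operator (single pass; the zero-phase
  # variant adds data-dependent edge padding)
  set.seed(3)
  a <- rnorm(2000); b <- rnorm(2000)
  lhs <- bandpass(2 * a - 3 * b, fs, cfg, mode = "single_pass")
  rhs <- 2 * bandpass(a, fs, cfg, mode = "single_pass") -
    3 * bandpass(b, fs, cfg, mode = "single_pass")
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("global short-channel regression removes the scalp component", {
  set.seed(4)
  Tn <- 5000
  ar1 <- function(n) as.numeric(stats::filter(rnorm(n), 0.8,
                                              method = "recursive"))
  g <- ar1(Tn); s <- ar1(Tn)
  short <- c(TRUE, TRUE, FALSE)
  X <- cbind(g, g, 2 * g + s)
  res <- regress_scalp_global(X, short)
  expect_lt(max(abs(res[, 1:2])), 1e-10)      # perfect fit channels
  expect_gt(cor(res[, 3], s), 0.99)           # independent part survives
  # orthogonal channel is untouched
  o <- s - g * sum(s * (g - mean(g))) / sum((g - mean(g))^2)
  o <- o - mean(o)
  X2 <- cbind(g, o)
  res2 <- regress_scalp_global(X2, c(TRUE, FALSE))
  expect_lt(max(abs(res2[, 2] - o)), 1e-10)
  # idempotence (the second pass finds a variance-free regressor)
  expect_warning(twice <- regress_scalp_global(res, short),
                 "zero variance")
  expect_lt(max(abs(twice - res)), 1e-10)
})

test_that("time-point removal triggers on short channels only, exactly", {
  set.seed(5)
  Tn <- 1000
  X <- matrix(rnorm(3 * Tn), Tn, 3)
  short <- c(TRUE, TRUE, FALSE)
  base <- remove_bad_timepoints(X, short)
  spike_at <- 517
  X2 <- X
  X2[spike_at, 1] <- mean(X[, 1]) + 10 * popsd_(X[, 1])
  r2 <- remove_bad_timepoints(X2, short)
  expect_true(spike_at %in% r2$removed)
  expect_setequal(setdiff(r2$removed, base$removed), spike_at)
  # spike in a long channel changes nothing
  X3 <- X
  X3[spike_at, 3] <- 100
  r3 <- remove_bad_timepoints(X3, short)
  expect_equal(r3$removed, base$removed)
  # constant signals never trigger removal
  C <- matrix(1, 100, 2)
  expect_length(remove_bad_timepoints(C, c(TRUE, TRUE))$removed, 0)
})

test_that("preprocess_run rejects injected artifacts and keeps alignment", {
  spec <- truth_spec(n_subjects = 1, n_runs = 1, duration = 90, seed = 21)
  study <- suppressWarnings(simulate_study(spec))
  run <- study$subjects[[1]]$run1
  pre <- preprocess_run(run$cts)
  expect_true(all(run$bad_injected %in% pre$bad))
  expect_true(all(run$saturated_injected %in% pre$bad))
  expect_equal(length(pre$good) + length(pre$bad), nrow(run$cts$channels))
  # same retained set across wavelengths, metadata preserved
  expect_equal(unique(vapply(pre$od, nrow, 1L)), length(pre$retained))
  expect_equal(nrow(pre$channels), length(pre$good))
  # computing the global short mean after masking equals masking first
  od <- to_optical_density(run$cts)
  filt <- bandpass(od$data[[1]], run$cts$fs, preprocess_config())
  short <- run$cts$channels$class == "short"
  bad <- seq_len(ncol(filt)) %in% pre$bad
  g1 <- rowMeans(filt[, short & !bad, drop = FALSE])
  sub <- filt[, !bad, drop = FALSE]
  g2 <- rowMeans(sub[, short[!bad], drop = FALSE])
  expect_equal(g1, g2)
})

test_that("decimation preserves channels and rescales the clock", {
  spec <- truth_spec(n_subjects = 1, n_runs = 1, duration = 90, seed = 22)
  study <- suppressWarnings(simulate_study(spec))
  pre <- preprocess_run(study$subjects[[1]]$run1$cts)
  dec <- decimate_run(pre, 5)
  expect_equal(dec$fs, pre$fs / 5)
  expect_equal(ncol(dec$od[[1]]), ncol(pre$od[[1]]))
  expect_equal(dec$od[[2]][2, ], pre$od[[2]][6, ])
})
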
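test_that("Fisher z-transformation clips at the boundary", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(round(fisher_z(0.5), 5), 0.54931)
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1), -fisher_z(1))
  expect_error(fisher_z(1.2), "not a correlation")
})

test_that("matrix similarity is a z-space Pearson correlation", {
  set.seed(20)
  R <- 7
  C1 <- partial_correlation(matrix(rnorm(300 * R), ncol = R) %*%
                              chol(diag(R) * 0.5 + 0.5))
  dimnames(C1) <- list(paste0("r", 1:R), paste0("r", 1:R))
  # self-similarity saturates
  s <- similarity(C1, C1)
  expect_equal(s$r, 1)
  expect_equal(s$z, atanh(1 - 1e-7))
  # monotone transform fixture vs hand-rolled Pearson
  C2 <- tanh(1.3 * atanh(C1)); diag(C2) <- 1; dimnames(C2) <- dimnames(C1)
  s2 <- similarity(C1, C2)
  v1 <- atanh(pmin(pmax(C1[lower.tri(C1)], -1 + 1e-7), 1 - 1e-7))
  v2 <- atanh(pmin(pmax(C2[lower.tri(C2)], -1 + 1e-7), 1 - 1e-7))
  pearson <- sum((v1 - mean(v1)) * (v2 - mean(v2))) /
    sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
  expect_equal(s2$r, pearson, tolerance = 1e-12)
  # symmetry and joint permutation invariance
  expect_equal(similarity(C2, C1)$r, s2$r)
  p <- sample(R)
  expect_equal(similarity(C1[p, p], C2[p, p])$r, s2$r, tolerance = 1e-12)
  # mismatched ROI sets are refused
  C3 <- C1; rownames(C3)[1] <- "other"
  expect_error(similarity(C1, C3), "ROI sets differ")
})

test_that("consistency ICC matches the ANOVA table and Spearman-Brown", {
  # perfect consistency
  d <- cbind(1:6, 1:6)
  icc <- icc_consistency(d)
  expect_equal(icc$icc_c1, 1)
  expect_equal(icc$icc_ck, 1)

  # worked fixture vs an independent aov()-based oracle
  set.seed(21)
  d2 <- matrix(rnorm(12), 6, 2) + rowMeans(matrix(rnorm(12), 6, 2))
  icc2 <- icc_consistency(d2)
  long <- data.frame(y = as.numeric(d2),
                     item = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ item + rater, data = long))[[1]]
  msr <- ms["item", "Mean Sq"]; mse <- ms["Residuals", "Mean Sq"]
  k <- 2
  expect_equal(icc2$icc_c1, (msr - mse) / (msr + (k - 1) * mse),
               tolerance = 1e-10)
  expect_equal(icc2$icc_ck, (msr - mse) / msr, tolerance = 1e-10)

  # Spearman-Brown identity on every call
  for (kk in 2:4) {
    dk <- matrix(rnorm(8 * kk), 8) + rnorm(8)
    ic <- icc_consistency(dk)
    sb <- kk * ic$icc_c1 / (1 + (kk - 1) * ic$icc_c1)
    expect_equal(ic$icc_ck, sb, tolerance = 1e-12)
    if (ic$icc_c1 > 0) expect_gte(ic$icc_ck, ic$icc_c1)
  }

  # zero between-item variance is undefined
  flat <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_true(is.na(icc_consistency(flat)$icc_c1))
})

test_that("one-way ANOVA with Tukey-Kramer matches hand-computed sums of
           squares and handles unequal groups", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12))
  out <- anova_tukey(groups)
  # brute-force ANOVA table
  all_v <- unlist(groups); gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  Fref <- (ssb / 2) / (ssw / 6)
  expect_equal(out$F, Fref, tolerance = 1e-10)
  expect_equal(out$df, c(2, 6))
  expect_equal(out$p, stats::pf(Fref, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # Tukey p for a vs c against ptukey
  msw <- ssw / 6
  qac <- abs(mean(groups$c) - mean(groups$a)) /
    sqrt(msw / 2 * (1 / 3 + 1 / 3))
  pac <- stats::ptukey(qac, 3, 6, lower.tail = FALSE)
  row <- out$pairwise[out$pairwise$pair == "c-a", ]
  expect_equal(row$p_adj, pac, tolerance = 1e-10)
  expect_true(row$significant)

  # unequal sizes accepted
  out2 <- anova_tukey(list(x = rnorm(4), y = rnorm(7), z = rnorm(5)))
  expect_equal(out2$df, c(2, 13))
  # all-identical values degenerate gracefully
  flat <- anova_tukey(list(a = c(1, 1), b = c(1, 1)))
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)
})

test_that("split-half designs collapse correctly on duplicated runs and
           show no intra/inter gap on stationary data", {
  set.seed(22)
  R <- 6
  Sigma <- crossprod(matrix(rnorm(R * R), R)) / R + diag(R)
  mk <- function(Tn) matrix(rnorm(Tn * R), ncol = R) %*% chol(Sigma)
  # run2 an exact copy of run1: inter designs equal intra designs
  ts1 <- mk(400)
  res <- split_half_analysis(list(S1 = list(run1 = ts1, run2 = ts1)),
                             fs = 1, min_minutes = 0)
  pd <- res$per_design
  expect_equal(pd$r[pd$design == "inter_FH"],
               pd$r[pd$design == "intra_run1"] * 0 +
                 similarity(partial_correlation(ts1[1:200, ]),
                            partial_correlation(ts1[1:200, ]))$r)
  expect_equal(pd$r[pd$design == "inter_SH"], 1)
  # odd length: FH gets the extra sample
  ts_odd <- mk(401)
  res_odd <- split_half_analysis(list(S = list(run1 = ts_odd,
                                               run2 = ts_odd)),
                                 fs = 1, min_minutes = 0)
  expect_equal(nrow(res_odd$per_design), 4)

  # stationary subjects: intra and half-length inter match on average
  subs <- lapply(1:10, function(i) list(run1 = mk(600), run2 = mk(600)))
  names(subs) <- paste0("S", 1:10)
  out <- split_half_analysis(subs, fs = 1, min_minutes = 0)
  expect_lt(abs(out$t_test$mean_r_intra - out$t_test$mean_r_inter), 0.1)
  expect_gt(out$t_test$p, 0.05)
  # too-short halves excluded
  short <- list(SS = list(run1 = mk(40), run2 = mk(40)))
  expect_error(split_half_analysis(short, fs = 1, min_minutes = 2),
               "minimum length")
})

test_that("interrun_reproducibility couples similarity and ICC", {
  set.seed(23)
  R <- 6
  C1 <- partial_correlation(matrix(rnorm(200 * R), ncol = R))
  C2 <- partial_correlation(matrix(rnorm(200 * R), ncol = R))
  rep <- interrun_reproducibility(C1, C2)
  expect_equal(rep$r, similarity(C1, C2)$r)
  sb <- 2 * rep$icc_c1 / (1 + rep$icc_c1)
  expect_equal(rep$icc_ck, sb, tolerance = 1e-12)
  self <- interrun_reproducibility(C1, C1)
  expect_equal(self$icc_c1, 1)
})
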
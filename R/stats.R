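#' Fisher z-transformation
#'
#' `z = atanh(r)`, with inputs clipped to +/-(1 - 1e-7) so that perfect
#' correlations map to a large finite value rather than infinity.
#'
#' @param r correlation(s) in [-1, 1].
#' @param clip clipping margin.
#' @export
fisher_z <- function(r, clip = 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("|r| > 1 is not a correlation")
  }
  atanh(pmin(pmax(r, -1 + clip), 1 - clip))
}

# strict lower triangle of a connectivity matrix, Fisher-z transformed
z_lower <- function(C, clip = 1e-7) {
  fisher_z(C[lower.tri(C)], clip)
}

#' Similarity between two connectivity matrices
#'
#' The strict lower triangles are vectorized, Fisher-z transformed
#' entrywise, Pearson-correlated, and the resulting coefficient is itself
#' Fisher-z transformed. Both matrices must cover the same available-ROI
#' set in the same order.
#'
#' @param C1,C2 ROI x ROI connectivity matrices with matching dimnames.
#' @return list with `r`, `z` and `n_pairs`.
#' @export
similarity <- function(C1, C2) {
  if (!is.null(rownames(C1)) && !is.null(rownames(C2)) &&
      !identical(rownames(C1), rownames(C2))) {
    stop("ROI sets differ: ",
         paste(union(setdiff(rownames(C1), rownames(C2)),
                     setdiff(rownames(C2), rownames(C1))), collapse = ", "))
  }
  if (!all(dim(C1) == dim(C2))) stop("connectivity matrices differ in size")
  v1 <- z_lower(C1); v2 <- z_lower(C2)
  r <- stats::cor(v1, v2)
  list(r = r, z = fisher_z(r), n_pairs = length(v1))
}

#' Two-way consistency intraclass correlation
#'
#' ICC(C,1) and ICC(C,k) from the two-way mixed-model (consistency)
#' decomposition with items (ROI-pair connection values) as rows and
#' raters (runs or half-runs) as columns:
#' \deqn{ICC(C,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E}, \quad
#'       ICC(C,k) = \frac{MS_R - MS_E}{MS_R}}
#' The two measures are tied by the Spearman-Brown relation
#' \eqn{ICC(C,k) = k\,ICC(C,1) / (1 + (k-1)\,ICC(C,1))}.
#'
#' @param data n_items x k_raters numeric matrix.
#' @return list with `icc_c1`, `icc_ck`, `k`, `n` and the mean squares.
#'   With zero between-item variance both values are `NA` (undefined).
#' @export
icc_consistency <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  stopifnot(n >= 2, k >= 2)
  grand <- mean(data)
  SSR <- k * sum((rowMeans(data) - grand)^2)
  SSC <- n * sum((colMeans(data) - grand)^2)
  SST <- sum((data - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= 0) {
    return(list(icc_c1 = NA_real_, icc_ck = NA_real_, k = k, n = n,
                ms_rows = MSR, ms_error = MSE,
                note = "zero between-item variance; ICC undefined"))
  }
  list(icc_c1 = (MSR - MSE) / (MSR + (k - 1) * MSE),
       icc_ck = (MSR - MSE) / MSR,
       k = k, n = n, ms_rows = MSR, ms_error = MSE)
}

#' One-way ANOVA with Tukey-Kramer pairwise comparisons
#'
#' Omnibus F test across groups followed by all pairwise comparisons with
#' the studentized-range (Tukey-Kramer, unequal group sizes allowed)
#' correction, as used to compare algorithms on per-subject z-scores.
#'
#' @param groups named list of numeric vectors (>= 2 groups of >= 2
#'   values).
#' @param alpha significance level for flagging pairs.
#' @return list with `F`, `df`, `p`, and `pairwise` (data frame: pair,
#'   difference, confidence bounds, adjusted p, significance).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups)))
  if (stats::var(df$value) == 0) {
    return(list(F = 0, df = c(length(groups) - 1,
                              nrow(df) - length(groups)),
                p = 1, pairwise = NULL))
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairwise <- data.frame(pair = rownames(tk),
                         diff = tk[, "diff"], lwr = tk[, "lwr"],
                         upr = tk[, "upr"], p_adj = tk[, "p adj"],
                         significant = tk[, "p adj"] < alpha,
                         row.names = NULL)
  list(F = an[["F value"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]),
       p = an[["Pr(>F)"]][1],
       pairwise = pairwise)
}

#' Inter-run reproducibility of connectivity
#'
#' Fisher-z similarity between the two runs' matrices plus ICC(C,1) and
#' ICC(C,k) over the z-transformed connection values (items = ROI pairs,
#' raters = runs).
#'
#' @param C1,C2 connectivity matrices for run 1 and run 2.
#' @return list with `r`, `z`, `icc_c1`, `icc_ck`.
#' @export
interrun_reproducibility <- function(C1, C2) {
  sim <- similarity(C1, C2)
  icc <- icc_consistency(cbind(z_lower(C1), z_lower(C2)))
  list(r = sim$r, z = sim$z, icc_c1 = icc$icc_c1, icc_ck = icc$icc_ck)
}

#' Split-half reliability designs
#'
#' Each run's retained ROI time series is split at the midpoint (the
#' first half receives the extra sample when the length is odd) and
#' connectivity is computed per half. Four designs are evaluated:
#' `intra_run1` (run1-FH vs run1-SH), `intra_run2`, `inter_FH` (run1-FH
#' vs run2-FH) and `inter_SH` -- the last two form the "half-length
#' inter-run" reproducibility that is compared against the intra-run
#' designs by an unpaired two-sided t-test on the z-values (a null
#' difference indicates stationarity across the session).
#'
#' @param ts_by_subject list per subject of lists with elements `run1`
#'   and `run2`, each a time x ROI matrix of retained samples.
#' @param fs sampling rate of the series (Hz), used for the minimum-length
#'   rule.
#' @param min_minutes halves shorter than this are flagged and the
#'   subject excluded from group statistics (default 2 minutes).
#' @param shrinkage passed to [partial_correlation()].
#' @return list with `per_design` (tidy data frame: subject, design, r,
#'   z, icc_c1, icc_ck), `excluded` subjects, and `t_test` comparing
#'   intra vs half-length-inter z-values (`statistic`, `p`, means).
#' @export
split_half_analysis <- function(ts_by_subject, fs, min_minutes = 2,
                                shrinkage = NULL) {
  halves <- function(ts) {
    Tn <- nrow(ts)
    fh <- seq_len(ceiling(Tn / 2))
    list(FH = ts[fh, , drop = FALSE], SH = ts[-fh, , drop = FALSE])
  }
  min_len <- min_minutes * 60 * fs
  rows <- NULL
  excluded <- character(0)
  for (s in seq_along(ts_by_subject)) {
    subj <- names(ts_by_subject)[s] %||% as.character(s)
    h1 <- halves(ts_by_subject[[s]]$run1)
    h2 <- halves(ts_by_subject[[s]]$run2)
    if (min(vapply(c(h1, h2), nrow, 1L)) < min_len) {
      excluded <- c(excluded, subj)
      next
    }
    C <- lapply(list(r1FH = h1$FH, r1SH = h1$SH,
                     r2FH = h2$FH, r2SH = h2$SH),
                partial_correlation, shrinkage = shrinkage)
    designs <- list(intra_run1 = c("r1FH", "r1SH"),
                    intra_run2 = c("r2FH", "r2SH"),
                    inter_FH = c("r1FH", "r2FH"),
                    inter_SH = c("r1SH", "r2SH"))
    for (d in names(designs)) {
      rep <- interrun_reproducibility(C[[designs[[d]][1]]],
                                      C[[designs[[d]][2]]])
      rows <- rbind(rows, data.frame(
        subject = subj, design = d, r = rep$r, z = rep$z,
        icc_c1 = rep$icc_c1, icc_ck = rep$icc_ck,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) stop("no subject had halves above the minimum length")
  intra <- rows$z[startsWith(rows$design, "intra")]
  inter <- rows$z[startsWith(rows$design, "inter")]
  tt <- tryCatch(stats::t.test(intra, inter, var.equal = TRUE),
                 error = function(e) {
                   # degenerate case: identical runs leave no variance
                   list(statistic = 0, p.value = 1)
                 })
  list(per_design = rows, excluded = excluded,
       t_test = list(statistic = unname(tt$statistic), p = tt$p.value,
                     mean_intra = mean(intra), mean_inter = mean(inter),
                     mean_r_intra = mean(rows$r[startsWith(rows$design, "intra")]),
                     mean_r_inter = mean(rows$r[startsWith(rows$design, "inter")])))
}
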
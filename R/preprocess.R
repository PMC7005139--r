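#' Multichannel three-wavelength fNIRS container
#'
#' @param data list of time x channel matrices, one per wavelength, or a
#'   3-d array (time x channel x wavelength).
#' @param fs sampling rate in Hz.
#' @param channels channel metadata data frame (as in a
#'   [probe_layout()]`$channels`), with at least a `class` column
#'   (short/long).
#' @param wavelengths wavelengths in nm.
#' @param units `"V"` (raw voltages) or `"OD"` (optical density); the two
#'   are never mixed in one container.
#' @return object of class `channel_ts`.
#' @export
channel_timeseries <- function(data, fs = 18.5, channels = NULL,
                               wavelengths = c(780, 805, 830),
                               units = "V") {
  if (is.array(data) && length(dim(data)) == 3) {
    data <- lapply(seq_len(dim(data)[3]), function(w) data[, , w])
  }
  stopifnot(is.list(data), length(data) == length(wavelengths), fs > 0)
  nch <- unique(vapply(data, ncol, 1L))
  nt <- unique(vapply(data, nrow, 1L))
  if (length(nch) != 1 || length(nt) != 1) {
    stop("all wavelengths must share the same time x channel shape")
  }
  if (!is.null(channels) && nrow(channels) != nch) {
    stop("channel metadata does not match data width")
  }
  names(data) <- as.character(wavelengths)
  structure(
    list(data = data, fs = fs, channels = channels,
         wavelengths = wavelengths, units = units,
         bad_channels = NULL, retained = NULL),
    class = "channel_ts"
  )
}

#' @export
print.channel_ts <- function(x, ...) {
  cat(sprintf("<channel_ts> %d samples x %d channels x %d wavelengths [%s] @ %.2f Hz\n",
              nrow(x$data[[1]]), ncol(x$data[[1]]), length(x$data),
              x$units, x$fs))
  invisible(x)
}

# population SD (the CV derivation uses sigma = sqrt(mean((x - mu)^2)))
popsd <- function(x) sqrt(mean((x - mean(x))^2))

#' Convert voltages to optical density
#'
#' Log-ratio conversion `od(t) = -log10(V(t) / Vbar)` with `Vbar` the
#' per-channel temporal mean, so each OD trace fluctuates around zero.
#' Channels with any non-positive voltage cannot be transformed and are
#' flagged invalid (their OD is set to `NA`) rather than silently
#' converted.
#'
#' @param x a `channel_ts` in volts, or a plain time x channel matrix.
#' @return same type as the input, in OD; invalid channels are recorded in
#'   `bad_channels` (container) or in the `invalid` attribute (matrix).
#' @export
to_optical_density <- function(x) {
  od1 <- function(V) {
    invalid <- apply(V <= 0, 2, any)
    od <- -log10(sweep(V, 2, colMeans(V), "/"))
    od[, invalid] <- NA_real_
    attr(od, "invalid") <- invalid
    od
  }
  if (is.matrix(x)) return(od1(x))
  stopifnot(inherits(x, "channel_ts"))
  if (x$units != "V") stop("container is already in ", x$units)
  ods <- lapply(x$data, od1)
  invalid <- Reduce(`|`, lapply(ods, attr, "invalid"))
  x$data <- lapply(ods, function(m) { attr(m, "invalid") <- NULL; m })
  x$units <- "OD"
  x$invalid_channels <- which(invalid)
  x
}

#' Coefficient of variation per channel
#'
#' `CV = 100 * sigma / mu` in percent, computed on the raw voltages
#' (before any filtering), per channel and wavelength. A zero mean yields
#' an infinite CV, which marks the channel for rejection.
#'
#' @param x a `channel_ts` in volts, or a time x channel matrix.
#' @return channels x wavelengths matrix (or a vector for a matrix input).
#' @export
channel_cv <- function(x) {
  cv1 <- function(V) {
    mu <- colMeans(V)
    sd <- apply(V, 2, popsd)
    ifelse(mu == 0, Inf, 100 * sd / abs(mu))
  }
  if (is.matrix(x)) return(cv1(x))
  stopifnot(inherits(x, "channel_ts"))
  if (x$units != "V") {
    stop("channel CV is defined on raw voltages, not ", x$units)
  }
  sapply(x$data, cv1)
}

#' Detect saturated channels
#'
#' A channel is saturated when its voltage sits at the ADC ceiling for at
#' least `frac` of the samples (at any wavelength).
#'
#' @param x a `channel_ts` in volts, or a time x channel matrix.
#' @param ceiling ADC ceiling voltage.
#' @param frac minimum fraction of ceiling samples.
#' @return logical vector per channel.
#' @export
detect_saturation <- function(x, ceiling = 5, frac = 0.01) {
  sat1 <- function(V) colMeans(V >= ceiling * (1 - 1e-9)) >= frac
  if (is.matrix(x)) return(sat1(x))
  stopifnot(inherits(x, "channel_ts"))
  Reduce(`|`, lapply(x$data, sat1))
}

#' Reject bad channels
#'
#' A channel is rejected iff its CV strictly exceeds the threshold at one
#' or more wavelengths, or it is saturated. A CV of exactly the threshold
#' is retained.
#'
#' @param cv channels x wavelengths CV matrix from [channel_cv()].
#' @param saturated optional logical vector from [detect_saturation()].
#' @param threshold CV threshold in percent (default 15).
#' @return logical vector: `TRUE` = bad.
#' @export
reject_bad_channels <- function(cv, saturated = NULL, threshold = 15) {
  cv <- as.matrix(cv)
  bad <- apply(cv > threshold | !is.finite(cv), 1, any)
  if (!is.null(saturated)) bad <- bad | saturated
  if (all(bad)) {
    stop("all channels rejected (CV > ", threshold,
         "% or saturated); check acquisition quality")
  }
  unname(bad)
}

#' Regress the global short-channel mean out of every channel
#'
#' The global average of the good short (13-mm) channels is taken as the
#' scalp hemodynamics and removed from each channel by least squares
#' (intercept + slope), leaving residuals orthogonal to the regressor.
#' This step belongs to the minimum-norm branch only; the hierarchical
#' Bayesian solver receives unregressed data and models the scalp
#' explicitly.
#'
#' @param X time x channel matrix (filtered OD).
#' @param short_mask logical per channel: short (13-mm) channel.
#' @param bad_mask logical per channel: bad channel (excluded from the
#'   global mean).
#' @return matrix of residuals, same shape; the regressor is attached as
#'   attribute `"regressor"`.
#' @export
regress_scalp_global <- function(X, short_mask,
                                 bad_mask = rep(FALSE, ncol(X))) {
  use <- short_mask & !bad_mask
  if (!any(use)) stop("no good short channels to form the scalp regressor")
  g <- rowMeans(X[, use, drop = FALSE])
  gc <- g - mean(g)
  # a regressor with (numerically) no variance relative to the data adds
  # nothing and only amplifies round-off; applies in particular when the
  # regression is applied twice
  if (sum(gc^2) <= 1e-20 * max(colSums(sweep(X, 2, colMeans(X))^2), 1e-300)) {
    warning("scalp regressor has zero variance; series returned unchanged")
    attr(X, "regressor") <- g
    return(X)
  }
  beta <- crossprod(gc, X) / sum(gc^2)
  out <- X - outer(gc, as.numeric(beta))
  out <- sweep(out, 2, colMeans(out), "-")
  attr(out, "regressor") <- g
  out
}

#' Flag and remove motion-contaminated time points
#'
#' A time point is dropped when its absolute deviation from the channel
#' mean exceeds `k` standard deviations in at least one good short
#' channel; the same index set is removed from every channel so all
#' series stay aligned. Channels with zero variance never trigger
#' removal.
#'
#' @param X time x channel matrix (filtered).
#' @param short_mask,bad_mask logical per channel.
#' @param k threshold in SD units (default 3).
#' @return list with `retained` and `removed` sample indices.
#' @export
remove_bad_timepoints <- function(X, short_mask,
                                  bad_mask = rep(FALSE, ncol(X)), k = 3) {
  use <- which(short_mask & !bad_mask)
  if (!length(use)) stop("no good short channels for time-point screening")
  bad_t <- rep(FALSE, nrow(X))
  for (c in use) {
    v <- X[, c]
    s <- popsd(v)
    if (s > 0) bad_t <- bad_t | (abs(v - mean(v)) > k * s)
  }
  if (all(bad_t)) stop("all time points flagged as bad")
  if (mean(bad_t) > 0.5) {
    warning(sprintf("%.0f%% of time points removed", 100 * mean(bad_t)))
  }
  list(retained = which(!bad_t), removed = which(bad_t))
}

#' Preprocessing configuration
#'
#' Defaults follow the standard resting-state fNIRS settings: CV rejection
#' above 15%, Butterworth high-pass of order 3 at 0.009 Hz, low-pass of
#' order 7 at 0.08 Hz, and a 3-SD motion criterion on the short channels.
#'
#' @param cv_threshold CV rejection threshold in percent.
#' @param hp_order,hp_cutoff high-pass order and cutoff (Hz).
#' @param lp_order,lp_cutoff low-pass order and cutoff (Hz).
#' @param spike_sd motion threshold in SD units.
#' @param scalp_regression regress out the global short-channel mean
#'   (minimum-norm branch only).
#' @param sat_ceiling,sat_frac saturation criterion (ceiling voltage and
#'   minimum fraction of ceiling samples).
#' @param filter_mode `"zero_phase"` (default) or `"single_pass"`.
#' @export
preprocess_config <- function(cv_threshold = 15,
                              hp_order = 3, hp_cutoff = 0.009,
                              lp_order = 7, lp_cutoff = 0.08,
                              spike_sd = 3, scalp_regression = FALSE,
                              sat_ceiling = 5, sat_frac = 0.01,
                              filter_mode = "zero_phase") {
  stopifnot(hp_order >= 1, lp_order >= 1, cv_threshold > 0, spike_sd > 0)
  list(cv_threshold = cv_threshold,
       hp_order = hp_order, hp_cutoff = hp_cutoff,
       lp_order = lp_order, lp_cutoff = lp_cutoff,
       spike_sd = spike_sd, scalp_regression = scalp_regression,
       sat_ceiling = sat_ceiling, sat_frac = sat_frac,
       filter_mode = filter_mode)
}

#' Run the full preprocessing chain on one recording
#'
#' Applies, in order: (1) voltage to optical density, (2) CV and
#' saturation channel rejection on the raw voltages, (3) band-pass
#' filtering, (4) optional global short-channel scalp regression, and
#' (5) 3-SD time-point removal screened on the good short channels (the
#' union over wavelengths, so every wavelength keeps the same samples).
#'
#' @param cts a `channel_ts` in volts.
#' @param config a [preprocess_config()].
#' @return object of class `preprocessed_run`: list with `od` (list per
#'   wavelength of retained-time x good-channel matrices), `good`/`bad`
#'   channel indices, `short` mask over the good channels, `retained`
#'   sample indices, `fs`, `channels` metadata and the `config` used.
#' @export
preprocess_run <- function(cts, config = preprocess_config()) {
  stopifnot(inherits(cts, "channel_ts"), cts$units == "V")
  cv <- channel_cv(cts)
  sat <- detect_saturation(cts, config$sat_ceiling, config$sat_frac)
  od <- to_optical_density(cts)
  invalid <- rep(FALSE, ncol(cts$data[[1]]))
  invalid[od$invalid_channels] <- TRUE
  bad <- reject_bad_channels(cv, sat | invalid, config$cv_threshold)

  short <- cts$channels$class == "short"
  good <- which(!bad)
  filt <- lapply(od$data, function(M) {
    bandpass(M[, good, drop = FALSE], cts$fs, config, config$filter_mode)
  })
  if (config$scalp_regression) {
    filt <- lapply(filt, regress_scalp_global, short_mask = short[good])
    filt <- lapply(filt, function(m) { attr(m, "regressor") <- NULL; m })
  }
  bad_t <- rep(FALSE, nrow(filt[[1]]))
  for (w in seq_along(filt)) {
    r <- remove_bad_timepoints(filt[[w]], short[good], k = config$spike_sd)
    flag <- rep(TRUE, length(bad_t)); flag[r$retained] <- FALSE
    bad_t <- bad_t | flag
  }
  retained <- which(!bad_t)
  out_od <- lapply(filt, function(m) m[retained, , drop = FALSE])

  structure(
    list(od = out_od, fs = cts$fs, wavelengths = cts$wavelengths,
         channels = cts$channels[good, , drop = FALSE],
         good = good, bad = which(bad), cv = cv, saturated = which(sat),
         short = short[good], retained = retained,
         n_removed = sum(bad_t), config = config,
         scalp_regressed = config$scalp_regression),
    class = "preprocessed_run"
  )
}

#' @export
print.preprocessed_run <- function(x, ...) {
  cat(sprintf(
    "<preprocessed_run> %d retained samples x %d good channels (%d bad, %d samples removed)%s\n",
    length(x$retained), length(x$good), length(x$bad), x$n_removed,
    if (x$scalp_regressed) ", scalp-regressed" else ""))
  invisible(x)
}

#' Decimate a preprocessed run
#'
#' Keeps every `factor`-th retained sample. The hemodynamic band ends at
#' 0.08 Hz, far below the decimated Nyquist frequency for any moderate
#' factor, so connectivity estimates are unaffected while the inverse
#' solvers scale down by the same factor.
#'
#' @param pre a `preprocessed_run`.
#' @param factor positive integer subsampling factor.
#' @export
decimate_run <- function(pre, factor) {
  stopifnot(inherits(pre, "preprocessed_run"), factor >= 1)
  if (factor == 1) return(pre)
  idx <- seq(1, nrow(pre$od[[1]]), by = factor)
  pre$od <- lapply(pre$od, function(m) m[idx, , drop = FALSE])
  pre$retained <- pre$retained[idx]
  pre$fs <- pre$fs / factor
  pre$decimation <- factor
  pre
}
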
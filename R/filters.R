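# Butterworth design in second-order sections (biquad cascade).
#
# The band of interest sits two decades below the Nyquist frequency, so
# the filter poles crowd the unit circle; expanded transfer-function
# polynomials lose precision there, while a cascade of first/second-order
# sections keeps each recursion well conditioned. Analog Butterworth
# prototype poles are prewarped and mapped by the bilinear transform,
# conjugate pairs combined into biquads, and each section normalized to
# unit passband gain (DC for low-pass, Nyquist for high-pass).
butter_sos <- function(order, cutoff, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, cutoff > 0, cutoff < fs / 2)
  wc <- 2 * fs * tan(pi * cutoff / fs)         # prewarped analog cutoff
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit prototype
  s <- if (type == "low") wc * p else wc / p   # analog poles
  bil <- function(sp) (2 * fs + sp) / (2 * fs - sp)

  sections <- list()
  used <- rep(FALSE, order)
  for (i in seq_len(order)) {
    if (used[i]) next
    j <- which(!used & abs(s - Conj(s[i])) < 1e-9 * abs(s[i]) &
                 seq_len(order) != i)
    if (Im(s[i]) != 0 && length(j)) {          # conjugate pair -> biquad
      used[c(i, j[1])] <- TRUE
      zp <- bil(s[i])
      a <- c(1, -2 * Re(zp), Mod(zp)^2)
      b <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
    } else {                                   # real pole -> first order
      used[i] <- TRUE
      zp <- Re(bil(s[i]))
      a <- c(1, -zp)
      b <- if (type == "low") c(1, 1) else c(1, -1)
    }
    zref <- if (type == "low") 1 else -1       # passband reference
    gain <- sum(a * zref^-(seq_along(a) - 1)) /
      sum(b * zref^-(seq_along(b) - 1))
    sections[[length(sections) + 1]] <- list(b = Re(b * gain), a = Re(a))
  }
  sections
}

# run a biquad cascade over a vector (direct-form recursion per section)
sos_filter <- function(sections, x) {
  for (s in sections) {
    x <- as.numeric(signal::filter(s$b, s$a, x))
  }
  x
}

# forward-backward pass with odd-reflection padding (zero phase)
sos_filtfilt <- function(sections, x) {
  n <- length(x)
  np <- min(n - 1, 9 * length(sections))
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- sos_filter(sections, c(pre, x, post))
  y <- rev(sos_filter(sections, rev(y)))
  y[(np + 1):(np + n)]
}

#' Band-pass filter channel time series
#'
#' Cascade of the high-pass (Butterworth order 3, cutoff 0.009 Hz) and
#' low-pass (order 7, cutoff 0.08 Hz) filters that isolate the
#' low-frequency hemodynamic band, implemented in second-order sections
#' for numerical stability at these deep cutoffs. `zero_phase` (default)
#' applies each stage forward and backward, which doubles the magnitude
#' attenuation but leaves no phase distortion -- the appropriate choice
#' before computing temporal correlations. `single_pass` applies each
#' stage once, so the single-stage magnitude follows the analytic
#' Butterworth response \eqn{|H(f)| = (1 + (f/f_c)^{2n})^{-1/2}} (and its
#' high-pass mirror).
#'
#' @param x numeric vector, or matrix with time in rows.
#' @param fs sampling rate in Hz.
#' @param config a [preprocess_config()] (orders/cutoffs are taken from it).
#' @param mode `"zero_phase"` or `"single_pass"`.
#' @return filtered data, same shape as `x`.
#' @export
bandpass <- function(x, fs = 18.5, config = preprocess_config(),
                     mode = c("zero_phase", "single_pass")) {
  mode <- match.arg(mode)
  if (config$hp_cutoff >= fs / 2 || config$lp_cutoff >= fs / 2) {
    stop("filter cutoffs must lie below the Nyquist frequency")
  }
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  minlen <- 3 * (max(config$hp_order, config$lp_order) + 1)
  if (nrow(X) <= minlen) {
    stop("series too short for stable filtering (need > ", minlen,
         " samples)")
  }
  hp <- butter_sos(config$hp_order, config$hp_cutoff, fs, "high")
  lp <- butter_sos(config$lp_order, config$lp_cutoff, fs, "low")
  apply1 <- function(v) {
    if (mode == "zero_phase") {
      sos_filtfilt(lp, sos_filtfilt(hp, v))
    } else {
      sos_filter(lp, sos_filter(hp, v))
    }
  }
  out <- apply(X, 2, apply1)
  if (vec) as.numeric(out) else {
    dimnames(out) <- dimnames(X)
    out
  }
}
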
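#' Specification of a synthetic resting-state study
#'
#' Defines the generating conditions of a simulated high-density fNIRS
#' study: number of subjects and runs, run length and sampling rate,
#' montage size, the cortical band, the target ROI connectivity, the
#' scalp-interference mixture and the artifact load. Defaults mirror a
#' realistic resting-state protocol: two 10-minute runs per subject
#' sampled at 18.5 Hz, 19 available ROIs, band-limited (0.009-0.08 Hz)
#' cortical signals, and scalp interference 1.5x the cortical amplitude
#' split between a global systemic component and a spatially smooth
#' inhomogeneous field -- the regime in which global short-channel
#' regression is expected to underperform an explicit scalp model.
#'
#' @param n_subjects subjects (default 20).
#' @param n_runs runs per subject (default 2).
#' @param duration run length in seconds (default 600).
#' @param fs sampling rate in Hz (default 18.5).
#' @param n_arrays optode arrays in the montage (default 2).
#' @param n_rois target available-ROI count (default 19).
#' @param band cortical band in Hz.
#' @param sparsity fraction of ROI pairs with a direct (precision)
#'   coupling.
#' @param strength coupling strength scale (kept diagonally dominant).
#' @param voxel_snr cortical voxel SNR: ROI latent SD over voxel-noise SD.
#' @param channel_snr long-channel SNR: in-band clean OD SD over in-band
#'   measurement-noise SD (`Inf` disables noise).
#' @param od_scale calibrated SD of the clean long-channel OD signal
#'   (base-10 OD units).
#' @param deoxy_ratio deoxy-Hb amplitude relative to oxy-Hb (negatively
#'   coupled).
#' @param scalp list: `factor` (scalp SD over cortical SD), `global_frac`
#'   (fraction of scalp variance that is globally homogeneous), `freqs`
#'   and systemic sinusoid weights `amps`, `corr_length` (mm) and
#'   `n_kernels` of the inhomogeneous smooth field, `cardiac` frequency
#'   (Hz) and `cardiac_amp`.
#' @param artifacts list: `n_bad` drifting channels (CV forced above the
#'   rejection threshold), `n_saturated`, motion `spike_rate` (events/s),
#'   `spike_width` (s), `spike_amp` range (multiples of the signal SD).
#' @param seed master seed.
#' @return object of class `truth_spec`.
#' @export
truth_spec <- function(n_subjects = 20, n_runs = 2, duration = 600,
                       fs = 18.5, n_arrays = 2, n_rois = 19,
                       band = c(0.009, 0.08),
                       sparsity = 0.25, strength = 0.5,
                       voxel_snr = 2, channel_snr = 5, od_scale = 0.005,
                       deoxy_ratio = 0.4,
                       scalp = list(), artifacts = list(), seed = 1) {
  scalp_def <- list(factor = 1.5, global_frac = 0.5,
                    freqs = c(0.01, 0.04, 0.1), amps = c(1, 1, 0.5),
                    corr_length = 40, n_kernels = 12,
                    cardiac = 1.1, cardiac_amp = 0.3)
  art_def <- list(n_bad = 3, n_saturated = 1, spike_rate = 0.05,
                  spike_width = 0.15, spike_amp = c(5, 10))
  scalp <- utils::modifyList(scalp_def, scalp)
  artifacts <- utils::modifyList(art_def, artifacts)
  stopifnot(fs > 2 * band[2], n_rois >= 3, duration > 0)
  structure(
    list(n_subjects = n_subjects, n_runs = n_runs, duration = duration,
         fs = fs, n_arrays = n_arrays, n_rois = n_rois, band = band,
         sparsity = sparsity, strength = strength,
         voxel_snr = voxel_snr, channel_snr = channel_snr,
         od_scale = od_scale, deoxy_ratio = deoxy_ratio,
         scalp = scalp, artifacts = artifacts, seed = seed),
    class = "truth_spec"
  )
}

#' Random sparse SPD precision matrix and its partial correlations
#'
#' Draws a sparse symmetric precision matrix with unit diagonal and
#' off-diagonal couplings on a random edge set, rescaled to diagonal
#' dominance (hence SPD); redraws with an incremented sub-seed in the
#' unlikely event of numerical non-SPD-ness. The partial-correlation
#' matrix is \eqn{pc_{ij} = -P_{ij} / \sqrt{P_{ii} P_{jj}}}.
#'
#' When ROI center `distances` are supplied the edge set is spatially
#' organized the way resting-state connectivity is in practice:
#' neighbouring regions couple positively (in group-mean connectivity
#' maps most adjacent-ROI pairs correlate positively), and the remaining
#' couplings are long-range with mixed sign. Without distances the edge
#' set is uniformly random.
#'
#' @param R number of ROIs (>= 3).
#' @param sparsity fraction of pairs carrying a direct coupling.
#' @param strength coupling scale.
#' @param seed RNG seed.
#' @param distances optional R x R matrix of ROI center distances (mm).
#' @param adjacency_mm pairs closer than this couple positively.
#' @return list with `precision`, `pc` (partial correlations, unit
#'   diagonal), `sigma` (implied covariance).
#' @export
make_truth_connectivity <- function(R, sparsity = 0.25, strength = 0.5,
                                    seed = 1, distances = NULL,
                                    adjacency_mm = 20) {
  stopifnot(R >= 3, sparsity > 0, sparsity <= 1)
  attempt <- 0
  repeat {
    set.seed(seed + attempt)
    npairs <- R * (R - 1) / 2
    m <- max(1, round(sparsity * npairs))
    P <- matrix(0, R, R)
    lt <- which(lower.tri(P))
    if (!is.null(distances)) {
      adj <- lt[distances[lower.tri(distances)] <= adjacency_mm]
      far <- setdiff(lt, adj)
      n_far <- max(0, m - length(adj))
      edges <- c(adj, sample(far, min(n_far, length(far))))
      sgn <- c(rep(1, length(adj)),
               sample(c(-1, 1), length(edges) - length(adj),
                      replace = TRUE, prob = c(0.4, 0.6)))
    } else {
      edges <- sample(lt, m)
      sgn <- sample(c(-1, 1), m, replace = TRUE, prob = c(0.3, 0.7))
    }
    # pc_ij = -P_ij / sqrt(P_ii P_jj): a positive partial correlation
    # needs a negative precision entry
    vals <- -strength * stats::runif(length(edges), 0.5, 1) * sgn
    P[edges] <- vals
    P <- P + t(P)
    # enforce diagonal dominance (row sums of |off-diagonal| < 1)
    sc <- max(1, max(rowSums(abs(P))) / 0.95)
    P <- P / sc
    diag(P) <- 1
    if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) > 1e-8) {
      break
    }
    attempt <- attempt + 1
    message("non-SPD precision; redrawing with sub-seed ", seed + attempt)
  }
  d <- sqrt(diag(P))
  pc <- -P / tcrossprod(d)
  diag(pc) <- 1
  list(precision = P, pc = pc, sigma = solve(P))
}

# unit-variance Fourier basis of the in-band frequencies of a run:
# rows are sqrt(2)*cos / sqrt(2)*sin at the discrete frequencies k/T*fs
# inside `band` -- an exactly band-limited, low-rank noise model.
fourier_band_basis <- function(Tn, fs, band) {
  k <- seq_len(floor((Tn - 1) / 2))
  f <- k * fs / Tn
  k <- k[f >= band[1] & f <= band[2]]
  if (!length(k)) stop("run too short to contain in-band frequencies")
  t <- seq_len(Tn) - 1
  ang <- outer(2 * pi * k / Tn, t)
  rbind(sqrt(2) * cos(ang), sqrt(2) * sin(ang))
}

# band-limited unit-variance noise, Tn x n (AR(1) innovations shaped by
# the standard band-pass cascade)
band_noise <- function(Tn, fs, band, n, ar = 0.97) {
  z <- matrix(stats::rnorm(Tn * n), Tn, n)
  z <- apply(z, 2, function(v) stats::filter(v, ar, method = "recursive"))
  cfg <- preprocess_config(hp_cutoff = band[1], lp_cutoff = band[2])
  z <- bandpass(z, fs, cfg, mode = "zero_phase")
  sweep(z, 2, pmax(apply(z, 2, popsd), 1e-12), "/")
}

#' Precompute the shared geometry of a synthetic study
#'
#' Builds the montage, reconstruction grid, sensitivity matrix,
#' extinction table, sensitive-voxel mask and synthetic parcellation
#' shared by all subjects of a study, plus the projection operators the
#' per-run generator needs.
#'
#' @param spec a [truth_spec()].
#' @return list used by [simulate_subject()] / [simulate_study()].
#' @export
prepare_study_geometry <- function(spec) {
  layout <- probe_layout(default_layout_config(n_arrays = spec$n_arrays))
  grid <- build_voxel_grid(layout)
  sm <- build_sensitivity(layout, grid)
  E <- extinction_matrix()
  nsens <- normalized_sensitivity(sm, "cortex")
  mask <- sensitive_mask(nsens, 0.5)
  parc <- make_parcellation(grid, mask, n_rois = spec$n_rois,
                            seed = spec$seed)
  rois <- available_rois(parc, mask)
  if (length(rois) < spec$n_rois) {
    stop("only ", length(rois), " available ROIs for ", spec$n_rois,
         " requested; enlarge the montage")
  }
  cortex <- which(grid$compartment == "cortex")
  scalpv <- which(grid$compartment == "scalp")
  # ROI membership operator (voxels x R)
  Mc <- matrix(0, grid$n, spec$n_rois)
  for (r in seq_len(spec$n_rois)) Mc[parc$labels == r, r] <- 1
  glob <- as.numeric(grid$compartment == "scalp")

  list(layout = layout, grid = grid, sm = sm, E = E,
       nsens = nsens, mask = mask, parcellation = parc, rois = rois,
       cortex = cortex, scalp = scalpv,
       Mc = Mc, glob = glob,
       SMc = sm$S %*% Mc,
       Sglob = sm$S %*% glob)
}

# run-specific smooth inhomogeneous scalp field: Gaussian kernels at
# random centers on the scalp sheet (the spatial pattern of systemic
# interference is not assumed stable across runs)
scalp_field_projector <- function(spec, geom) {
  pos <- geom$grid$centers[geom$scalp, , drop = FALSE]
  K <- spec$scalp$n_kernels
  cen <- cbind(stats::runif(K, min(pos[, 1]), max(pos[, 1])),
               stats::runif(K, min(pos[, 2]), max(pos[, 2])))
  sigk <- spec$scalp$corr_length / 2
  Phi <- matrix(0, geom$grid$n, K)
  Phi[geom$scalp, ] <- exp(-(outer(pos[, 1], cen[, 1], "-")^2 +
                               outer(pos[, 2], cen[, 2], "-")^2) /
                             (2 * sigk^2))
  Phi
}

# draw correlated ROI latents with population covariance `sigma`,
# band-limited, unit marginal SD
roi_latents <- function(R, Tn, fs, band, sigma) {
  Z <- t(band_noise(Tn, fs, band, R))       # R x T, unit variance, indep
  lat <- t(chol(sigma)) %*% Z
  sweep(lat, 1, sqrt(diag(sigma)), "/")     # unit marginal SD
}

#' Simulate one subject of a synthetic study
#'
#' Generates `spec$n_runs` recordings for one subject. Each run contains:
#' ROI-level cortical latents with the study's target partial-correlation
#' structure (band-limited Gaussian processes); cortical voxel series =
#' ROI latent + voxel noise; scalp series = global systemic sinusoids +
#' a spatially smooth inhomogeneous field + cardiac tone; channel optical
#' densities through the Rytov forward operator and the extinction
#' matrix, plus white and 1/f measurement noise; and injected artifacts
#' (drifting bad channels, a saturated channel, motion spikes). A
#' noiseless "reference modality" (ROI latents + small independent
#' noise) is exported separately, standing in for a reference scan of
#' the same connectivity.
#'
#' @param spec a [truth_spec()].
#' @param geom from [prepare_study_geometry()].
#' @param truth from [make_truth_connectivity()].
#' @param subject subject index.
#' @param seed subject seed (derived from the master seed by default).
#' @return list of runs; each run has `cts` (a `channel_ts` of voltages),
#'   `latents_oxy`/`latents_deoxy` (calibrated R x T concentration
#'   latents), `reference` (time x ROI), and the run `seed`.
#' @export
simulate_subject <- function(spec, geom, truth, subject,
                             seed = spec$seed * 10000 + subject * 100) {
  runs <- vector("list", spec$n_runs)
  for (run in seq_len(spec$n_runs)) {
    runs[[run]] <- simulate_run(spec, geom, truth, seed + run)
  }
  names(runs) <- paste0("run", seq_len(spec$n_runs))
  runs
}

simulate_run <- function(spec, geom, truth, seed) {
  set.seed(seed)
  Tn <- round(spec$duration * spec$fs)
  fs <- spec$fs
  R <- spec$n_rois
  N <- nrow(geom$sm$S)
  ch <- geom$layout$channels
  t_sec <- (seq_len(Tn) - 1) / fs

  # --- cortical ROI latents (unit SD, target covariance) ---
  lat_o <- roi_latents(R, Tn, fs, spec$band, truth$sigma)
  lat_ind <- roi_latents(R, Tn, fs, spec$band, truth$sigma)
  dr <- spec$deoxy_ratio
  lat_d <- -dr * (0.55 * lat_o + 0.45 * lat_ind) /
    sqrt(0.55^2 + 0.45^2)  # anticorrelated, same connectivity

  # --- scalp components (unit-SD building blocks) ---
  sc <- spec$scalp
  amp_tot <- sc$factor
  a_glob <- amp_tot * sqrt(sc$global_frac)
  a_field <- amp_tot * sqrt(1 - sc$global_frac)
  w <- sc$amps / sqrt(sum(sc$amps^2) / 2)  # sinusoid mixture, unit SD
  mk_glob <- function() {
    ph <- stats::runif(length(sc$freqs), 0, 2 * pi)
    g <- colSums(w * sin(outer(2 * pi * sc$freqs, t_sec) + ph))
    g + sc$cardiac_amp * sin(2 * pi * sc$cardiac * t_sec +
                               stats::runif(1, 0, 2 * pi))
  }
  g_o <- mk_glob(); g_d <- mk_glob()
  Phi <- scalp_field_projector(spec, geom)
  SPhi <- geom$sm$S %*% Phi
  K <- ncol(Phi)
  F_o <- t(band_noise(Tn, fs, spec$band, K))   # K x T
  F_d <- t(band_noise(Tn, fs, spec$band, K))

  # --- cortical voxel noise, exactly band-limited and low rank ---
  Fb <- fourier_band_basis(Tn, fs, spec$band)  # 2F x T
  nb <- nrow(Fb)
  vnoise_proj <- function() {
    if (!is.finite(spec$voxel_snr)) return(matrix(0, N, Tn))
    Coef <- matrix(stats::rnorm(length(geom$cortex) * nb), ncol = nb) /
      sqrt(nb)
    (geom$sm$S[, geom$cortex, drop = FALSE] %*% Coef) %*% Fb /
      spec$voxel_snr
  }

  # --- clean channel concentrations (N x T), oxy and deoxy ---
  # cortical and scalp contributions are calibrated at the channel
  # level: on the long (29-mm) channels the cortical signal has SD
  # `od_scale` (in OD units at the reference wavelength) and the scalp
  # interference `scalp$factor` times that -- the regime reported for
  # superficial contamination of real recordings
  long <- ch$class == "long"
  E <- geom$E$E
  ch_sd <- function(m) {
    stats::median(apply((E[2, "oxy"] * m)[long, , drop = FALSE], 1,
                        popsd))
  }
  cx_o <- geom$SMc %*% lat_o + vnoise_proj()
  cx_d <- geom$SMc %*% lat_d + dr * vnoise_proj()
  sp_o <- as.numeric(geom$Sglob) %o% (a_glob * g_o) +
    SPhi %*% (a_field * F_o)
  sp_d <- -dr * (as.numeric(geom$Sglob) %o% (a_glob * g_d) +
                   SPhi %*% (a_field * F_d))
  cal_cx <- spec$od_scale / ch_sd(cx_o)
  cal_sp <- if (sc$factor > 0 && ch_sd(sp_o) > 0) {
    sc$factor * spec$od_scale / ch_sd(sp_o)
  } else 0
  ch_o <- cal_cx * cx_o + cal_sp * sp_o
  ch_d <- cal_cx * cx_d + cal_sp * sp_d
  cal <- cal_cx

  od <- lapply(seq_len(nrow(E)), function(wl) {
    E[wl, "oxy"] * ch_o + E[wl, "deoxy"] * ch_d
  })

  # --- measurement noise: white + 1/f ---
  if (is.finite(spec$channel_snr)) {
    band_frac <- (spec$band[2] - spec$band[1]) / (fs / 2)
    sd_w <- spec$od_scale / spec$channel_snr / sqrt(band_frac)
    kp <- seq_len(floor(Tn / 2))
    fp <- kp * fs / Tn
    kp <- kp[fp >= 0.002 & fp <= 1]
    ang <- outer(2 * pi * kp / Tn, seq_len(Tn) - 1)
    pink_basis <- rbind(cos(ang), sin(ang)) / sqrt(rep(kp, 2))
    pink_basis <- pink_basis / sqrt(sum(1 / kp))
    od <- lapply(od, function(m) {
      pink <- (matrix(stats::rnorm(N * 2 * length(kp)), N) %*%
                 pink_basis) * (0.5 * sd_w * sqrt(2))
      m + matrix(stats::rnorm(N * Tn, sd = sd_w), N, Tn) + pink
    })
  }

  # --- motion spikes: global excursions removed later by screening ---
  art <- spec$artifacts
  n_ev <- stats::rpois(1, art$spike_rate * spec$duration)
  if (n_ev > 0) {
    centers <- stats::runif(n_ev, 0, spec$duration)
    width <- art$spike_width
    amp <- stats::runif(n_ev, art$spike_amp[1], art$spike_amp[2]) *
      spec$od_scale * sample(c(-1, 1), n_ev, replace = TRUE)
    chgain <- stats::runif(N, 0.5, 1.5)
    bump <- matrix(0, 1, Tn)
    for (e in seq_len(n_ev)) {
      bump <- bump + amp[e] * exp(-(t_sec - centers[e])^2 / (2 * width^2))
    }
    spikes <- chgain %o% as.numeric(bump)
    od <- lapply(od, function(m) m + spikes)
  }

  # --- to voltages, then channel-level artifacts ---
  volts <- lapply(od, function(m) t(10^(-m)))
  bad_pick <- sample.int(N, art$n_bad + art$n_saturated)
  drift_ch <- utils::head(bad_pick, art$n_bad)
  sat_ch <- utils::tail(bad_pick, art$n_saturated)
  f_drift <- max(0.004, 2 / spec$duration)  # >= 2 periods per run
  for (b in drift_ch) {
    ph <- stats::runif(1, 0, 2 * pi)
    drift <- 1 + 0.3 * sin(2 * pi * f_drift * t_sec + ph)
    volts <- lapply(volts, function(m) { m[, b] <- m[, b] * drift; m })
  }
  for (b in sat_ch) {
    i0 <- sample.int(Tn - round(0.02 * Tn), 1)
    sat_idx <- i0:(i0 + round(0.02 * Tn))
    volts <- lapply(volts, function(m) { m[sat_idx, b] <- 5; m })
  }

  cts <- channel_timeseries(volts, fs = fs, channels = ch,
                            wavelengths = geom$E$wavelengths, units = "V")
  reference <- t(lat_o) + 0.1 * band_noise(Tn, fs, spec$band, R)
  colnames(reference) <- names(geom$rois)

  list(cts = cts,
       latents_oxy = cal * lat_o,
       latents_deoxy = cal * lat_d,
       reference = reference,
       bad_injected = drift_ch, saturated_injected = sat_ch,
       seed = seed)
}

#' Simulate a complete multi-subject study
#'
#' Generates the shared geometry, the ground-truth connectivity and all
#' subject recordings, with per-run seeds derived deterministically from
#' the master seed (regeneration under the same spec is identical).
#'
#' @param spec a [truth_spec()].
#' @return object of class `synthetic_study`: list with `spec`, `geom`,
#'   `truth` (restricted to the available ROIs, with names), `subjects`
#'   (nested run lists) and a `manifest` of seeds.
#' @export
simulate_study <- function(spec) {
  geom <- prepare_study_geometry(spec)
  cen <- t(vapply(seq_len(spec$n_rois), function(r) {
    colMeans(geom$grid$centers[geom$parcellation$labels == r, ,
                               drop = FALSE])
  }, numeric(3)))
  truth <- make_truth_connectivity(spec$n_rois, spec$sparsity,
                                   spec$strength, spec$seed,
                                   distances = as.matrix(stats::dist(cen)))
  dimnames(truth$pc) <- list(names(geom$rois), names(geom$rois))
  subjects <- vector("list", spec$n_subjects)
  manifest <- NULL
  for (s in seq_len(spec$n_subjects)) {
    subjects[[s]] <- simulate_subject(spec, geom, truth, s)
    manifest <- rbind(manifest, data.frame(
      subject = s, run = seq_len(spec$n_runs),
      seed = spec$seed * 10000 + s * 100 + seq_len(spec$n_runs)))
  }
  names(subjects) <- paste0("S", seq_len(spec$n_subjects))
  structure(
    list(spec = spec, geom = geom, truth = truth, subjects = subjects,
         manifest = manifest),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d subjects x %d runs, %.0f s @ %.1f Hz, %d ROIs, %d channels\n",
    x$spec$n_subjects, x$spec$n_runs, x$spec$duration, x$spec$fs,
    x$spec$n_rois, nrow(x$geom$sm$S)))
  invisible(x)
}
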
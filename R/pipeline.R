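#' Reconstruct one preprocessed run with a chosen algorithm
#'
#' Dispatches to the minimum-norm variants or the two-step hierarchical
#' Bayesian solver, per wavelength, then unmixes the per-wavelength
#' absorption images into oxy-/deoxy-Hb and (optionally) smooths them.
#' For `HB` the first step is an MN reconstruction of the same
#' (unregressed) data, whose per-voxel mean squares seed the hierarchical
#' prior.
#'
#' @param pre a [preprocess_run()] output (scalp-regressed for the MN
#'   variants, unregressed for HB).
#' @param sm the study [build_sensitivity()] object.
#' @param ext an [extinction_matrix()].
#' @param algorithm `"HB"`, `"MN"` or `"MN_WU"`.
#' @param gamma0_factor HB confidence as a multiple of the retained
#'   sample count L (default 0.1).
#' @param hb [hb_config()] overrides (list).
#' @param smooth_fwhm Gaussian smoothing FWHM in mm applied to the Hb
#'   images (0 disables; default 8).
#' @return list with `oxy`, `deoxy` (voxels x time), `algorithm` and
#'   per-wavelength `diagnostics`.
#' @export
reconstruct_run <- function(pre, sm, ext, algorithm = c("HB", "MN", "MN_WU"),
                            gamma0_factor = 0.1, hb = list(),
                            smooth_fwhm = 8) {
  algorithm <- match.arg(algorithm)
  Ssub <- sm$S[pre$good, , drop = FALSE]
  dw <- depth_weights(sm, mode = if (algorithm == "MN_WU") "MN_WU" else "MN")
  basis <- if (algorithm == "HB") scalp_basis(sm$grid) else NULL
  images <- vector("list", length(pre$od))
  diags <- vector("list", length(pre$od))
  for (w in seq_along(pre$od)) {
    Y <- t(pre$od[[w]])
    Tn <- ncol(Y)
    if (algorithm %in% c("MN", "MN_WU")) {
      img <- mn_reconstruct(Y, Ssub,
                            config = list(mode = dw$mode, L = dw$L,
                                          beta = dw$beta))
      img$grid <- sm$grid
      img$compartment <- sm$grid$compartment
    } else {
      mn1 <- mn_reconstruct(Y, Ssub,
                            config = list(mode = "MN", L = dw$L,
                                          beta = dw$beta))
      lam0 <- compute_lambda0(mn1$values)
      cortex <- sm$grid$compartment == "cortex"
      cfg <- do.call(hb_config, utils::modifyList(
        list(gamma0 = gamma0_factor * Tn,
             max_iter = 100, tol = 1e-4), hb))
      img <- hb_reconstruct(Y, Ssub, compartments = sm$grid$compartment,
                            prior = list(
                              lambda0 = lam0[cortex],
                              scalp_var = 10 * mean(lam0[!cortex]),
                              basis = basis),
                            config = cfg)
      img$grid <- sm$grid
    }
    images[[w]] <- img
    diags[[w]] <- img$diagnostics
  }
  hb_sp <- unmix_hemoglobin(images, ext)
  if (smooth_fwhm > 0) {
    hb_sp$oxy <- smooth_image(hb_sp$oxy, sm$grid, smooth_fwhm)
    hb_sp$deoxy <- smooth_image(hb_sp$deoxy, sm$grid, smooth_fwhm)
  }
  list(oxy = hb_sp$oxy, deoxy = hb_sp$deoxy, algorithm = algorithm,
       gamma0_factor = if (algorithm == "HB") gamma0_factor else NA_real_,
       diagnostics = diags)
}

#' Analyze a synthetic study with one or more DOT algorithms
#'
#' For every subject, run and algorithm: preprocess (with global
#' short-channel regression for the MN variants, without for HB),
#' decimate, reconstruct, unmix, smooth, extract ROI time series over the
#' sensitive voxels and compute the partial-correlation connectivity for
#' both Hb species. HB can be evaluated at several confidence settings at
#' once via `gamma0_factors` (entries beyond the first are labelled
#' `HB_g<factor>`).
#'
#' @param study a [simulate_study()] result.
#' @param algorithms subset of `c("HB", "MN", "MN_WU")`.
#' @param gamma0_factors HB confidence sweep (multiples of L).
#' @param decimate integer subsampling factor applied after preprocessing
#'   (default 25; the hemodynamic band ends at 0.08 Hz so this is
#'   lossless for connectivity).
#' @param shrinkage covariance ridge fraction for the ROI partial
#'   correlations (default 0.05): the inverse operator compresses the
#'   high-order spatial modes of the reconstruction, so the ROI
#'   covariance of reconstructed series is ill-conditioned and a small
#'   ridge keeps the precision matrix meaningful.
#' @param hb [hb_config()] overrides.
#' @param smooth_fwhm smoothing FWHM in mm.
#' @return object of class `study_analysis`: nested list
#'   `conn[[algo]][[subject]][[run]]` with `oxy`/`deoxy` connectivity
#'   matrices and ROI time series, plus reference connectivity per
#'   subject/run.
#' @export
analyze_study <- function(study, algorithms = c("HB", "MN", "MN_WU"),
                          gamma0_factors = 0.1, decimate = 25,
                          hb = list(), smooth_fwhm = 8,
                          shrinkage = 0.05) {
  stopifnot(inherits(study, "synthetic_study"))
  geom <- study$geom
  parc <- geom$parcellation
  algos <- character(0)
  for (a in algorithms) {
    if (a == "HB") {
      algos <- c(algos, vapply(seq_along(gamma0_factors), function(i) {
        if (i == 1) "HB" else paste0("HB_g", gamma0_factors[i])
      }, character(1)))
    } else algos <- c(algos, a)
  }
  conn <- stats::setNames(vector("list", length(algos)), algos)
  reference <- list()

  for (sname in names(study$subjects)) {
    runs <- study$subjects[[sname]]
    reference[[sname]] <- lapply(runs, function(rn) {
      idx <- seq(1, nrow(rn$reference), by = decimate)
      partial_correlation(rn$reference[idx, , drop = FALSE])
    })
    pre_plain <- lapply(runs, function(rn) {
      decimate_run(preprocess_run(rn$cts, preprocess_config()), decimate)
    })
    pre_regr <- lapply(runs, function(rn) {
      decimate_run(preprocess_run(
        rn$cts, preprocess_config(scalp_regression = TRUE)), decimate)
    })
    for (a in seq_along(algos)) {
      base <- sub("_g.*$", "", algos[a])
      gf <- if (base == "HB") {
        if (algos[a] == "HB") gamma0_factors[1] else
          as.numeric(sub("^HB_g", "", algos[a]))
      } else NA_real_
      conn[[algos[a]]][[sname]] <- lapply(runs_idx <- seq_along(runs),
        function(rix) {
          pre <- if (base == "HB") pre_plain[[rix]] else pre_regr[[rix]]
          rec <- reconstruct_run(pre, geom$sm, geom$E, base,
                                 gamma0_factor = if (is.na(gf)) 0.1 else gf,
                                 hb = hb, smooth_fwhm = smooth_fwhm)
          ts_o <- roi_timeseries(rec$oxy, parc, geom$mask, geom$rois)
          ts_d <- roi_timeseries(rec$deoxy, parc, geom$mask, geom$rois)
          list(oxy = partial_correlation(ts_o, shrinkage = shrinkage),
               deoxy = partial_correlation(ts_d, shrinkage = shrinkage),
               ts_oxy = ts_o, ts_deoxy = ts_d)
        })
      names(conn[[algos[a]]][[sname]]) <- names(runs)
    }
  }
  structure(
    list(conn = conn, reference = reference, algorithms = algos,
         truth = study$truth, spec = study$spec, rois = geom$rois),
    class = "study_analysis"
  )
}

#' Group-level comparison of DOT algorithms
#'
#' Mirrors the evaluation battery of a multi-algorithm connectivity
#' study: per subject/run similarity of each algorithm's connectivity to
#' the ground truth (and to the reference modality), inter-run
#' reproducibility (Pearson r over z-transformed connection values plus
#' ICC(C,1)/ICC(C,k)), and a one-way ANOVA with Tukey-Kramer pairwise
#' comparisons across algorithms on the per-subject z-values (runs pooled
#' as observations for similarity).
#'
#' @param analysis a [analyze_study()] result.
#' @param species `"oxy"`, `"deoxy"` or both.
#' @return list with tidy data frames `similarity` (subject, run, algo,
#'   species, r_truth, z_truth, r_ref, z_ref), `reproducibility`
#'   (subject, algo, species, r, z, icc_c1, icc_ck) and per-species
#'   `anova` results.
#' @export
compare_study <- function(analysis, species = c("oxy", "deoxy")) {
  truth_pc <- analysis$truth$pc
  sim <- NULL; rep <- NULL
  for (sp in species) {
    for (a in analysis$algorithms) {
      for (sname in names(analysis$conn[[a]])) {
        runs <- analysis$conn[[a]][[sname]]
        for (rix in seq_along(runs)) {
          st <- similarity(runs[[rix]][[sp]], truth_pc)
          sr <- similarity(runs[[rix]][[sp]],
                           analysis$reference[[sname]][[rix]])
          sim <- rbind(sim, data.frame(
            subject = sname, run = rix, algorithm = a, species = sp,
            r_truth = st$r, z_truth = st$z, r_ref = sr$r, z_ref = sr$z,
            stringsAsFactors = FALSE))
        }
        if (length(runs) >= 2) {
          rr <- interrun_reproducibility(runs[[1]][[sp]], runs[[2]][[sp]])
          rep <- rbind(rep, data.frame(
            subject = sname, algorithm = a, species = sp,
            r = rr$r, z = rr$z, icc_c1 = rr$icc_c1, icc_ck = rr$icc_ck,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  anova <- list()
  multi <- length(analysis$algorithms) >= 2
  for (sp in species) {
    d <- sim[sim$species == sp, ]
    anova[[sp]] <- list(
      similarity_truth = if (multi) {
        anova_tukey(split(d$z_truth, d$algorithm))
      },
      reproducibility = if (multi && !is.null(rep)) {
        dr <- rep[rep$species == sp, ]
        anova_tukey(split(dr$z, dr$algorithm))
      })
  }
  list(similarity = sim, reproducibility = rep, anova = anova)
}

#' Run the simulate -> preprocess -> reconstruct -> connectivity ->
#' compare pipeline
#'
#' Thin driver tying the stages together under one configuration, with
#' optional CSV/JSON outputs. Reproducible under a fixed seed.
#'
#' @param config list (or path to a YAML/JSON file) with optional
#'   entries: `spec` (arguments to [truth_spec()]), `algorithms`,
#'   `gamma0_factors`, `decimate`, `smooth_fwhm`, `out_dir`, `seed`.
#' @return list with `study`, `analysis`, `comparison` and the resolved
#'   `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  algorithms <- config$algorithms %||% c("HB", "MN", "MN_WU")
  bad <- setdiff(sub("_g.*$", "", algorithms), c("HB", "MN", "MN_WU"))
  if (length(bad)) stop("unknown algorithm(s): ", paste(bad, collapse = ", "))
  spec_args <- config$spec %||% list()
  if (!is.null(config$seed)) spec_args$seed <- config$seed
  spec <- do.call(truth_spec, spec_args)
  message("simulate: ", spec$n_subjects, " subjects x ", spec$n_runs,
          " runs, seed ", spec$seed)
  study <- simulate_study(spec)
  message("analyze: ", paste(algorithms, collapse = ", "))
  analysis <- analyze_study(study, algorithms = algorithms,
                            gamma0_factors = config$gamma0_factors %||% 0.1,
                            decimate = config$decimate %||% 25,
                            smooth_fwhm = config$smooth_fwhm %||% 8)
  comparison <- compare_study(analysis)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(comparison$similarity,
                     file.path(config$out_dir, "similarity.csv"),
                     row.names = FALSE)
    if (!is.null(comparison$reproducibility)) {
      utils::write.csv(comparison$reproducibility,
                       file.path(config$out_dir, "reproducibility.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed = spec$seed, spec = unclass(spec),
           algorithms = algorithms,
           anova = lapply(comparison$anova, function(a) {
             lapply(a, function(x) if (is.null(x)) NULL else
               list(F = x$F, df = x$df, p = x$p))
           })),
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(study = study, analysis = analysis, comparison = comparison,
       config = config)
}
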
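# End-to-end orchestration: QC -> size model -> physicochemical PCA/MLR ->
# uptake fits -> uptake PCA/MLR, from one configuration, with a
# machine-readable exclusion log and byte-reproducible artifacts.

#' Pipeline configuration
#'
#' Exactly one of `library_path`/`uptake_path` (measured data) or
#' `synth` (a [synth_params()] object) must be set.
#'
#' @param library_path,uptake_path Paths to measured CSV/TSV tables.
#' @param synth A [synth_params()] object for a synthetic run.
#' @param seed Integer seed (synthetic runs).
#' @param single_particle_nm Single-particle DLS threshold, nm.
#' @param ratio_upper,ratio_lower Dispersion-class thresholds.
#' @param exponents Size-model exponents `(a, b)`.
#' @param pca_vars_physicochem Variables of the physicochemical PCA
#'   (`minus_z` is derived from `zeta` via [transform_zeta()]).
#' @param mlr_physicochem Predictors of the diameter MLR.
#' @param pca_vars_uptake Variables of the uptake PCA (on the
#'   [uptake_feature_table()]).
#' @param mlr_uptake Predictors of the HEK-uptake MLR.
#' @param ref_load Reference load for uptake reporting, ug mL^-1.
#' @param r2_threshold Uptake-fit exclusion threshold.
#' @param min_solid_fraction Samples with measured/theoretical solid
#'   content below this are excluded from uptake fitting (too little
#'   material for the cell titration).
#' @param out_dir Optional directory for CSV/report artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(library_path = NULL, uptake_path = NULL,
                            synth = NULL, seed = 1,
                            single_particle_nm = 800,
                            ratio_upper = 1.2, ratio_lower = 0.8,
                            exponents = c(1, 1),
                            pca_vars_physicochem = c("monomer_conc", "x", "mn",
                                                     "d_dls", "minus_z"),
                            mlr_physicochem = c("x", "minus_z", "mn"),
                            pca_vars_uptake = c("x", "mn_sq", "d_dls",
                                                "minus_z", "u_p_raw", "u_p_hek"),
                            mlr_uptake = c("x", "mn_sq", "d_dls", "minus_z"),
                            ref_load = 100, r2_threshold = 0.8,
                            min_solid_fraction = 0.5,
                            out_dir = NULL) {
  has_paths <- !is.null(library_path) || !is.null(uptake_path)
  has_synth <- !is.null(synth)
  if (has_paths == has_synth) {
    stop("exactly one of {library_path/uptake_path, synth} must be set",
         call. = FALSE)
  }
  if (has_paths && (is.null(library_path) || is.null(uptake_path))) {
    stop("both library_path and uptake_path are required for a measured run",
         call. = FALSE)
  }
  if (has_synth) stopifnot(inherits(synth, "synth_params"))
  stopifnot(single_particle_nm > 0, ratio_upper > ratio_lower,
            r2_threshold > 0, r2_threshold <= 1,
            min_solid_fraction >= 0, min_solid_fraction <= 1, ref_load > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

.log_exclusion <- function(log, sample_id, stage, reason) {
  dplyr::bind_rows(log, tibble::tibble(sample_id = sample_id, stage = stage,
                                       reason = reason))
}

#' Run the full structure-property-uptake analysis
#'
#' Stages, in order: load or simulate the library; DLS/SEM QC; micellar
#' size-model calibration on QC-passing samples; standardized PCA and
#' diameter MLR of the physicochemical variables; per-sample uptake fits
#' with R^2 and low-solid-content exclusion; uptake feature table, PCA and
#' HEK-uptake MLR; summaries.  With `out_dir` set, each stage writes its
#' CSV artifact plus a plain-text report (no timestamps, so identical
#' config + seed gives byte-identical artifacts).
#'
#' @param config A [pipeline_config()] object.
#' @return A list of class `uptake_pipeline` with elements `records`,
#'   `qc`, `size_model`, `pca_physicochem`, `mlr_physicochem`,
#'   `uptake_fits`, `uptake_summary`, `features`, `pca_uptake`,
#'   `mlr_uptake`, `simple_fits`, and `exclusions` (one row per excluded
#'   sample with a reason code: `aggregate`, `low-solid-content`,
#'   `low-R2`, `missing-data`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  excl <- tibble::tibble(sample_id = character(0), stage = character(0),
                         reason = character(0))

  if (!is.null(config$synth)) {
    lib <- simulate_library(config$synth, seed = config$seed)
    records <- lib$records
    uptake <- lib$uptake
  } else {
    records <- read_library_table(config$library_path)
    uptake <- read_uptake_table(config$uptake_path)
  }

  qc <- flag_single_particles(records, threshold_nm = config$single_particle_nm,
                              ratio_upper = config$ratio_upper,
                              ratio_lower = config$ratio_lower)
  agg <- qc$sample_id[qc$exclude_from_size_model]
  if (length(agg) > 0) excl <- .log_exclusion(excl, agg, "size_qc", "aggregate")

  size_model <- calibrate_k(records, qc, exponents = config$exponents)

  # aggregated samples carry an inflated hydrodynamic diameter and are left
  # out of the physicochemical multivariate stage
  not_agg <- !(records$sample_id %in%
                 qc$sample_id[qc$dispersion_class == "aggregated"])
  phys <- tibble::tibble(records[not_agg, c("sample_id", "monomer_conc", "x",
                                            "mn", "d_dls")],
                         minus_z = transform_zeta(records$zeta[not_agg]))
  cc <- stats::complete.cases(phys)
  if (any(!cc)) {
    excl <- .log_exclusion(excl, phys$sample_id[!cc], "pca_physicochem",
                           "missing-data")
  }
  std <- suppressMessages(standardize(phys[cc, ], config$pca_vars_physicochem))
  pca_phys <- pca(std)
  mlr_phys <- suppressMessages(
    mlr_fit(phys[cc, ], "d_dls", config$mlr_physicochem))

  # uptake stage: drop low-solid-content samples before fitting
  solid_frac <- records$solid_measured / records$solid_theoretical
  low_solid <- records$sample_id[!is.na(solid_frac) &
                                   solid_frac < config$min_solid_fraction]
  if (length(low_solid) > 0) {
    excl <- .log_exclusion(excl, low_solid, "uptake_fit", "low-solid-content")
  }
  uptake_in <- uptake[!(uptake$sample_id %in% low_solid), ]
  fits <- fit_uptake_all(uptake_in, records = records,
                         r2_threshold = config$r2_threshold,
                         ref_load = config$ref_load)
  low_r2 <- unique(fits$sample_id[fits$excluded])
  if (length(low_r2) > 0) {
    excl <- .log_exclusion(excl, low_r2, "uptake_fit", "low-R2")
  }
  uptake_summary <- lapply(stats::setNames(nm = unique(fits$cell_line)),
                           function(cl) summarize_uptake(fits, cl))

  features <- suppressMessages(uptake_feature_table(fits, records))
  pca_up <- NULL; mlr_up <- NULL; simple_fits <- NULL
  if (nrow(features) >= length(config$pca_vars_uptake) + 2) {
    pca_up <- pca(suppressMessages(standardize(features, config$pca_vars_uptake)))
    mlr_up <- suppressMessages(
      mlr_fit(features, "u_p_hek", config$mlr_uptake))
    feed <- parse_sample_id(features$sample_id)$sty_feed
    simple_fits <- list(
      hek_vs_x = simple_fit(features$x, features$u_p_hek),
      raw_vs_x = simple_fit(features$x, features$u_p_raw),
      hek_vs_x_group_means = simple_fit(features$x, features$u_p_hek,
                                        group = feed, group_means = TRUE)
    )
  }

  res <- structure(list(
    config = config, records = records, qc = qc, size_model = size_model,
    pca_physicochem = pca_phys, mlr_physicochem = mlr_phys,
    uptake_fits = fits, uptake_summary = uptake_summary,
    features = features, pca_uptake = pca_up, mlr_uptake = mlr_up,
    simple_fits = simple_fits, exclusions = excl
  ), class = "uptake_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(res, config$out_dir)
  res
}

#' Write pipeline artifacts to a directory
#'
#' CSVs per stage plus `report.txt`; artifacts carry no timestamps and are
#' byte-identical across reruns with the same config and seed.
#'
#' @param result An `uptake_pipeline` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_csv(x, file.path(out_dir, f), na = "")
  write_library_table(result$records, file.path(out_dir, "library.csv"))
  qc_out <- result$qc
  qc_out$ratio_r <- round_half_up(qc_out$ratio_r, 1)
  w(qc_out, "qc.csv")
  w(result$size_model$data, "size_model_predictions.csv")
  w(result$uptake_fits, "uptake_fits.csv")
  w(result$features, "uptake_features.csv")
  w(result$exclusions, "exclusions.csv")
  con <- file(file.path(out_dir, "report.txt"), "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(result)
  invisible(out_dir)
}

#' @export
print.uptake_pipeline <- function(x, ...) {
  cat("Particle-library structure-property-uptake analysis\n")
  cat(sprintf("  %d samples; %d excluded entries (%s)\n",
              nrow(x$records), nrow(x$exclusions),
              paste(unique(x$exclusions$reason), collapse = ", ")))
  print(x$size_model)
  cat("\nPhysicochemical PCA:\n"); print(x$pca_physicochem)
  cat("\nDiameter MLR:\n"); print(x$mlr_physicochem)
  for (cl in names(x$uptake_summary)) {
    s <- x$uptake_summary[[cl]]
    cat(sprintf("\n%s uptake at reference load: %.1f +/- %.1f %% (n = %d)\n",
                cl, s$mean, s$sd, s$n))
  }
  if (!is.null(x$pca_uptake)) {
    cat("\nUptake PCA:\n"); print(x$pca_uptake)
    cat("\nHEK uptake MLR:\n"); print(x$mlr_uptake)
    sf <- x$simple_fits
    cat(sprintf("\nSimple fits R^2: HEK~x %.4f, RAW~x %.4f, HEK~x (group means) %.4f\n",
                sf$hek_vs_x$r_squared, sf$raw_vs_x$r_squared,
                sf$hek_vs_x_group_means$r_squared))
  }
  invisible(x)
}
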
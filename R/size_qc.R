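# Aggregation / dispersity QC from paired DLS and SEM diameters, and
# redundancy screening of candidate analysis variables.

#' Round half away from zero
#'
#' Display rounding used for the DLS/SEM ratio: 0.25 -> 0.3 at one decimal,
#' unlike the IEC round-half-even of [round()].  Comparisons always use
#' full precision; this is presentation only.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Ratio of DLS to SEM diameter
#'
#' `r = d(DLS) / d(SEM)` compares the intensity-weighted hydrodynamic
#' diameter with the number-weighted micrograph diameter; r near 1 means a
#' well-dispersed sample, large r aggregation during the DLS measurement.
#' A missing SEM diameter (no single particles on the micrograph) yields a
#' missing ratio, not an error.
#'
#' @param d_dls DLS diameter(s), nm, > 0.
#' @param d_sem SEM diameter(s), nm, > 0 or `NA`.
#' @return The ratio at full precision (round for display with
#'   [round_half_up()]).
#' @export
dls_sem_ratio <- function(d_dls, d_sem) {
  if (any(d_dls <= 0, na.rm = TRUE)) stop("d_dls must be positive", call. = FALSE)
  if (any(d_sem <= 0, na.rm = TRUE)) stop("d_sem must be positive", call. = FALSE)
  d_dls / d_sem
}

#' Classify sample dispersion from the DLS/SEM ratio
#'
#' `aggregated` when r > 1.2 (aggregate formation during DLS),
#' `over_approximated` when r < 0.8 (size overestimated due to broad
#' dispersity), `consistent` for 0.8 <= r <= 1.2, `unknown` when the ratio
#' is missing.  Thresholds are strict, evaluated at full precision: a
#' sample printing r = 1.2 after rounding but measuring 1.19 is consistent.
#'
#' @param ratio DLS/SEM ratio(s), full precision; `NA` allowed.
#' @param upper,lower Aggregation / over-approximation thresholds.
#' @return Factor with levels `consistent`, `aggregated`,
#'   `over_approximated`, `unknown`.
#' @export
classify_dispersion <- function(ratio, upper = 1.2, lower = 0.8) {
  lv <- c("consistent", "aggregated", "over_approximated", "unknown")
  out <- ifelse(is.na(ratio), "unknown",
                ifelse(ratio > upper, "aggregated",
                       ifelse(ratio < lower, "over_approximated", "consistent")))
  factor(out, levels = lv)
}

#' QC a particle library: aggregation and single-particle status
#'
#' Computes the DLS/SEM ratio and dispersion class per sample and flags
#' single particles (d(DLS) strictly below the threshold; sub-threshold DLS
#' sizes were the ones confirmed as single particles in randomized SEM
#' examinations).  A sample is excluded from the size model when it is
#' aggregated or not a single particle.
#'
#' @param records Particle records (needs `sample_id`, `d_dls`, `d_sem`).
#' @param threshold_nm Single-particle DLS threshold, nm (default 800;
#'   `d_dls` exactly at the threshold is not a single particle).
#' @param ratio_upper,ratio_lower Dispersion-class thresholds, see
#'   [classify_dispersion()].
#' @return A QC tibble: `sample_id`, `ratio_r` (full precision),
#'   `dispersion_class`, `single_particle`, `exclude_from_size_model`.
#' @export
flag_single_particles <- function(records, threshold_nm = 800,
                                  ratio_upper = 1.2, ratio_lower = 0.8) {
  stopifnot(threshold_nm > 0)
  r <- dls_sem_ratio(records$d_dls, records$d_sem)
  cls <- classify_dispersion(r, upper = ratio_upper, lower = ratio_lower)
  single <- records$d_dls < threshold_nm
  tibble::tibble(
    sample_id = records$sample_id,
    ratio_r = r,
    dispersion_class = cls,
    single_particle = single,
    exclude_from_size_model = cls == "aggregated" | !single
  )
}

#' Screen variables for pairwise redundancy
#'
#' Pairwise Pearson correlations over complete rows; a variable whose
#' largest absolute correlation with any other reaches the threshold is
#' flagged as dependent on that partner (as the polydispersity index is on
#' the DLS diameter once aggregation couples them), and should not enter a
#' PCA as an independent variable.
#'
#' @param table Data frame holding the variables.
#' @param variables Column names to screen.
#' @param rho_threshold Absolute-correlation threshold (default 0.7).
#' @return A tibble: `variable`, `partner`, `max_abs_rho`, `dependent`;
#'   the full correlation matrix in attribute `"cor"`.
#' @export
screen_redundant_variables <- function(table, variables, rho_threshold = 0.7) {
  stopifnot(length(variables) >= 2, rho_threshold > 0)
  m <- as.matrix(table[, variables])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 complete rows", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variable(s): ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  }
  rho <- stats::cor(m)
  off <- abs(rho); diag(off) <- 0
  partner_idx <- apply(off, 1, which.max)
  out <- tibble::tibble(
    variable = variables,
    partner = variables[partner_idx],
    max_abs_rho = off[cbind(seq_along(variables), partner_idx)],
    dependent = off[cbind(seq_along(variables), partner_idx)] >= rho_threshold
  )
  attr(out, "cor") <- rho
  attr(out, "n_used") <- nrow(m)
  out
}
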
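# Logarithmic cellular-uptake model: the percentage of particle-positive
# cells U_P grows degressively with particle load p and is modelled as
#
#     U_P = u_S * log10(p_tilde) + u_L,
#
# with p_tilde the solid-content-corrected dimensionless load, u_S the
# uptake slope (% per decade of load) and u_L the level (% at the standard
# load p0).  Per-sample fits with R^2 below a threshold (default 0.80) are
# flagged as not following the model and excluded from summaries.

#' Correct a particle load for the measured solid content
#'
#' Nominal loads are computed from the theoretical solid content of the
#' synthesis; the real, measured solid content rescales them.  The result
#' is made dimensionless by the standard load `p0` (1 ug mL^-1).
#'
#' @param p Nominal particle load, ug mL^-1, > 0.
#' @param solid_theoretical Theoretical solid content (> 0).
#' @param solid_measured Measured solid content (> 0); defaults to the
#'   theoretical value when `NULL`/missing (no correction).
#' @param p0 Standard particle load, ug mL^-1 (default 1).
#' @return The corrected dimensionless load
#'   `(p * solid_measured / solid_theoretical) / p0`.
#' @export
correct_load <- function(p, solid_theoretical = 1, solid_measured = NULL,
                         p0 = 1) {
  if (is.null(solid_measured)) solid_measured <- solid_theoretical
  solid_measured <- ifelse(is.na(solid_measured), solid_theoretical, solid_measured)
  if (any(p <= 0) || any(solid_theoretical <= 0) ||
      any(solid_measured <= 0, na.rm = TRUE) || any(p0 <= 0)) {
    stop("loads and solid contents must be positive", call. = FALSE)
  }
  (p * solid_measured / solid_theoretical) / p0
}

#' Fit the logarithmic uptake model for one sample and cell line
#'
#' OLS of `positive_pct` against `log10(load_corrected)`: the slope is
#' u_S, the intercept u_L.  Requires at least 3 distinct loads (replicates
#' at a load are kept and pooled into the fit).  Fits with R^2 below
#' `r2_threshold` are marked excluded and report a missing reference
#' uptake.  The reference uptake `U_P_ref` is the model value at the
#' (corrected) reference load, clipped to [0, 100] for reporting; the
#' expected error `Er` is the pooled within-load replicate standard
#' deviation of the measurements, when replicates exist.
#'
#' @param measurements Tibble for one (sample, cell line): columns
#'   `positive_pct` and `load_corrected` (or `load_p`, corrected via
#'   `solid_theoretical`/`solid_measured`).
#' @param r2_threshold Exclusion threshold on R^2 (strict `<`, default 0.80).
#' @param ref_load Reference load for `U_P_ref`, ug mL^-1 (default 100),
#'   corrected like the measurement loads.
#' @param solid_theoretical,solid_measured Per-sample solid contents used
#'   when `load_corrected` is absent.
#' @param p0 Standard load, ug mL^-1.
#' @param log_base Base of the load logarithm (default 10).
#' @return A one-row tibble: `sample_id`, `cell_line`, `u_s`, `u_l`,
#'   `r_squared`, `excluded`, `u_p_ref` (%, clipped, `NA` when excluded),
#'   `u_p_ref_raw` (unclipped model value), `er` (%), `n_points`.
#' @export
fit_uptake <- function(measurements, r2_threshold = 0.8, ref_load = 100,
                       solid_theoretical = 1, solid_measured = NULL,
                       p0 = 1, log_base = 10) {
  m <- measurements
  ptilde <- if ("load_corrected" %in% names(m) && !all(is.na(m$load_corrected))) {
    m$load_corrected
  } else {
    correct_load(m$load_p, solid_theoretical, solid_measured, p0)
  }
  keep <- !is.na(ptilde) & !is.na(m$positive_pct)
  ptilde <- ptilde[keep]
  up <- m$positive_pct[keep]
  if (length(unique(ptilde)) < 3) {
    stop("need at least 3 distinct particle loads", call. = FALSE)
  }
  lp <- log(ptilde, base = log_base)
  fit <- stats::lm.fit(cbind(1, lp), up)
  u_l <- unname(fit$coefficients[1])
  u_s <- unname(fit$coefficients[2])
  ssr <- sum(fit$residuals^2)
  sst <- sum((up - mean(up))^2)
  r2 <- if (sst == 0) 0 else 1 - ssr / sst
  excluded <- r2 < r2_threshold
  ptilde_ref <- correct_load(ref_load, solid_theoretical, solid_measured, p0)
  u_p_raw <- u_s * log(ptilde_ref, base = log_base) + u_l
  # replicate-sd of the measurements, pooled over loads, as the expected
  # error of the reported uptake (first-order: the fit is linear in U_P)
  reps <- split(up, lp)
  reps <- reps[lengths(reps) > 1]
  er <- if (length(reps) > 0) {
    sqrt(mean(unlist(lapply(reps, stats::var))))
  } else {
    NA_real_
  }
  tibble::tibble(
    sample_id = if ("sample_id" %in% names(m)) m$sample_id[1] else NA_character_,
    cell_line = if ("cell_line" %in% names(m)) m$cell_line[1] else NA_character_,
    u_s = u_s, u_l = u_l, r_squared = r2, excluded = excluded,
    u_p_ref = ifelse(excluded, NA_real_, pmin(100, pmax(0, u_p_raw))),
    u_p_ref_raw = u_p_raw,
    er = er,
    n_points = length(up)
  )
}

#' Fit the uptake model for every (sample, cell line) group
#'
#' @param measurements Uptake tibble with `sample_id` and `cell_line`.
#' @param records Optional particle records supplying per-sample solid
#'   contents for the load correction.
#' @param ... Passed to [fit_uptake()].
#' @return A tibble of fits, one row per (sample, cell line).
#' @export
fit_uptake_all <- function(measurements, records = NULL, ...) {
  groups <- split(measurements,
                  list(measurements$sample_id, measurements$cell_line),
                  drop = TRUE)
  fits <- lapply(groups, function(g) {
    st <- 1; sm <- NULL
    if (!is.null(records)) {
      i <- match(g$sample_id[1], records$sample_id)
      if (!is.na(i) && !is.na(records$solid_theoretical[i])) {
        st <- records$solid_theoretical[i]
        sm <- records$solid_measured[i]
      }
    }
    fit_uptake(g, solid_theoretical = st, solid_measured = sm, ...)
  })
  out <- dplyr::bind_rows(fits)
  out[order(out$cell_line, out$sample_id), ]
}

#' Summarize reference uptake over non-excluded fits
#'
#' Arithmetic mean and sample standard deviation (n - 1) of the reference
#' uptake `u_p_ref` over fits that pass the R^2 exclusion rule.
#'
#' @param fits Fit tibble from [fit_uptake_all()].
#' @param cell_line Optional cell-line filter (`"RAW"` or `"HEK"`).
#' @return A list: `mean` (%), `sd` (%), `n`.
#' @export
summarize_uptake <- function(fits, cell_line = NULL) {
  f <- fits
  if (!is.null(cell_line)) f <- f[f$cell_line == cell_line, ]
  v <- f$u_p_ref[!f$excluded & !is.na(f$u_p_ref)]
  if (length(v) < 2) stop("need at least 2 non-excluded uptake values", call. = FALSE)
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Assemble the feature table for uptake multivariate analysis
#'
#' One row per sample with the variables used in the uptake PCA/MLR:
#' composition `x` (mol %), `mn_sq` (Mn squared, kg^2 mol^-2 — the squared
#' molecular weight follows the size model better than Mn itself),
#' `d_dls` (nm), `minus_z` (mV) and the reference uptake of each cell line
#' (`u_p_raw`, `u_p_hek`, %).  Rows with any missing variable (e.g. an
#' excluded uptake fit) are dropped with a message.
#'
#' @param fits Uptake fits from [fit_uptake_all()].
#' @param records Particle records.
#' @return A tibble with columns `sample_id`, `x`, `mn_sq`, `d_dls`,
#'   `minus_z`, `u_p_raw`, `u_p_hek`.
#' @export
uptake_feature_table <- function(fits, records) {
  if (length(intersect(fits$sample_id, records$sample_id)) == 0) {
    stop("no overlapping sample ids between fits and records", call. = FALSE)
  }
  f <- fits[, c("sample_id", "cell_line", "u_p_ref")]
  f$cell_line <- factor(f$cell_line, levels = intersect(c("RAW", "HEK"),
                                                        unique(f$cell_line)))
  f <- f[order(f$cell_line), ]
  wide <- tidyr::pivot_wider(f, names_from = "cell_line",
                             values_from = "u_p_ref")
  names(wide) <- c("sample_id", paste0("u_p_", tolower(names(wide)[-1])))
  merged <- dplyr::inner_join(
    tibble::tibble(sample_id = records$sample_id, x = records$x,
                   mn_sq = records$mn^2, d_dls = records$d_dls,
                   minus_z = transform_zeta(records$zeta)),
    wide, by = "sample_id"
  )
  cc <- stats::complete.cases(merged)
  if (any(!cc)) {
    message(sum(!cc), " sample(s) dropped from the uptake feature table ",
            "(missing variable or excluded fit)")
  }
  merged[cc, ]
}
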
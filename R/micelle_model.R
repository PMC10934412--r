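# Micellar particle-size model for soap-free emulsion polymerization.
#
# In soap-free emulsion polymerization every initiator-derived charge is the
# start of one chain, and charges sit at the micelle surface, so the surface
# potential tracks the surface charge density and the particle volume the
# product of chains per particle and chain length.  Combining these
# proportionalities gives the working model
#
#     d = k * (-z)^a * Mn^b,   defaults a = b = 1,
#
# with d the diameter (nm), -z the negated zeta potential (mV), Mn the
# number-average molecular weight (kg mol^-1) and k a proportionality
# constant absorbing density, packing and double-layer factors
# (nm mV^-1 mol kg^-1 at the default exponents).

#' Predict particle diameter from zeta potential and molecular weight
#'
#' @param minus_z Negated zeta potential, mV, > 0.
#' @param mn Number-average molecular weight, kg mol^-1, > 0.
#' @param k Proportionality constant, > 0.
#' @param exponents Length-2 numeric `(a, b)`: d = k * (-z)^a * Mn^b.
#' @return Predicted diameter(s), nm; strictly increasing in each argument.
#' @export
predict_diameter <- function(minus_z, mn, k, exponents = c(1, 1)) {
  if (any(minus_z <= 0)) stop("minus_z must be positive", call. = FALSE)
  if (any(mn <= 0)) stop("mn must be positive", call. = FALSE)
  if (any(k <= 0)) stop("k must be positive", call. = FALSE)
  stopifnot(length(exponents) == 2)
  k * minus_z^exponents[1] * mn^exponents[2]
}

#' Root-mean-square error of prediction
#'
#' @param observed,predicted Numeric vectors of equal nonzero length.
#' @return `sqrt(mean((observed - predicted)^2))`, in the units of the
#'   inputs.
#' @export
rmspe <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) == 0) stop("empty input", call. = FALSE)
  sqrt(mean((observed - predicted)^2))
}

#' Calibrate the micellar size model
#'
#' Least-squares fit of the proportionality constant k through the origin
#' (the model has no intercept): k minimizes sum over QC-passing samples of
#' `(d - k * (-z)^a * Mn^b)^2`, with the closed-form solution
#' `k = sum(d u) / sum(u^2)`, `u = (-z)^a Mn^b`.  The in-sample RMSPE is
#' reported on the same subset.
#'
#' @param records Particle records with `mn`, `zeta` and `d_dls`.
#' @param qc Optional QC tibble from [flag_single_particles()]; rows with
#'   `exclude_from_size_model` are dropped (aggregates and non-single
#'   particles distort a hydrodynamic-size model).
#' @param exponents Model exponents `(a, b)` as in [predict_diameter()].
#' @return An object of class `size_model_fit`: `k`, `rmspe` (nm, in
#'   sample), `n_used`, `subset_fraction` (of records with complete
#'   (-z, Mn, d)), `exponents`, and the fitted table in `$data`.
#' @export
calibrate_k <- function(records, qc = NULL, exponents = c(1, 1)) {
  minus_z <- -records$zeta
  complete <- !is.na(minus_z) & !is.na(records$mn) & !is.na(records$d_dls) &
    minus_z > 0 & records$mn > 0
  keep <- complete
  if (!is.null(qc)) {
    excl <- qc$exclude_from_size_model[match(records$sample_id, qc$sample_id)]
    keep <- keep & !(excl %in% TRUE)
  }
  if (sum(keep) < 2) {
    stop("fewer than 2 usable samples for size-model calibration", call. = FALSE)
  }
  u <- minus_z[keep]^exponents[1] * records$mn[keep]^exponents[2]
  d <- records$d_dls[keep]
  k <- sum(d * u) / sum(u^2)
  pred <- k * u
  structure(list(
    k = k,
    rmspe = rmspe(d, pred),
    n_used = sum(keep),
    subset_fraction = sum(keep) / sum(complete),
    exponents = exponents,
    data = tibble::tibble(sample_id = records$sample_id[keep],
                          minus_z = minus_z[keep], mn = records$mn[keep],
                          d_observed = d, d_predicted = pred)
  ), class = "size_model_fit")
}

#' @export
print.size_model_fit <- function(x, ...) {
  cat("Micellar size model d = k * (-z)^", x$exponents[1], " * Mn^",
      x$exponents[2], "\n", sep = "")
  cat(sprintf("  k = %.6g nm mV^-%g (kg mol^-1)^-%g\n",
              x$k, x$exponents[1], x$exponents[2]))
  cat(sprintf("  RMSPE (in-sample) = %.4g nm on n = %d samples (%.0f%% of usable data)\n",
              x$rmspe, x$n_used, 100 * x$subset_fraction))
  invisible(x)
}
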
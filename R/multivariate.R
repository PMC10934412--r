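# Standardized PCA, multiple linear regression with the relative
# variable-impact metric, simple/group-mean correlations, and bivariate
# mean confidence ellipses.

#' Standardize variables (autoscaling)
#'
#' Mean-centers and scales each variable by its sample standard deviation
#' (n - 1), the usual pretreatment before PCA of variables with unlike
#' units.  Rows with missing values are dropped with a message.
#'
#' @param table Data frame holding the variables.
#' @param variables Column names; default all numeric columns.
#' @return A numeric matrix with attributes `"means"` and `"sds"` (the
#'   centering/scaling used) and `"n_dropped"`.
#' @export
standardize <- function(table, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  m <- as.matrix(table[, variables, drop = FALSE])
  cc <- stats::complete.cases(m)
  if (any(!cc)) message(sum(!cc), " row(s) with missing values dropped")
  m <- m[cc, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 complete rows", call. = FALSE)
  means <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(variables[sds == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(m, 2, means, "-"), 2, sds, "/")
  attr(out, "means") <- means
  attr(out, "sds") <- sds
  attr(out, "n_dropped") <- sum(!cc)
  out
}

#' Negate zeta potential
#'
#' Anionic latexes have negative zeta potentials; multivariate analyses
#' here use the transformed value -z so all variables carry positive sign.
#'
#' @param z Zeta potential(s), mV.
#' @return `-z`.
#' @export
transform_zeta <- function(z) -z

#' Principal component analysis of a standardized matrix
#'
#' Eigendecomposition of the correlation matrix (the covariance of the
#' autoscaled data): loadings are unit-norm eigenvectors ordered by
#' decreasing eigenvalue, scores the projections `X %*% loadings`, and the
#' explained fraction each eigenvalue over their sum.  Each component is
#' oriented so its largest-magnitude loading is positive (eigenvector sign
#' is arbitrary; a fixed convention makes loadings comparable across runs).
#'
#' @param x Standardized numeric matrix (see [standardize()]).
#' @return An object of class `pca_result`: `loadings` (variables x
#'   components), `scores` (samples x components), `explained_fraction`,
#'   `eigenvalues`, `variable_names`, plus the `centering_means` /
#'   `scaling_sds` carried on `x` when present.
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows", call. = FALSE)
  n <- nrow(x)
  S <- crossprod(x) / (n - 1)
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  load <- eig$vectors
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  vars <- colnames(x)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(x)))
  dimnames(load) <- list(vars, paste0("PC", seq_len(ncol(load))))
  scores <- x %*% load
  rank_def <- sum(ev < max(ev) * 1e-12)
  structure(list(
    variable_names = vars,
    loadings = load,
    scores = scores,
    eigenvalues = ev,
    explained_fraction = ev / sum(ev),
    n = n,
    rank_deficient_components = rank_def,
    centering_means = attr(x, "means"),
    scaling_sds = attr(x, "sds")
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, n_components = min(2, length(x$eigenvalues)), ...) {
  cat("PCA of", length(x$variable_names), "variables,", x$n, "samples\n")
  hdr <- sprintf("PC%d (%.1f%%)", seq_len(n_components),
                 100 * x$explained_fraction[seq_len(n_components)])
  tab <- round(x$loadings[, seq_len(n_components), drop = FALSE], 2)
  colnames(tab) <- hdr
  print(tab)
  if (x$rank_deficient_components > 0) {
    cat(x$rank_deficient_components, "component(s) carry (numerically) zero variance\n")
  }
  invisible(x)
}

#' Multiple linear regression with relative variable impact
#'
#' Ordinary least squares with intercept on raw-scale (unstandardized)
#' data.  The relative impact of each predictor is
#' `I_v = |beta_j * sd_j| / sum_m |beta_m * sd_m|` — the coefficient times
#' the predictor's sample standard deviation, normalized; the product is
#' unit-free, so I_v does not depend on the units any predictor is recorded
#' in.  Predictors listed in `square` enter as their squares (e.g. Mn^2,
#' which follows from a size model multiplicative in Mn).
#'
#' @param table Data frame with the response and predictors.
#' @param response Response column name.
#' @param predictors Predictor column names (raw scale).
#' @param square Subset of `predictors` to square before fitting; squared
#'   columns are reported with an `_sq` suffix.
#' @param condition_threshold Error when the condition number of the
#'   centered design exceeds this (collinear predictors).
#' @return An object of class `mlr_result`: `intercept`, `coefficients`,
#'   `impact` (I_v, sums to 1), `rmspe` (response units), `r_squared`,
#'   `n_used`, `fitted`, `residuals`.
#' @export
mlr_fit <- function(table, response, predictors, square = character(),
                    condition_threshold = 1e8) {
  stopifnot(response %in% names(table), all(predictors %in% names(table)),
            all(square %in% predictors))
  d <- table[, c(response, predictors)]
  cc <- stats::complete.cases(d)
  if (any(!cc)) message(sum(!cc), " row(s) with missing values dropped")
  d <- d[cc, ]
  p <- length(predictors)
  if (nrow(d) < p + 2) stop("need at least p + 2 complete rows", call. = FALSE)
  X <- as.matrix(d[, predictors, drop = FALSE])
  nm <- predictors
  for (s in square) {
    j <- match(s, predictors)
    X[, j] <- X[, j]^2
    nm[j] <- paste0(s, "_sq")
  }
  colnames(X) <- nm
  kap <- kappa(scale(X, center = TRUE, scale = FALSE), exact = TRUE)
  if (!is.finite(kap) || kap > condition_threshold) {
    stop("collinear predictors: condition number ", format(kap, digits = 3),
         " exceeds ", condition_threshold, call. = FALSE)
  }
  y <- d[[response]]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  beta <- fit$coefficients[-1]
  sds <- apply(X, 2, stats::sd)
  w <- abs(beta * sds)
  res <- fit$residuals
  structure(list(
    response = response,
    intercept = unname(fit$coefficients[1]),
    coefficients = beta,
    impact = w / sum(w),
    rmspe = sqrt(mean(res^2)),
    r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
    n_used = nrow(d),
    fitted = unname(fit$fitted.values),
    residuals = unname(res)
  ), class = "mlr_result")
}

#' @export
print.mlr_result <- function(x, ...) {
  cat("MLR:", x$response, "~", paste(names(x$coefficients), collapse = " + "),
      sprintf("(n = %d)\n", x$n_used))
  tab <- cbind(coefficient = x$coefficients, I_v = round(x$impact, 3))
  print(tab)
  cat(sprintf("  intercept = %.4g, RMSPE = %.4g, R^2 = %.4f\n",
              x$intercept, x$rmspe, x$r_squared))
  invisible(x)
}

#' Simple linear correlation, optionally on group means
#'
#' OLS line through (x, y), with `R^2 = 1 - SS_res / SS_tot`.  With
#' `group_means = TRUE`, x and y are first averaged within the groups given
#' by `group` (e.g. the nominal feed composition), so complementary
#' influences of other variables average out before the fit.
#'
#' @param x,y Numeric vectors of equal length.
#' @param group Grouping key (required when `group_means`).
#' @param group_means Average x and y within groups before fitting.
#' @return A list: `slope`, `intercept`, `r_squared`, `n` (points fitted).
#' @export
simple_fit <- function(x, y, group = NULL, group_means = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (group_means) {
    if (is.null(group)) stop("group is required when group_means = TRUE", call. = FALSE)
    group <- group[keep]
    x <- tapply(x, group, mean)
    y <- tapply(y, group, mean)
    x <- as.numeric(x); y <- as.numeric(y)
  }
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = 1 - ssr / sst,
       n = length(x))
}

#' Confidence ellipse for a bivariate mean
#'
#' Hotelling-T^2 region for the mean of (x, y): the sample covariance
#' scaled by 1/n, with squared Mahalanobis radius
#' `p (n - 1) / (n - p) * qf(level, p, n - p)`, p = 2.  This bounds the
#' mean, not the data cloud.  The trend sign is the sign of the sample
#' correlation, `none` below `trend_min_cor`.
#'
#' @param x,y Numeric vectors, >= 3 points.
#' @param level Confidence level in (0, 1).
#' @param trend_min_cor Minimum |correlation| to call a trend.
#' @return An object of class `mean_ellipse`: `center`, `semi_axes`
#'   (major, minor), `angle` (radians, major axis vs x), `level`,
#'   `trend_sign` (`"positive"`, `"negative"`, `"none"`), `n`.
#' @export
mean_confidence_ellipse <- function(x, y, level = 0.95, trend_min_cor = 0.1) {
  stopifnot(level > 0, level < 1, length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  S <- stats::cov(cbind(x, y))
  # a zero-variance margin is degenerate; perfect correlation is allowed and
  # collapses the minor semi-axis to 0
  if (any(diag(S) == 0)) stop("degenerate covariance", call. = FALSE)
  p <- 2
  c2 <- p * (n - 1) / (n - p) * stats::qf(level, p, n - p)
  eig <- eigen(S / n, symmetric = TRUE)
  semi <- sqrt(pmax(eig$values, 0) * c2)
  rho <- suppressWarnings(stats::cor(x, y))
  trend <- if (is.na(rho) || abs(rho) < trend_min_cor) "none" else {
    if (rho > 0) "positive" else "negative"
  }
  structure(list(
    center = c(x = mean(x), y = mean(y)),
    semi_axes = semi,
    angle = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
    level = level,
    trend_sign = trend,
    n = n
  ), class = "mean_ellipse")
}

#' @export
print.mean_ellipse <- function(x, ...) {
  cat(sprintf("%.1f%% mean confidence ellipse (n = %d)\n", 100 * x$level, x$n))
  cat(sprintf("  center (%.4g, %.4g), semi-axes %.4g / %.4g, angle %.1f deg, trend %s\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
              180 / pi * x$angle, x$trend_sign))
  invisible(x)
}
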
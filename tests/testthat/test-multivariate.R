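test_that("standardize autoscales, is idempotent, and names bad columns", {
  m <- standardize(tibble::tibble(a = c(1, 2, 3)))
  expect_equal(as.numeric(m), c(-1, 0, 1))
  twice <- standardize(tibble::as_tibble(as.data.frame(m)))
  expect_equal(unclass(twice)[, 1], unclass(m)[, 1], ignore_attr = TRUE)
  expect_error(standardize(tibble::tibble(a = rep(2, 4), b = 1:4)),
               "zero-variance.*a")
  expect_message(standardize(tibble::tibble(a = c(1, 2, NA, 4), b = c(1, 5, 2, 9))),
                 "1 row")
  withr::local_seed(1)
  x <- matrix(rnorm(60), 20, 3)
  s <- standardize(as.data.frame(x))
  expect_lt(max(abs(colMeans(s))), 1e-12)
  expect_equal(apply(s, 2, sd), rep(1, 3), ignore_attr = TRUE)
})

test_that("two perfectly correlated variables put all variance on PC1", {
  tab <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  res <- pca(standardize(tab))
  expect_equal(res$explained_fraction, c(1, 0), tolerance = 1e-12)
  expect_equal(res$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(res$rank_deficient_components, 1)
})

test_that("loadings match the characteristic-polynomial oracle on 3-variable problems", {
  for (seed in 1:20) {
    withr::local_seed(seed)
    x <- standardize(as.data.frame(matrix(rnorm(45), 15, 3)))
    res <- pca(x)
    S <- crossprod(x) / (nrow(x) - 1)
    oracle <- eig3_oracle(S)
    expect_equal(res$eigenvalues, oracle$values, tolerance = 1e-8)
    expect_equal(unname(res$loadings), unname(oracle$vectors), tolerance = 1e-8)
  }
})

test_that("PCA satisfies its structural invariants", {
  withr::local_seed(4)
  x <- standardize(as.data.frame(matrix(rnorm(120), 24, 5)))
  res <- pca(x)
  L <- res$loadings
  expect_equal(crossprod(L), diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(res$explained_fraction) <= 1e-12))
  expect_equal(sum(res$explained_fraction), 1)
  # reconstruction with all components retained
  expect_equal(res$scores %*% t(L), unclass(x), tolerance = 1e-8,
               ignore_attr = TRUE)
  # scores are the projections, and prcomp agrees up to the sign convention
  pr <- stats::prcomp(unclass(x), center = FALSE, scale. = FALSE)
  expect_equal(abs(unname(L)), abs(unname(pr$rotation)), tolerance = 1e-8)
  # invariance to variable ordering (up to permutation)
  perm <- c(3, 1, 5, 2, 4)
  res2 <- pca(x[, perm])
  expect_equal(unname(res2$loadings), unname(L[perm, ]), tolerance = 1e-8)
})

test_that("zeta transform is the sign flip and an involution", {
  expect_equal(transform_zeta(-45), 45)
  expect_equal(transform_zeta(0), 0)
  expect_equal(transform_zeta(transform_zeta(c(-3, 7))), c(-3, 7))
})

test_that("MLR matches the normal-equations oracle on random designs", {
  for (seed in 1:10) {
    withr::local_seed(seed)
    tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(90), 30, 3)))
    names(tab) <- c("p1", "p2", "p3")
    tab$y <- 2 + 1.5 * tab$p1 - 3 * tab$p2 + 0.5 * tab$p3 + rnorm(30, 0, 0.3)
    fit <- mlr_fit(tab, "y", c("p1", "p2", "p3"))
    oracle <- normal_eq_coef(tab[, c("p1", "p2", "p3")], tab$y)
    expect_equal(unname(c(fit$intercept, fit$coefficients)), oracle,
                 tolerance = 1e-8)
    # residuals orthogonal to each predictor and the constant
    X <- as.matrix(tab[, c("p1", "p2", "p3")])
    expect_lt(max(abs(crossprod(cbind(1, X), fit$residuals))) /
                sqrt(sum(fit$residuals^2)), 1e-8)
    expect_equal(sum(fit$impact), 1)
  }
})

test_that("variable impact is symmetric for equal standardized effects and unit free", {
  withr::local_seed(2)
  n <- 200
  tab <- tibble::tibble(p1 = rnorm(n), p2 = rnorm(n))
  tab$p1 <- (tab$p1 - mean(tab$p1)) / sd(tab$p1)
  tab$p2 <- as.numeric(stats::lm.fit(cbind(1, tab$p1), tab$p2)$residuals)
  tab$p2 <- tab$p2 / sd(tab$p2)
  tab$y <- 3 * tab$p1 + 3 * tab$p2  # noiseless, uncorrelated, equal effects
  fit <- mlr_fit(tab, "y", c("p1", "p2"))
  expect_equal(unname(fit$impact), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(fit$rmspe, 0, tolerance = 1e-10)
  # rescaling a predictor's units leaves I_v unchanged
  tab2 <- tab; tab2$p1 <- tab2$p1 * 1000
  fit2 <- mlr_fit(tab2, "y", c("p1", "p2"))
  expect_equal(fit2$impact, fit$impact, tolerance = 1e-10)
  # single predictor normalizes to 1
  expect_equal(unname(mlr_fit(tab, "y", "p1")$impact), 1)
})

test_that("squared-predictor transform and collinearity guard work", {
  withr::local_seed(5)
  tab <- tibble::tibble(mn = runif(30, 90, 350), z = rnorm(30))
  tab$y <- 0.01 * tab$mn^2 + 2 * tab$z + rnorm(30, 0, 0.1)
  fit <- mlr_fit(tab, "y", c("mn", "z"), square = "mn")
  expect_named(fit$coefficients, c("mn_sq", "z"))
  expect_equal(unname(fit$coefficients["mn_sq"]), 0.01, tolerance = 1e-3)
  tab$dup <- 2 * tab$mn
  expect_error(mlr_fit(tab, "y", c("mn", "dup")), "collinear")
})

test_that("simple fit recovers lines, nulls, and group means", {
  f <- simple_fit(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  withr::local_seed(10)
  f0 <- simple_fit(rnorm(1000), rnorm(1000))
  expect_lt(f0$r_squared, 0.02)
  # group means: averaging removes within-group scatter
  feed <- rep(c(0, 25, 50, 75, 100), each = 8)
  withr::local_seed(11)
  x <- feed + rnorm(40, 0, 8)
  y <- 0.5 * feed + rnorm(40, 0, 8)
  fg <- simple_fit(x, y, group = feed, group_means = TRUE)
  expect_equal(fg$n, 5)
  expect_gt(fg$r_squared, simple_fit(x, y)$r_squared)
  expect_error(simple_fit(1:2, 1:2), "3 points")
})

test_that("mean confidence ellipses behave like Hotelling regions", {
  withr::local_seed(21)
  x <- rnorm(10000); y <- rnorm(10000)
  e <- mean_confidence_ellipse(x, y, 0.95)
  expect_equal(e$semi_axes[1] / e$semi_axes[2], 1, tolerance = 0.05)
  # closed form for the isotropic case: sqrt(var/n * c2)
  n <- 10000
  c2 <- 2 * (n - 1) / (n - 2) * qf(0.95, 2, n - 2)
  expect_equal(unname(e$semi_axes[1]), sqrt(max(var(x), var(y)) / n * c2),
               tolerance = 0.05)
  # higher level strictly contains lower level
  e999 <- mean_confidence_ellipse(x, y, 0.999)
  expect_true(all(e999$semi_axes > e$semi_axes))
  # degenerate limit: perfect correlation
  ep <- mean_confidence_ellipse(1:50, 2 * (1:50))
  expect_equal(ep$trend_sign, "positive")
  expect_lt(ep$semi_axes[2] / ep$semi_axes[1], 1e-8)
  en <- mean_confidence_ellipse(1:50, -(1:50) + rnorm(50, 0, 1))
  expect_equal(en$trend_sign, "negative")
  expect_error(mean_confidence_ellipse(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(mean_confidence_ellipse(1:10, 1:10, level = 1.2))
})
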
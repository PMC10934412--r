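test_that("load correction scales by solid content and the standard load", {
  expect_equal(correct_load(100, 5, 5, 1), 100)
  expect_equal(correct_load(100, 10, 5, 1), 50)
  expect_equal(correct_load(100), 100)  # p0 defaults to 1 ug/mL, no correction
  expect_equal(correct_load(100, 10, NA, 1), 100)  # missing measured -> theoretical
  expect_equal(correct_load(8, p0 = 2), 4)
  expect_error(correct_load(-1), "positive")
  expect_error(correct_load(10, 5, -2), "positive")
})

test_that("noiseless log-linear data are recovered exactly, R^2 = 1", {
  loads <- c(8, 80, 160)
  m <- tibble::tibble(sample_id = "s", cell_line = "HEK",
                      load_corrected = loads,
                      positive_pct = 50 * log10(loads) + 40)
  fit <- fit_uptake(m)
  expect_equal(fit$u_s, 50, tolerance = 1e-12)
  expect_equal(fit$u_l, 40, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_false(fit$excluded)
  # reference value above 100 is reported capped, raw value retained
  expect_equal(fit$u_p_ref, 100)
  expect_equal(fit$u_p_ref_raw, 50 * 2 + 40)
})

test_that("the fit needs three distinct loads", {
  m <- tibble::tibble(load_corrected = c(8, 8, 80, 80),
                      positive_pct = c(10, 11, 20, 21))
  expect_error(fit_uptake(m), "3 distinct")
  expect_error(fit_uptake(tibble::tibble(load_corrected = rep(8, 5),
                                         positive_pct = 1:5)), "3 distinct")
})

test_that("flat-noise samples are excluded by the R^2 rule", {
  excluded <- vapply(1:200, function(s) {
    withr::local_seed(s)
    m <- tibble::tibble(load_corrected = rep(c(8, 80, 160), each = 3),
                        positive_pct = pmin(100, pmax(0, 50 + rnorm(9, 0, 3))))
    fit_uptake(m)$excluded
  }, TRUE)
  expect_gte(mean(excluded), 0.95)
  # an excluded fit reports no reference uptake
  withr::local_seed(1)
  m <- tibble::tibble(load_corrected = rep(c(8, 80, 160), each = 3),
                      positive_pct = 50 + rnorm(9, 0, 3))
  f <- fit_uptake(m)
  expect_true(f$excluded)
  expect_true(is.na(f$u_p_ref))
})

test_that("uptake fits are equivariant under level shifts and load scaling", {
  withr::local_seed(14)
  loads <- rep(c(8, 80, 160), each = 3)
  up <- 20 * log10(loads) + 10 + rnorm(9, 0, 2)
  base <- fit_uptake(tibble::tibble(load_corrected = loads, positive_pct = up))
  shifted <- fit_uptake(tibble::tibble(load_corrected = loads,
                                       positive_pct = up + 7))
  expect_equal(shifted$u_s, base$u_s, tolerance = 1e-10)
  expect_equal(shifted$u_l, base$u_l + 7, tolerance = 1e-10)
  scaled <- fit_uptake(tibble::tibble(load_corrected = 5 * loads,
                                      positive_pct = up))
  expect_equal(scaled$u_s, base$u_s, tolerance = 1e-10)
  expect_equal(scaled$u_l, base$u_l - base$u_s * log10(5), tolerance = 1e-10)
})

test_that("slope recovery error is small relative to the true spread", {
  p <- synth_params()
  errs <- unlist(lapply(1:5, function(s) {
    lib <- simulate_library(p, seed = 100 + s)
    fits <- fit_uptake_all(lib$uptake, records = lib$records)
    tr <- lib$uptake_truth
    key <- match(paste(fits$sample_id, fits$cell_line),
                 paste(tr$sample_id, tr$cell_line))
    abs(fits$u_s - tr$u_s_true[key])
  }))
  lib <- simulate_library(p, seed = 100)
  spread <- diff(range(lib$uptake_truth$u_s_true))
  expect_gte(length(errs), 200)
  expect_lt(stats::median(errs), 0.1 * spread)
})

test_that("published uptake parameters summarize to the reported cohort mean", {
  ref <- reference_uptake_fits()
  ref$excluded <- is.na(ref$u_p_ref)
  s <- summarize_uptake(ref, "RAW")
  expect_equal(s$n, 20)
  expect_equal(round_half_up(s$mean, 1), 75.4)
  expect_equal(round_half_up(s$sd, 1), 12.1)
  # mean/sd agree with a two-pass oracle on random vectors
  for (seed in 1:5) {
    withr::local_seed(seed)
    v <- runif(30, 0, 100)
    fits <- tibble::tibble(u_p_ref = v, excluded = FALSE)
    s2 <- summarize_uptake(fits)
    o <- mean_sd_oracle(v)
    expect_equal(s2$mean, o$mean, tolerance = 1e-12)
    expect_equal(s2$sd, o$sd, tolerance = 1e-12)
  }
  expect_error(summarize_uptake(tibble::tibble(u_p_ref = 50, excluded = FALSE)),
               "at least 2")
})

test_that("summaries of identical values have zero spread", {
  fits <- tibble::tibble(u_p_ref = rep(80, 4), excluded = FALSE)
  s <- summarize_uptake(fits)
  expect_equal(s$sd, 0)
  expect_equal(s$mean, 80)
})

test_that("the uptake feature table merges fits with records", {
  lib <- simulate_library(synth_params(), seed = 9)
  fits <- fit_uptake_all(lib$uptake, records = lib$records)
  ft <- suppressMessages(uptake_feature_table(fits, lib$records))
  expect_named(ft, c("sample_id", "x", "mn_sq", "d_dls", "minus_z",
                     "u_p_raw", "u_p_hek"))
  # one row per labeled sample minus those with an excluded fit
  n_labeled <- sum(lib$records$labeled)
  n_excluded_samples <- dplyr::n_distinct(fits$sample_id[fits$excluded])
  expect_equal(nrow(ft), n_labeled - n_excluded_samples)
  # Mn enters squared, zeta negated
  i <- match(ft$sample_id, lib$records$sample_id)
  expect_equal(ft$mn_sq, lib$records$mn[i]^2)
  expect_equal(ft$minus_z, -lib$records$zeta[i])
  bad <- fits; bad$sample_id <- paste0("zz", bad$sample_id)
  expect_error(uptake_feature_table(bad, lib$records), "overlap")
})
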
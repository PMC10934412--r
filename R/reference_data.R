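# Bundled reference characterization data for a 48-member
# poly(styrene-co-methyl methacrylate) latex library.

#' Reference DLS/SEM diameter comparison
#'
#' Published-style per-sample comparison of SEM and DLS diameters for the
#' Sty/MMA latex library, with the printed 1-decimal ratio and footnote
#' class (`aggregated`, `over_approximated`, or the agglomerates-only
#' sample without a SEM diameter).  Used to validate the QC stage.
#'
#' @return A tibble: `sample_id`, `d_sem` (nm, `NA` when no single
#'   particles were found), `d_dls` (nm), `r_printed` (1-decimal ratio),
#'   `footnote`.
#' @export
reference_dls_sem <- function() {
  path <- system.file("extdata", "sty_mma_dls_sem_diameters.csv",
                      package = "uptakemva", mustWork = TRUE)
  readr::read_csv(path, na = c("", "-"), show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", d_sem = "d", d_dls = "d",
                    r_printed = "d", footnote = "c"))
}

#' Reference cellular-uptake fit parameters
#'
#' Per-sample logarithmic-uptake parameters (slope `u_s`, level `u_l`),
#' the reported percent particle-positive cells at a 100 ug mL^-1 load
#' (`u_p_ref`; values computed above 100 were capped at 100; `NA` for fits
#' with R^2 < 0.8) and the replicate-derived expected error `er`, for RAW
#' and HEK cells.  Used to validate the uptake summaries.
#'
#' @return A tibble: `sample_id`, `cell_line`, `u_s`, `u_l`, `u_p_ref`,
#'   `er`.
#' @export
reference_uptake_fits <- function() {
  path <- system.file("extdata", "sty_mma_uptake_parameters.csv",
                      package = "uptakemva", mustWork = TRUE)
  readr::read_csv(path, na = c("", "-"), show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", cell_line = "c", u_s = "d", u_l = "d",
                    u_p_ref = "d", er = "d"))
}
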
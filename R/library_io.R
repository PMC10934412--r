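# Data model and tidy-table I/O for particle libraries and uptake measurements.

# Canonical snake_case schema for the particle-library table.  The alias map
# accepts the shorthand column names commonly used in published tables.
.library_numeric_cols <- c(
  "sty_feed", "conc_factor", "monomer_conc", "x", "mn", "d_dls", "pdi",
  "d_sem", "zeta", "solid_theoretical", "solid_measured"
)
.library_cols <- c("sample_id", .library_numeric_cols[1:3], "labeled",
                   .library_numeric_cols[-(1:3)])

.library_aliases <- c(
  id = "sample_id", ID = "sample_id",
  x = "x", Mn = "mn", d = "d_dls", PdI = "pdi", z = "zeta",
  solid_content_theoretical = "solid_theoretical",
  solid_content_measured = "solid_measured"
)

.uptake_cols <- c("sample_id", "cell_line", "load_p", "positive_pct",
                  "load_corrected")
.cell_lines <- c("RAW", "HEK")

#' Convert a concentration factor to a monomer concentration
#'
#' Library members are synthesized on a relative concentration scale; a
#' concentration factor of 1.0 corresponds to the highest monomer
#' concentration used, taken as 2.625 mol L^-1 so that factor 0.8 maps to
#' the reported 2.10 mmol mL^-1.
#'
#' @param conc_factor Dimensionless concentration factor(s), > 0.
#' @param base Monomer concentration at factor 1.0, mol L^-1.
#' @return Monomer concentration(s) in mol L^-1.
#' @export
conc_factor_to_molar <- function(conc_factor, base = 2.625) {
  stopifnot(is.numeric(conc_factor), all(conc_factor > 0), base > 0)
  conc_factor * base
}

#' Parse Sty[X]MMA[Y][Z] sample identifiers
#'
#' Library members are denoted `Sty<X>MMA<Y><Z>` where `<X>` is the molar
#' percentage of styrene in the monomer feed, `<Y>` the concentration factor
#' and `<Z>` the labelling index (`N` nonlabeled, `F` fluorescence-labeled).
#'
#' @param id Character vector of sample identifiers.
#' @return A tibble with columns `sty_feed` (mol %), `conc_factor` and
#'   `labeled` (logical, `TRUE` for `F`).
#' @examples
#' parse_sample_id("Sty25MMA0.8F")
#' @seealso [format_sample_id()]
#' @export
parse_sample_id <- function(id) {
  stopifnot(is.character(id))
  pat <- "^Sty([0-9]+)MMA([0-9]+(?:\\.[0-9]+)?)([NF])$"
  ok <- grepl(pat, id)
  if (!all(ok)) {
    bad <- id[!ok][1]
    # name the offending token: first component that fails its sub-pattern
    token <- if (!grepl("^Sty", bad)) {
      "feed prefix 'Sty<int>'"
    } else if (!grepl("^Sty[0-9]+MMA", bad)) {
      "concentration token 'MMA<decimal>'"
    } else {
      "label suffix 'N' or 'F'"
    }
    stop("malformed sample id '", bad, "': expected Sty<int>MMA<decimal><N|F>, ",
         "offending token: ", token, call. = FALSE)
  }
  tibble::tibble(
    sty_feed = as.numeric(sub(pat, "\\1", id)),
    conc_factor = as.numeric(sub(pat, "\\2", id)),
    labeled = sub(pat, "\\3", id) == "F"
  )
}

#' Format a design point as a Sty[X]MMA[Y][Z] identifier
#'
#' Inverse of [parse_sample_id()]: `format_sample_id(parse_sample_id(id))`
#' reproduces `id` for every well-formed identifier.
#'
#' @param sty_feed Mol % styrene in the feed, or a data frame with columns
#'   `sty_feed`, `conc_factor`, `labeled`.
#' @param conc_factor Concentration factor.
#' @param labeled Logical; `TRUE` formats as `F`, `FALSE` as `N`.
#' @return Character vector of identifiers.
#' @export
format_sample_id <- function(sty_feed, conc_factor = NULL, labeled = NULL) {
  if (is.data.frame(sty_feed)) {
    d <- sty_feed
    sty_feed <- d$sty_feed; conc_factor <- d$conc_factor; labeled <- d$labeled
  }
  stopifnot(is.numeric(sty_feed), is.numeric(conc_factor), is.logical(labeled))
  # at least one decimal place, trailing zeros beyond it dropped ("1.0", "0.85")
  fac <- sub("0+$", "", sprintf("%.6f", conc_factor))
  fac <- ifelse(grepl("\\.$", fac), paste0(fac, "0"), fac)
  sprintf("Sty%dMMA%s%s", as.integer(sty_feed), fac, ifelse(labeled, "F", "N"))
}

.detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

.read_raw_table <- function(path, delim) {
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = character(), progress = FALSE,
                    show_col_types = FALSE, trim_ws = TRUE)
}

# coerce a character column to numeric; "" and "-" are missing; anything else
# non-numeric is an error that names the column and the offending row
.to_numeric <- function(col, name) {
  miss <- is.na(col) | col %in% c("", "-", "NA")
  out <- suppressWarnings(as.numeric(col))
  bad <- which(!miss & is.na(out))
  if (length(bad) > 0) {
    stop("non-numeric value '", col[bad[1]], "' in column '", name,
         "' at row ", bad[1], call. = FALSE)
  }
  out[miss] <- NA_real_
  out
}

.canonicalize_headers <- function(nms, canonical, aliases) {
  mapped <- ifelse(nms %in% names(aliases), unname(aliases[nms]), nms)
  unknown <- setdiff(mapped, canonical)
  if (length(unknown) > 0) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  mapped
}

#' Read a particle-library table
#'
#' Reads a delimited table of per-sample particle characteristics into the
#' canonical schema (`sample_id`, `sty_feed`, `conc_factor`, `monomer_conc`,
#' `labeled`, `x`, `mn`, `d_dls`, `pdi`, `d_sem`, `zeta`,
#' `solid_theoretical`, `solid_measured`).  Shorthand headers (`x`, `Mn`,
#' `d`, `PdI`, `z`) are accepted.  Empty cells and `"-"` are missing values,
#' as used for samples without single-particle SEM diameters.
#'
#' @param path Path to a CSV (default) or TSV file; the delimiter is chosen
#'   from the extension unless `delim` is given.
#' @param delim Optional field delimiter overriding extension detection.
#' @param check_zeta Assert that measured zeta potentials are non-positive
#'   (sulfate-initiated latexes are anionic).  Set `FALSE` for other
#'   chemistries.
#' @return A tibble of particle records, one row per sample.
#' @export
read_library_table <- function(path, delim = NULL, check_zeta = TRUE) {
  raw <- .read_raw_table(path, .detect_delim(path, delim))
  if (nrow(raw) == 0) {
    warning("empty library table: ", path, call. = FALSE)
    out <- tibble::as_tibble(stats::setNames(
      rep(list(numeric(0)), length(.library_cols)), .library_cols))
    out$sample_id <- character(0); out$labeled <- logical(0)
    return(out[.library_cols])
  }
  names(raw) <- .canonicalize_headers(names(raw), .library_cols, .library_aliases)
  out <- tibble::tibble(.rows = nrow(raw))
  out$sample_id <- if ("sample_id" %in% names(raw)) raw$sample_id else NA_character_
  for (nm in .library_numeric_cols) {
    out[[nm]] <- if (nm %in% names(raw)) .to_numeric(raw[[nm]], nm) else NA_real_
  }
  out$labeled <- if ("labeled" %in% names(raw)) {
    tolower(raw$labeled) %in% c("true", "t", "1", "f.labeled", "yes")
  } else if (all(!is.na(out$sample_id))) {
    parse_sample_id(out$sample_id)$labeled
  } else {
    NA
  }
  validate_particle_records(out[.library_cols], check_zeta = check_zeta)
}

#' Validate particle records against the schema invariants
#'
#' @param records Particle-record tibble in the canonical schema.
#' @param check_zeta Assert `zeta <= 0` where present.
#' @return `records`, invisibly unchanged, if all invariants hold.
#' @export
validate_particle_records <- function(records, check_zeta = TRUE) {
  chk <- function(cond, msg) if (any(cond, na.rm = TRUE)) stop(msg, call. = FALSE)
  chk(records$x < 0 | records$x > 100, "x must lie in [0, 100] mol %")
  chk(records$mn <= 0, "Mn must be positive")
  chk(records$d_dls <= 0, "d_dls must be positive")
  chk(records$pdi < 0, "PdI must be non-negative")
  chk(records$d_sem <= 0, "d_sem must be positive when present")
  chk(records$conc_factor <= 0, "conc_factor must be positive")
  if (isTRUE(check_zeta)) {
    chk(records$zeta > 0, "zeta must be <= 0 for this chemistry (set check_zeta = FALSE to disable)")
  }
  records
}

#' Write a particle-library table
#'
#' Writes the canonical schema; missing values become empty cells.
#'
#' @param records Particle-record tibble.
#' @param path Output path; delimiter chosen from the extension.
#' @param delim Optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_library_table <- function(records, path, delim = NULL) {
  readr::write_delim(records[, intersect(.library_cols, names(records))], path,
                     delim = .detect_delim(path, delim), na = "")
  invisible(path)
}

#' Read a cellular-uptake table
#'
#' Reads per-measurement uptake data: `sample_id`, `cell_line`
#' (`RAW`/`HEK`), `load_p` (particle load, ug mL^-1), `positive_pct`
#' (percent particle-positive cells) and optionally `load_corrected`
#' (solid-content-corrected dimensionless load).  Replicate rows for the
#' same (sample, cell line, load) are kept and noted in a message.
#'
#' @inheritParams read_library_table
#' @return A tibble of uptake measurements.
#' @export
read_uptake_table <- function(path, delim = NULL) {
  raw <- .read_raw_table(path, .detect_delim(path, delim))
  if (nrow(raw) == 0) {
    warning("empty uptake table: ", path, call. = FALSE)
    return(tibble::tibble(sample_id = character(0), cell_line = character(0),
                          load_p = numeric(0), positive_pct = numeric(0),
                          load_corrected = numeric(0)))
  }
  names(raw) <- .canonicalize_headers(names(raw), .uptake_cols,
                                      c(id = "sample_id", ID = "sample_id"))
  need <- c("sample_id", "cell_line", "load_p", "positive_pct")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("uptake table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = raw$sample_id,
    cell_line = raw$cell_line,
    load_p = .to_numeric(raw$load_p, "load_p"),
    positive_pct = .to_numeric(raw$positive_pct, "positive_pct"),
    load_corrected = if ("load_corrected" %in% names(raw)) {
      .to_numeric(raw$load_corrected, "load_corrected")
    } else {
      NA_real_
    }
  )
  validate_uptake_measurements(out)
}

#' Validate uptake measurements against the schema invariants
#'
#' @param measurements Uptake-measurement tibble.
#' @return `measurements`, unchanged, if valid.
#' @export
validate_uptake_measurements <- function(measurements) {
  bad_cell <- setdiff(unique(measurements$cell_line), .cell_lines)
  if (length(bad_cell) > 0) {
    stop("unknown cell_line label(s): ", paste(bad_cell, collapse = ", "),
         " (expected ", paste(.cell_lines, collapse = "/"), ")", call. = FALSE)
  }
  if (any(measurements$load_p <= 0, na.rm = TRUE)) {
    stop("load_p must be positive", call. = FALSE)
  }
  oob <- which(measurements$positive_pct < 0 | measurements$positive_pct > 100)
  if (length(oob) > 0) {
    stop("positive_pct outside [0, 100] at row ", oob[1], ": ",
         measurements$positive_pct[oob[1]], call. = FALSE)
  }
  dup <- duplicated(measurements[, c("sample_id", "cell_line", "load_p")])
  if (any(dup)) {
    message(sum(dup), " replicate (sample, cell line, load) row(s) kept")
  }
  measurements
}

#' Write a cellular-uptake table
#'
#' @param measurements Uptake-measurement tibble.
#' @inheritParams write_library_table
#' @return `path`, invisibly.
#' @export
write_uptake_table <- function(measurements, path, delim = NULL) {
  readr::write_delim(measurements[, intersect(.uptake_cols, names(measurements))],
                     path, delim = .detect_delim(path, delim), na = "")
  invisible(path)
}
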
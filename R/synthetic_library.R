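# Synthetic particle libraries with the statistical structure the analysis
# assumes: styrene enrichment in the copolymer, Mn rising with monomer
# concentration and falling with Sty feed, zeta-potential magnitude tracking
# concentration, diameters from the micellar forward model, sporadic DLS
# aggregation, and logarithmic dose-uptake with composition-dependent
# parameters per cell line.

#' Parameters of the synthetic library generator
#'
#' Returns the default generator parameterization; any field can be
#' overridden by name.  Defaults define the emulated study conditions: a
#' 48-member Sty/MMA library (5 feeds x 5 concentration factors x two
#' labelling states minus two gaps), triplicate uptake measurements at
#' loads 8/80/160 ug mL^-1, and effect sizes in realistic soap-free
#' emulsion ranges (Mn ~90-350 kg mol^-1, -z ~25-46 mV, d ~150-800 nm).
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `synth_params`.
#' @details Key fields:
#' * `enrichment`: Mayo-Lewis-type enrichment factor E in
#'   x/100 = E f / (E f + 1 - f) with f the feed fraction; the default 7/3
#'   puts ~70 mol % Sty in the copolymer at 50 mol % feed.
#' * `mn_base`, `mn_slope_conc`, `mn_slope_feed`, `mn_noise_sd`: Mn
#'   (kg mol^-1) = base + slope_conc * c + slope_feed * (feed/100) + noise.
#' * `zeta_base`, `zeta_slope_conc`, `zeta_noise_sd`: -z (mV) =
#'   base + slope * c + noise.
#' * `k_true`: micellar proportionality constant, nm mV^-1 mol kg^-1.
#' * `n_poly_scale`: scale of the latent chains-per-particle count
#'   n_poly = scale * (-z) * d^2 (surface-charge bookkeeping, truth table
#'   only).
#' * `aggregate_prob`, `aggregate_range`: probability of DLS aggregation
#'   and the uniform range of the diameter inflation factor.
#' * `dls_noise_sdlog`: multiplicative lognormal noise on d(DLS).
#' * `sem_round_nm`: reading precision of SEM diameters (nm; 0 = exact).
#' * `pdi_*`: polydispersity baseline, concentration slope, noise and the
#'   aggregation-linked shift.
#' * `solid_*`, `low_solid_prob`, `low_solid_ratio`: measured/theoretical
#'   solid-content ratio model.
#' * `uptake`: per-cell-line linear maps x -> (u_S, u_L); RAW is high with
#'   weak composition dependence (phagocytic, unspecific), HEK rises
#'   steeply with styrene content.
#' * `uptake_noise_sd` (% points), `n_replicates`, `loads` (ug mL^-1).
#' @export
synth_params <- function(...) {
  p <- list(
    enrichment = 7 / 3,
    x_noise_sd = 2,
    mn_base = 150, mn_slope_conc = 80, mn_slope_feed = -100, mn_noise_sd = 15,
    zeta_base = 20, zeta_slope_conc = 10, zeta_noise_sd = 2,
    k_true = 0.05,
    n_poly_scale = 1,
    aggregate_prob = 0.1, aggregate_range = c(1.5, 5),
    dls_noise_sdlog = 0.08,
    sem_round_nm = 50,
    pdi_base = 0.06, pdi_slope_conc = 0.04, pdi_noise_sd = 0.02,
    pdi_aggregate_shift = 0.25, pdi_aggregate_slope = 0.1,
    solid_scale = 100,
    solid_ratio_mean = 0.9, solid_ratio_sd = 0.08,
    low_solid_prob = 0.05, low_solid_ratio = 0.3,
    conc_base = 2.625,
    uptake = list(
      RAW = c(s0 = 28, s_x = 0.04, l0 = 18, l_x = 0.02),
      HEK = c(s0 = 15, s_x = 0.20, l0 = 5, l_x = 0.06)
    ),
    uptake_noise_sd = 3,
    n_replicates = 3,
    loads = c(8, 80, 160),
    p0 = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) {
    stop("unknown synth_params field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(over)] <- over
  sds <- c(p$x_noise_sd, p$mn_noise_sd, p$zeta_noise_sd, p$dls_noise_sdlog,
           p$pdi_noise_sd, p$solid_ratio_sd, p$uptake_noise_sd)
  stopifnot(all(sds >= 0), p$aggregate_prob >= 0, p$aggregate_prob <= 1,
            p$k_true > 0, p$n_poly_scale > 0, all(p$loads > 0),
            p$n_replicates >= 1)
  structure(p, class = "synth_params")
}

#' Noise-free generator parameters
#'
#' Convenience wrapper setting every noise standard deviation and the
#' aggregation/low-solid probabilities to zero, for forward-inverse
#' consistency checks.
#'
#' @param ... Further overrides passed to [synth_params()].
#' @return A `synth_params` object.
#' @export
synth_params_noiseless <- function(...) {
  synth_params(x_noise_sd = 0, mn_noise_sd = 0, zeta_noise_sd = 0,
               dls_noise_sdlog = 0, pdi_noise_sd = 0, solid_ratio_sd = 0,
               uptake_noise_sd = 0, aggregate_prob = 0, low_solid_prob = 0,
               sem_round_nm = 0, ...)
}

#' Generate a factorial particle-library design
#'
#' Full factorial grid of feed ratios, concentration factors and labelling
#' states, minus an optional drop list.  The defaults reproduce the
#' 48-member library layout: feeds 0/25/50/75/100 mol %, factors
#' 0.2-1.0, both labels, with the two Sty0 points at factor 1.0 absent.
#'
#' @param feeds Mol % styrene in the feed (0-100).
#' @param factors Concentration factors (> 0).
#' @param labels `"both"`, `"N"` (nonlabeled only) or `"F"` (labeled only).
#' @param drop Sample ids removed from the grid.
#' @param conc_base Monomer concentration at factor 1.0, mol L^-1.
#' @return A tibble of design points with `sample_id`, `sty_feed`,
#'   `conc_factor`, `monomer_conc` and `labeled`; deterministic given its
#'   inputs.
#' @export
generate_design <- function(feeds = c(0, 25, 50, 75, 100),
                            factors = seq(0.2, 1, by = 0.2),
                            labels = c("both", "N", "F"),
                            drop = c("Sty0MMA1.0N", "Sty0MMA1.0F"),
                            conc_base = 2.625) {
  labels <- match.arg(labels)
  if (length(feeds) == 0) stop("feeds must be nonempty", call. = FALSE)
  if (length(factors) == 0) stop("factors must be nonempty", call. = FALSE)
  stopifnot(all(feeds >= 0 & feeds <= 100), all(factors > 0))
  lab <- switch(labels, both = c(FALSE, TRUE), N = FALSE, F = TRUE)
  grid <- expand.grid(labeled = lab, conc_factor = factors, sty_feed = feeds,
                      KEEP.OUT.ATTRS = FALSE)
  d <- tibble::tibble(
    sample_id = format_sample_id(grid$sty_feed, grid$conc_factor, grid$labeled),
    sty_feed = grid$sty_feed,
    conc_factor = grid$conc_factor,
    monomer_conc = conc_factor_to_molar(grid$conc_factor, conc_base),
    labeled = grid$labeled
  )
  d <- d[!(d$sample_id %in% drop), ]
  d <- d[order(d$sty_feed, d$conc_factor, d$labeled), ]
  tibble::as_tibble(d)
}

# Mayo-Lewis-shaped enrichment of styrene in the copolymer, pinned at the
# homopolymer endpoints; E > 1 enriches styrene.
.enrichment_curve <- function(feed, E) {
  f <- feed / 100
  100 * E * f / (E * f + (1 - f))
}

# All randomness flows from one integer seed via fixed offsets:
# physicochemical stage uses `seed`, uptake stage `seed + 1`, replicate
# libraries in recovery studies use consecutive seeds from the caller.
.set_stage_seed <- function(seed, offset = 0L) {
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
}

#' Simulate physicochemical characterization of a particle library
#'
#' Draws copolymer composition, molecular weight, zeta potential, solid
#' contents and DLS/SEM diameters for each design point.  The true diameter
#' follows the micellar forward model `d = k_true * (-z) * Mn` evaluated at
#' the realized (noisy) Mn and -z; the SEM diameter is the true diameter
#' rounded to 50 nm (micrograph reading precision) and the DLS diameter
#' carries multiplicative lognormal noise, inflated by a factor drawn from
#' `aggregate_range` when the sample aggregates in the cuvette.
#'
#' @param designs Design tibble from [generate_design()].
#' @param params A [synth_params()] object.
#' @param seed Integer seed for this stage.
#' @return A list with `records` (particle records in the canonical schema)
#'   and `truth` (row-aligned latent values: `d_true`, `aggregated`,
#'   `aggregate_factor`, `n_poly`).
#' @export
simulate_physicochem <- function(designs, params = synth_params(), seed = 1) {
  stopifnot(inherits(params, "synth_params"), nrow(designs) > 0)
  .set_stage_seed(seed, 0L)
  n <- nrow(designs)
  feed <- designs$sty_feed
  conc <- designs$monomer_conc

  x <- .enrichment_curve(feed, params$enrichment)
  interior <- feed > 0 & feed < 100
  x[interior] <- pmin(100, pmax(0, x[interior] +
                                  stats::rnorm(sum(interior), 0, params$x_noise_sd)))

  mn <- params$mn_base + params$mn_slope_conc * conc +
    params$mn_slope_feed * (feed / 100) +
    stats::rnorm(n, 0, params$mn_noise_sd)
  mn <- pmax(mn, 1)

  minus_z <- params$zeta_base + params$zeta_slope_conc * conc +
    stats::rnorm(n, 0, params$zeta_noise_sd)
  minus_z <- pmax(minus_z, 0.1)

  d_true <- params$k_true * minus_z * mn
  # micrograph diameters are read to sem_round_nm precision; 0 disables
  d_sem <- if (params$sem_round_nm > 0) {
    pmax(params$sem_round_nm, round(d_true / params$sem_round_nm) * params$sem_round_nm)
  } else {
    d_true
  }

  aggregated <- stats::runif(n) < params$aggregate_prob
  agg_factor <- ifelse(aggregated,
                       stats::runif(n, params$aggregate_range[1],
                                    params$aggregate_range[2]), 1)
  d_dls <- d_true * exp(stats::rnorm(n, 0, params$dls_noise_sdlog)) * agg_factor

  pdi <- params$pdi_base + params$pdi_slope_conc * designs$conc_factor +
    stats::rnorm(n, 0, params$pdi_noise_sd) +
    ifelse(aggregated,
           params$pdi_aggregate_shift +
             params$pdi_aggregate_slope * (agg_factor - params$aggregate_range[1]),
           0)
  pdi <- pmax(pdi, 0)

  solid_theoretical <- params$solid_scale * conc
  low <- stats::runif(n) < params$low_solid_prob
  ratio <- ifelse(low, params$low_solid_ratio,
                  pmin(1.1, pmax(0.5, stats::rnorm(n, params$solid_ratio_mean,
                                                   params$solid_ratio_sd))))
  solid_measured <- solid_theoretical * ratio

  records <- tibble::tibble(
    sample_id = designs$sample_id,
    sty_feed = feed, conc_factor = designs$conc_factor, monomer_conc = conc,
    labeled = designs$labeled,
    x = x, mn = mn, d_dls = d_dls, pdi = pdi, d_sem = d_sem,
    zeta = -minus_z,
    solid_theoretical = solid_theoretical, solid_measured = solid_measured
  )
  truth <- tibble::tibble(
    sample_id = designs$sample_id,
    d_true = d_true,
    aggregated = aggregated,
    aggregate_factor = agg_factor,
    n_poly = params$n_poly_scale * minus_z * d_true^2
  )
  list(records = validate_particle_records(records), truth = truth)
}

#' Simulate cellular-uptake measurements
#'
#' For each (labeled) particle record and cell line, draws percent
#' particle-positive cells at each particle load from the logarithmic
#' uptake model `U_P = u_S * log10(p_tilde) + u_L + noise`, clipped to
#' [0, 100].  The slope and level depend linearly on the styrene content x
#' through the per-cell-line maps in `params$uptake`; loads are corrected
#' by the sample's measured/theoretical solid-content ratio.
#'
#' @param records Particle records carrying `x` (and solid contents).
#' @param params A [synth_params()] object.
#' @param loads Particle loads, ug mL^-1 (default `params$loads`).
#' @param seed Integer seed; stage offset +1 from the physicochemical stage.
#' @param labeled_only Restrict to fluorescence-labeled records (uptake is
#'   only measurable with a label).
#' @return A list with `measurements` (uptake tibble incl. `load_corrected`
#'   and `replicate`) and `truth` (one row per sample x cell line with
#'   `u_s_true`, `u_l_true`).
#' @export
simulate_uptake <- function(records, params = synth_params(),
                            loads = params$loads, seed = 1,
                            labeled_only = TRUE) {
  stopifnot(inherits(params, "synth_params"))
  if (any(loads <= 0)) stop("particle loads must be positive", call. = FALSE)
  .set_stage_seed(seed, 1L)
  recs <- if (labeled_only) records[records$labeled %in% TRUE, ] else records
  if (nrow(recs) == 0) stop("no (labeled) records to simulate uptake for",
                            call. = FALSE)

  truth <- do.call(rbind, lapply(names(params$uptake), function(cl) {
    u <- params$uptake[[cl]]
    tibble::tibble(
      sample_id = recs$sample_id,
      cell_line = cl,
      u_s_true = unname(u["s0"] + u["s_x"] * recs$x),
      u_l_true = unname(u["l0"] + u["l_x"] * recs$x)
    )
  }))
  truth <- tibble::as_tibble(truth)

  solid_ratio <- ifelse(is.na(recs$solid_measured) | is.na(recs$solid_theoretical),
                        1, recs$solid_measured / recs$solid_theoretical)
  grid <- expand.grid(replicate = seq_len(params$n_replicates),
                      load_p = loads, row = seq_len(nrow(recs)),
                      cell_line = names(params$uptake),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- match(paste(recs$sample_id[grid$row], grid$cell_line),
               paste(truth$sample_id, truth$cell_line))
  ptilde <- correct_load(grid$load_p,
                         solid_theoretical = 1,
                         solid_measured = solid_ratio[grid$row],
                         p0 = params$p0)
  up <- truth$u_s_true[key] * log10(ptilde) + truth$u_l_true[key] +
    stats::rnorm(nrow(grid), 0, params$uptake_noise_sd)
  measurements <- tibble::tibble(
    sample_id = recs$sample_id[grid$row],
    cell_line = grid$cell_line,
    load_p = grid$load_p,
    load_corrected = ptilde,
    positive_pct = pmin(100, pmax(0, up)),
    replicate = grid$replicate
  )
  ord <- order(measurements$sample_id, measurements$cell_line,
               measurements$load_p, measurements$replicate)
  list(measurements = measurements[ord, ], truth = truth)
}

#' Simulate a complete synthetic library
#'
#' Convenience wrapper chaining [generate_design()],
#' [simulate_physicochem()] and [simulate_uptake()] under one seed.
#'
#' @param params A [synth_params()] object.
#' @param seed Integer master seed.
#' @param ... Passed to [generate_design()].
#' @return A list with `design`, `records`, `truth` (physicochemical),
#'   `uptake` (measurements) and `uptake_truth`.
#' @export
simulate_library <- function(params = synth_params(), seed = 1, ...) {
  design <- generate_design(conc_base = params$conc_base, ...)
  phys <- simulate_physicochem(design, params, seed = seed)
  upt <- simulate_uptake(phys$records, params, seed = seed)
  list(design = design, records = phys$records, truth = phys$truth,
       uptake = upt$measurements, uptake_truth = upt$truth)
}
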
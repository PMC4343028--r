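#' Parameters of one simulated cell population
#'
#' Intensity is modelled as a truncated lognormal: `tfi_scale` is the
#' geometric mean in arbitrary fluorescence units, `tfi_cv` the coefficient
#' of variation (the log-scale SD is `sqrt(log(1 + cv^2))`), and the draw is
#' truncated at `truncation_sd` log-SDs on both sides. Hard truncation is
#' deliberate: it makes the empty interval between two populations an exact
#' structural guarantee, not an asymptotic one, so gap-based gating can be
#' tested against exact zeros.
#'
#' @param label population label carried into the ground-truth column.
#' @param proportion mixture proportion in (0, 1].
#' @param tfi_scale geometric mean TFI (> 0).
#' @param tfi_cv coefficient of variation (default 0.15).
#' @param genome optional [genome_spec()].
#' @param truncation_sd truncation half-width in log-SDs (default 3).
#' @return A `population_spec`.
#' @export
population_spec <- function(label, proportion, tfi_scale, tfi_cv = 0.15,
                            genome = NULL, truncation_sd = 3) {
  stopifnot_number(proportion, "proportion", positive = TRUE)
  if (proportion > 1) {
    abort_cometcal("`proportion` must be in (0, 1]", "cometcal_parameter_error")
  }
  stopifnot_number(tfi_scale, "tfi_scale", positive = TRUE)
  stopifnot_number(tfi_cv, "tfi_cv", positive = TRUE)
  stopifnot_number(truncation_sd, "truncation_sd", positive = TRUE)
  structure(list(label = as.character(label), proportion = proportion,
                 tfi_scale = tfi_scale, tfi_cv = tfi_cv, genome = genome,
                 truncation_sd = truncation_sd),
            class = "population_spec")
}

#' Saturating radiation damage model
#'
#' The expected Tail %DNA at dose d is `100 * (1 - exp(-(b0 + beta * d)))`
#' with `b0 = -log(1 - baseline_td / 100)`: linear in dose at low doses
#' (initial slope about `100 * beta` %TD per Gy) and saturating towards
#' 100%, reproducing the loss of linearity above ~80 %TD. Per-cell Tail
#' %DNA is drawn from a beta distribution on \[0, 100\] centered on the
#' expectation with concentration `cell_dispersion`, so the \[0, 100\] bound
#' is structural, not clipped. Tail Moment is emitted as
#' `tm_tail_scale * TD^2 / 100` — tail fraction times a tail length growing
#' proportionally with TD; when `tm_tail_scale` is `NULL` it is calibrated
#' analytically so the expected control-cell TM equals `target_control_tm`
#' (default 2.35, the middle of the 2.2-2.5 band typical of undamaged
#' testicular classes).
#'
#' @param baseline_td expected %TD at 0 Gy (default 2).
#' @param beta per-Gy rate (> 0).
#' @param cell_dispersion beta-distribution concentration (> 0, default 200).
#' @param tm_tail_scale tail-length surrogate scale, or `NULL` to calibrate.
#' @param target_control_tm control-cell mean TM used for the calibration.
#' @return A `damage_model`.
#' @export
damage_model <- function(baseline_td = 2, beta = 0.06, cell_dispersion = 200,
                         tm_tail_scale = NULL, target_control_tm = 2.35) {
  stopifnot_number(baseline_td, "baseline_td", positive = TRUE)
  if (baseline_td >= 100) {
    abort_cometcal("`baseline_td` must be < 100", "cometcal_parameter_error")
  }
  stopifnot_number(beta, "beta", positive = TRUE)
  stopifnot_number(cell_dispersion, "cell_dispersion", positive = TRUE)
  if (is.null(tm_tail_scale)) {
    # E[TM] = s * E[TD^2] / 100 with TD = 100 B, B ~ Beta(mean p, conc c)
    p <- baseline_td / 100
    var_td <- 1e4 * p * (1 - p) / (cell_dispersion + 1)
    tm_tail_scale <- target_control_tm * 100 / (baseline_td^2 + var_td)
  }
  stopifnot_number(tm_tail_scale, "tm_tail_scale", positive = TRUE)
  structure(list(baseline_td = baseline_td, beta = beta,
                 cell_dispersion = cell_dispersion,
                 b0 = -log(1 - baseline_td / 100),
                 tm_tail_scale = tm_tail_scale),
            class = "damage_model")
}

#' Expected Tail %DNA at a dose
#'
#' @param model a [damage_model()].
#' @param dose_gy dose(s) in Gy.
#' @return Expected %TD, same length as `dose_gy`.
#' @export
expected_td <- function(model, dose_gy) {
  100 * (1 - exp(-(model$b0 + model$beta * dose_gy)))
}

#' Rate constant reaching a target %TD at a calibration dose
#'
#' Solves `expected_td(model, dose) = td` for `beta`; used e.g. to place the
#' human-lymphocyte curve at 85 %TD by 15 Gy, inside the saturation regime.
#'
#' @param baseline_td %TD at 0 Gy.
#' @param dose_gy calibration dose (> 0).
#' @param td target %TD at that dose (baseline < td < 100).
#' @return beta (per Gy).
#' @export
beta_for_target_td <- function(baseline_td, dose_gy, td) {
  stopifnot_number(dose_gy, "dose_gy", positive = TRUE)
  if (td <= baseline_td || td >= 100) {
    abort_cometcal("`td` must lie strictly between baseline_td and 100",
                   "cometcal_parameter_error")
  }
  b0 <- -log(1 - baseline_td / 100)
  (-log(1 - td / 100) - b0) / dose_gy
}

# core draw, no seeding: callers own the RNG stream
sim_population_core <- function(spec, model, dose_gy, n) {
  sigma <- sqrt(log(1 + spec$tfi_cv^2))
  t <- spec$truncation_sd
  u <- stats::runif(n, stats::pnorm(-t), stats::pnorm(t))
  tfi <- spec$tfi_scale * exp(sigma * stats::qnorm(u))
  p <- expected_td(model, dose_gy) / 100
  td <- 100 * stats::rbeta(n, p * model$cell_dispersion,
                           (1 - p) * model$cell_dispersion)
  tm <- model$tm_tail_scale * td^2 / 100
  data.frame(tfi = tfi, tail_dna_pct = td, tail_moment = tm,
             dose_gy = dose_gy, true_population = spec$label,
             stringsAsFactors = FALSE)
}

#' Simulate one cell population at one dose
#'
#' Draws `n` comets from the truncated-lognormal intensity model of `spec`
#' and the saturating damage model at `dose_gy`. Fully reproducible: equal
#' seeds give identical datasets.
#'
#' @param spec a [population_spec()].
#' @param model a [damage_model()].
#' @param dose_gy dose in Gy (default 0).
#' @param n number of comets (> 0).
#' @param seed integer seed.
#' @return A [comet_dataset()] carrying `dose_gy` and the ground-truth
#'   `true_population` column.
#' @export
simulate_population <- function(spec, model, dose_gy = 0, n, seed = 1L) {
  if (!inherits(spec, "population_spec")) {
    abort_cometcal("`spec` must be a population_spec", "cometcal_parameter_error")
  }
  if (!inherits(model, "damage_model")) {
    abort_cometcal("`model` must be a damage_model", "cometcal_parameter_error")
  }
  if (!is_number(n) || n < 1) {
    abort_cometcal("`n` must be a positive integer", "cometcal_parameter_error")
  }
  stopifnot_number(dose_gy, "dose_gy", nonneg = TRUE)
  set.seed(as.integer(seed))
  df <- sim_population_core(spec, model, dose_gy, as.integer(n))
  df$experiment_id <- "sim"
  df$sample_id <- spec$label
  df$cell_index <- seq_len(nrow(df))
  comet_dataset(df, provenance = sprintf(
    "simulate_population(label=%s, dose=%g, n=%d, seed=%d)",
    spec$label, dose_gy, as.integer(n), as.integer(seed)))
}

#' Exact class counts by largest-remainder apportionment
#'
#' Splits `n` into integer counts proportional to `proportions`: each class
#' gets the floor of its exact share, and the remaining units go to the
#' largest fractional remainders (ties to the earlier class). Used so that
#' fixture class counts are deterministic rather than multinomial.
#'
#' @param n total count.
#' @param proportions numeric vector summing to 1.
#' @return Integer vector summing to `n`.
#' @examples
#' apportion_largest_remainder(100, c(0.594, 0.235, 0.172) / 1.001)
#' @export
apportion_largest_remainder <- function(n, proportions) {
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort_cometcal("`proportions` must sum to 1", "cometcal_parameter_error")
  }
  exact <- n * proportions
  counts <- floor(exact)
  left <- round(n - sum(counts))
  if (left > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Simulate a control human testicular cell suspension
#'
#' Emulates the trimodal TFI distribution of a pooled control testicular
#' biopsy: three populations — haploid spermatids (1n), diploid cells (2n)
#' and premeiotic 4c spermatocytes — with geometric-mean intensities
#' 255 000 / 471 000 / 761 000 a.u. and proportions 59.4 / 23.5 / 17.2%
#' (normalized to sum to one), at 0 Gy with a tight control damage model
#' whose class-mean Tail Moment sits in the 2.2-2.5 band. Class counts are
#' apportioned exactly by largest remainder, so the standard 1600-cell
#' fixture always contains 949 + 376 + 275 comets.
#'
#' @param n_total total number of comets (>= 100).
#' @param seed integer seed (default 1).
#' @param overrides optional list of [population_spec()] replacing the
#'   default three (proportions must sum to 1).
#' @param model optional [damage_model()] replacing the control default.
#' @return A [comet_dataset()] with ground-truth `true_population`.
#' @export
simulate_testicular <- function(n_total, seed = 1L, overrides = NULL,
                                model = NULL) {
  if (!is_number(n_total) || n_total < 100) {
    abort_cometcal("`n_total` must be >= 100", "cometcal_parameter_error")
  }
  specs <- overrides %||% testicular_default_specs()
  props <- vapply(specs, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9) {
    abort_cometcal("population proportions must sum to 1",
                   "cometcal_parameter_error")
  }
  model <- model %||% damage_model(baseline_td = 2, beta = 0.06,
                                   cell_dispersion = 600)
  counts <- apportion_largest_remainder(as.integer(n_total), props)
  set.seed(as.integer(seed))
  parts <- lapply(seq_along(specs), function(i) {
    if (counts[i] == 0L) return(NULL)
    sim_population_core(specs[[i]], model, 0, counts[i])
  })
  df <- do.call(rbind, parts)
  df$dose_gy <- NA_real_  # unirradiated control; no dose series here
  df$experiment_id <- "sim-testis"
  df$sample_id <- "testis"
  df$cell_index <- seq_len(nrow(df))
  comet_dataset(df, provenance = sprintf(
    "simulate_testicular(n_total=%d, seed=%d)",
    as.integer(n_total), as.integer(seed)))
}

testicular_default_specs <- function() {
  props <- c(0.594, 0.235, 0.172)
  props <- props / sum(props)
  scales <- c(255000, 471000, 761000)
  labels <- c("1n", "2n", "4c")
  lapply(1:3, function(i) {
    population_spec(labels[i], props[i], scales[i])
  })
}

#' Simulate a 1:1 fish-erythrocyte / human-PBMN mixture dose series
#'
#' Emulates mixed gels of turbot erythrocytes (FE, 0.86 pg haploid genome)
#' and human peripheral blood mononuclear cells (PBMN, 3.50 pg) irradiated
#' at an X-ray dose series (default 0, 1.5, 3, 6, 8, 10, 15 Gy). Geometric
#' mean TFI of each population is `intensity_per_pg` times its diploid DNA
#' mass, so the FE/PBMN median ratio equals the genome-mass ratio (about
#' 4.07); with the default calibration of 25 000 a.u./pg the 3-SD-truncated
#' supports end below 70 000 and start above 100 000 a.u., leaving that
#' interval exactly empty. The PBMN damage rate is solved so expected Tail
#' %DNA reaches `td_at_15` (default 85%) at the 15 Gy calibration dose —
#' past the ~80% dynamic range — and the FE rate is scaled down by the
#' diploid genome-mass ratio (smaller radiation target). TFI is
#' dose-independent by construction.
#'
#' @param doses dose series in Gy (non-empty).
#' @param n_per_dose_per_pop comets per population per dose (default 100).
#' @param seed integer seed.
#' @param intensity_per_pg TFI units per pg of DNA (default 25 000).
#' @param fe_genome,pbmn_genome [genome_spec()] of the two populations.
#' @param baseline_td control %TD (default 2).
#' @param td_at_15 expected PBMN %TD at the 15 Gy calibration dose.
#' @param tfi_cv,truncation_sd,cell_dispersion see [population_spec()] /
#'   [damage_model()].
#' @return A [comet_dataset()] with `dose_gy` and ground-truth
#'   `true_population` (`"FE"` / `"PBMN"`).
#' @export
simulate_mixture_dose_series <- function(doses = c(0, 1.5, 3, 6, 8, 10, 15),
                                         n_per_dose_per_pop = 100L,
                                         seed = 1L,
                                         intensity_per_pg = 25000,
                                         fe_genome = genome_spec("turbot", 0.86),
                                         pbmn_genome = genome_spec("human", 3.50),
                                         baseline_td = 2,
                                         td_at_15 = 85,
                                         tfi_cv = 0.15,
                                         truncation_sd = 3,
                                         cell_dispersion = 200) {
  if (length(doses) == 0L || any(doses < 0)) {
    abort_cometcal("`doses` must be a non-empty vector of doses >= 0",
                   "cometcal_parameter_error")
  }
  fe_mass <- fe_genome$haploid_genome_pg * fe_genome$ploidy_factor
  pbmn_mass <- pbmn_genome$haploid_genome_pg * pbmn_genome$ploidy_factor
  fe_spec <- population_spec("FE", 0.5, intensity_per_pg * fe_mass,
                             tfi_cv = tfi_cv, genome = fe_genome,
                             truncation_sd = truncation_sd)
  pbmn_spec <- population_spec("PBMN", 0.5, intensity_per_pg * pbmn_mass,
                               tfi_cv = tfi_cv, genome = pbmn_genome,
                               truncation_sd = truncation_sd)
  sigma <- sqrt(log(1 + tfi_cv^2))
  lo_spec <- if (fe_spec$tfi_scale < pbmn_spec$tfi_scale) fe_spec else pbmn_spec
  hi_spec <- if (fe_spec$tfi_scale < pbmn_spec$tfi_scale) pbmn_spec else fe_spec
  if (lo_spec$tfi_scale * exp(truncation_sd * sigma) >=
      hi_spec$tfi_scale * exp(-truncation_sd * sigma)) {
    abort_cometcal(
      "truncated TFI supports of the two populations overlap; no empty interval can exist",
      "cometcal_configuration_error")
  }
  beta_pbmn <- beta_for_target_td(baseline_td, 15, td_at_15)
  beta_fe <- beta_pbmn * fe_mass / pbmn_mass
  fe_model <- damage_model(baseline_td, beta_fe, cell_dispersion)
  pbmn_model <- damage_model(baseline_td, beta_pbmn, cell_dispersion)
  n <- as.integer(n_per_dose_per_pop)
  set.seed(as.integer(seed))
  parts <- lapply(doses, function(d) {
    rbind(sim_population_core(fe_spec, fe_model, d, n),
          sim_population_core(pbmn_spec, pbmn_model, d, n))
  })
  df <- do.call(rbind, parts)
  df$experiment_id <- "sim-mix"
  df$sample_id <- sprintf("%s_%gGy", df$true_population, df$dose_gy)
  df$cell_index <- stats::ave(seq_len(nrow(df)), df$sample_id,
                              FUN = seq_along)
  comet_dataset(df, provenance = sprintf(
    "simulate_mixture_dose_series(doses=%s, n=%d, seed=%d)",
    paste(doses, collapse = "/"), n, as.integer(seed)))
}
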
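#' Per-population, per-dose damage summaries
#'
#' Collapses a labeled dose-series dataset to one dose point per
#' (population, dose): the damage center (mean by default, as when mean Tail
#' %DNA per population is used to construct dose-response curves; median
#' optionally), the cell count and the damage SD. Every population must be
#' observed at every dose; an empty (population, dose) cell is an error
#' naming the missing combinations rather than a silently shorter table.
#'
#' @param dataset a [comet_dataset()] whose records carry `dose_gy` and a
#'   population label (by default `class_label`, as assigned by
#'   [classify_by_tfi()] or after [split_reference_sample()]).
#' @param summary `"mean"` or `"median"`.
#' @param damage_metric `"tail_dna_pct"` or `"tail_moment"`.
#' @param population_col column holding the population label.
#' @return A `dose_points` data.frame with columns `population`, `dose_gy`,
#'   `damage_center`, `n_cells`, `damage_spread`.
#' @export
summarize_dose_series <- function(dataset, summary = c("mean", "median"),
                                  damage_metric = c("tail_dna_pct", "tail_moment"),
                                  population_col = "class_label") {
  summary <- match.arg(summary)
  damage_metric <- match.arg(damage_metric)
  if (!population_col %in% names(dataset)) {
    abort_cometcal(sprintf("population column '%s' not found", population_col),
                   "cometcal_parameter_error")
  }
  keep <- !is.na(dataset$dose_gy) & !is.na(dataset[[population_col]])
  if (!any(keep)) {
    abort_cometcal("no records with both a dose and a population label",
                   "cometcal_parameter_error")
  }
  d <- dataset[keep, , drop = FALSE]
  pops <- unique(d[[population_col]])
  doses <- sort(unique(d$dose_gy))
  grid <- expand.grid(population = pops, dose_gy = doses,
                      stringsAsFactors = FALSE)
  key <- paste(d[[population_col]], d$dose_gy, sep = "\r")
  have <- paste(grid$population, grid$dose_gy, sep = "\r") %in% key
  if (any(!have)) {
    abort_cometcal(
      sprintf("no records for: %s",
              paste(sprintf("(%s, %g Gy)", grid$population[!have],
                            grid$dose_gy[!have]), collapse = ", ")),
      "cometcal_missing_cell_error")
  }
  center_fun <- if (summary == "mean") mean else stats::median
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- d[[population_col]] == grid$population[i] &
      d$dose_gy == grid$dose_gy[i]
    dmg <- d[[damage_metric]][sel]
    data.frame(population = grid$population[i],
               dose_gy = grid$dose_gy[i],
               damage_center = center_fun(dmg, na.rm = TRUE),
               n_cells = sum(sel),
               damage_spread = stats::sd(dmg, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$population, out$dose_gy), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, summary = summary, damage_metric = damage_metric,
            class = c("dose_points", "data.frame"))
}

#' Fit a linear dose-response calibration with dynamic-range truncation
#'
#' Ordinary least squares of the per-dose damage center on dose, after
#' excluding dose points whose center exceeds the assay's dynamic range
#' (default 80 % Tail DNA — above that, damage no longer responds linearly
#' to dose and the point would distort the calibration, as at 15 Gy in
#' irradiated lymphocytes). Excluded doses are listed, never silently
#' dropped. Optional inverse-variance weighting is available; the default
#' fit is unweighted.
#'
#' @param points a `dose_points` data.frame (one population; use
#'   `population` to pick one from a multi-population table).
#' @param dynamic_range_max damage center above which a dose point is
#'   excluded (default 80).
#' @param population population label to fit when `points` covers several.
#' @param weights `"none"` (default) or `"inverse_variance"`
#'   (`1 / damage_spread^2`).
#' @param genome_mass_pg optional DNA mass per cell (pg) attached to the
#'   curve for [slope_per_genome_mass()].
#' @return A `dose_response_curve`: slope (%TD per Gy), intercept (%TD at
#'   0 Gy), `r_squared`, `dynamic_range_max`, `excluded_doses`,
#'   `population_label`, `genome_mass_pg`, and the points used.
#' @export
fit_linear <- function(points, dynamic_range_max = 80, population = NULL,
                       weights = c("none", "inverse_variance"),
                       genome_mass_pg = NULL) {
  weights <- match.arg(weights)
  stopifnot_number(dynamic_range_max, "dynamic_range_max", positive = TRUE)
  pts <- as.data.frame(points)
  if (!is.null(population)) {
    pts <- pts[pts$population == population, , drop = FALSE]
  }
  pops <- unique(pts$population)
  if (length(pops) != 1L) {
    abort_cometcal("`points` must cover exactly one population (use `population =`)",
                   "cometcal_parameter_error")
  }
  over <- pts$damage_center > dynamic_range_max
  excluded <- pts$dose_gy[over]
  use <- pts[!over, , drop = FALSE]
  if (nrow(use) < 3L) {
    abort_cometcal(sprintf("only %d dose point(s) within the dynamic range; need >= 3",
                           nrow(use)),
                   "cometcal_insufficient_points_error")
  }
  w <- if (weights == "inverse_variance") 1 / use$damage_spread^2 else NULL
  fit <- stats::lm(damage_center ~ dose_gy, data = use, weights = w)
  # r^2 from the decomposition directly; summary.lm() warns on exact fits
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((use$damage_center - mean(use$damage_center))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 dynamic_range_max = dynamic_range_max,
                 excluded_doses = excluded,
                 population_label = pops,
                 genome_mass_pg = genome_mass_pg,
                 weights = weights,
                 points = use,
                 fit = fit),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("<dose_response_curve> %s: TD = %.4g + %.4g * dose (r^2 = %.4f)\n",
              x$population_label, x$intercept, x$slope, x$r_squared))
  if (length(x$excluded_doses)) {
    cat(sprintf("  excluded beyond %g %%TD: %s Gy\n", x$dynamic_range_max,
                paste(x$excluded_doses, collapse = ", ")))
  }
  invisible(x)
}

#' Gray-equivalent of an observed damage level
#'
#' Inverts a dose-response calibration: the X-ray dose that would produce
#' the observed Tail %DNA on this curve. This is how internal reference
#' cells carrying known radiation-induced lesion levels convert a damage
#' reading into a dose-equivalent (and from there, via a user-supplied
#' lesions-per-Gy constant, into lesion frequencies). Values below the
#' intercept return 0 Gy; values beyond the dynamic range are refused rather
#' than extrapolated.
#'
#' @param td observed Tail %DNA.
#' @param curve a `dose_response_curve` with positive slope.
#' @return Dose in Gy (>= 0).
#' @export
gy_equivalent <- function(td, curve) {
  if (!inherits(curve, "dose_response_curve")) {
    abort_cometcal("`curve` must be a dose_response_curve",
                   "cometcal_parameter_error")
  }
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    abort_cometcal("curve slope must be > 0 to invert",
                   "cometcal_invalid_curve_error")
  }
  stopifnot_number(td, "td")
  if (td > curve$dynamic_range_max) {
    abort_cometcal(
      sprintf("TD = %g is beyond the dynamic range of the assay (max %g)",
              td, curve$dynamic_range_max),
      "cometcal_out_of_range_error")
  }
  max(0, (td - curve$intercept) / curve$slope)
}

#' Dose-response slope per unit genome mass
#'
#' Less damage is induced per Gy in small-genome cells simply because they
#' present a smaller DNA target; dividing the slope by the DNA mass per cell
#' puts populations of different genome size on a per-target-mass footing.
#'
#' @param curve a `dose_response_curve` carrying `genome_mass_pg`.
#' @return Slope in %TD per Gy per pg.
#' @export
slope_per_genome_mass <- function(curve) {
  if (!inherits(curve, "dose_response_curve")) {
    abort_cometcal("`curve` must be a dose_response_curve",
                   "cometcal_parameter_error")
  }
  if (is.null(curve$genome_mass_pg)) {
    abort_cometcal("curve has no genome_mass_pg; supply it to fit_linear()",
                   "cometcal_missing_parameter_error")
  }
  curve$slope / curve$genome_mass_pg
}

#' Lesion count from a gray-equivalent
#'
#' Converts a dose-equivalent to lesions per cell using a user-supplied
#' radiation yield. No default constant is bundled: the yield depends on
#' lesion type, assay conditions and cell type, so it must be given
#' explicitly.
#'
#' @param gy dose-equivalent in Gy (>= 0).
#' @param lesions_per_gy lesions per cell per Gy (> 0, required).
#' @return Lesions per cell.
#' @export
lesions_from_gy <- function(gy, lesions_per_gy) {
  if (missing(lesions_per_gy) || is.null(lesions_per_gy)) {
    abort_cometcal("`lesions_per_gy` must be supplied; no default yield exists",
                   "cometcal_missing_parameter_error")
  }
  stopifnot_number(lesions_per_gy, "lesions_per_gy", positive = TRUE)
  stopifnot_number(gy, "gy", nonneg = TRUE)
  gy * lesions_per_gy
}

#' QC check: TFI should not trend with dose
#'
#' Radiation changes how a comet's fluorescence is distributed between head
#' and tail, not how much DNA is stained, so median TFI should be flat
#' across doses. For each population this fits the slope of median TFI
#' versus dose, expresses it as a fraction of the 0-dose (lowest-dose)
#' median per Gy, and bootstraps a confidence interval by resampling cells
#' within each (population, dose) group. A large relative slope flags
#' staining drift or signal saturation.
#'
#' @param dataset a labeled [comet_dataset()] with `dose_gy`.
#' @param population_col column holding the population label.
#' @param n_boot bootstrap replicates (default 199).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return data.frame with one row per population: `relative_slope`
#'   (fraction of the low-dose median per Gy), `ci_lower`, `ci_upper`.
#' @export
tfi_dose_invariance <- function(dataset, population_col = "class_label",
                                n_boot = 199L, conf = 0.95, seed = 1L) {
  keep <- !is.na(dataset$dose_gy) & !is.na(dataset[[population_col]])
  d <- dataset[keep, , drop = FALSE]
  set.seed(as.integer(seed))
  out <- lapply(unique(d[[population_col]]), function(pop) {
    dd <- d[d[[population_col]] == pop, , drop = FALSE]
    doses <- sort(unique(dd$dose_gy))
    if (length(doses) < 2L) {
      abort_cometcal(sprintf("population '%s' has a single dose; TFI trend undefined",
                             pop),
                     "cometcal_degenerate_trend_error")
    }
    groups <- split(dd$tfi, dd$dose_gy)
    rel_slope <- function(tfi_by_dose) {
      med <- vapply(tfi_by_dose, stats::median, numeric(1))
      dg <- as.numeric(names(tfi_by_dose))
      b <- stats::coef(stats::lm(med ~ dg))[2L]
      unname(b / med[which.min(dg)])
    }
    obs <- rel_slope(groups)
    boots <- vapply(seq_len(n_boot), function(i) {
      rel_slope(lapply(groups, function(g) g[sample.int(length(g),
                                                        replace = TRUE)]))
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
    data.frame(population = pop, relative_slope = obs,
               ci_lower = ci[1], ci_upper = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
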
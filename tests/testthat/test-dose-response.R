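make_points <- function(dose, td, population = "PBMN", n = 100, spread = 1) {
  structure(data.frame(population = population, dose_gy = dose,
                       damage_center = td, n_cells = n, damage_spread = spread,
                       stringsAsFactors = FALSE),
            class = c("dose_points", "data.frame"))
}

test_that("dose series are summarized per population and dose", {
  mix <- label_by_gap(simulate_mixture_dose_series(seed = 4))
  pts <- summarize_dose_series(mix)
  expect_equal(nrow(pts), 14L)  # 7 doses x 2 populations
  expect_setequal(unique(pts$population), c("FE", "PBMN"))
  expect_equal(sort(unique(pts$dose_gy)), c(0, 1.5, 3, 6, 8, 10, 15))
  expect_true(all(pts$n_cells == 100L))

  # hand-built check: 4 records, one population, one dose
  ds <- make_ds(c(1e5, 1e5, 1e5, 1e5), tail_dna_pct = c(2, 4, 6, 8),
                dose_gy = 3, class_label = "PBMN")
  hand <- summarize_dose_series(ds)
  expect_equal(hand$damage_center, 5)
  expect_equal(hand$n_cells, 4L)
  expect_equal(hand$damage_spread, sd(c(2, 4, 6, 8)))

  # symmetric toy data: median summary equals mean summary
  med <- summarize_dose_series(ds, summary = "median")
  expect_equal(med$damage_center, hand$damage_center)
})

test_that("an empty (population, dose) cell is reported, not skipped", {
  ds <- make_ds(c(1e5, 1e5, 3e4), tail_dna_pct = c(2, 4, 3),
                dose_gy = c(0, 3, 0), class_label = c("PBMN", "PBMN", "FE"))
  expect_error(summarize_dose_series(ds), regexp = "FE, 3 Gy",
               class = "cometcal_missing_cell_error")
})

test_that("exact linear points are fitted exactly", {
  doses <- c(0, 1.5, 3, 6, 8)
  pts <- make_points(doses, 5 + 6 * doses)
  curve <- fit_linear(pts)
  expect_equal(curve$slope, 6)
  expect_equal(curve$intercept, 5)
  expect_equal(curve$r_squared, 1)
  expect_length(curve$excluded_doses, 0)
})

test_that("points beyond the dynamic range are excluded and listed", {
  doses <- c(0, 1.5, 3, 6, 8, 15)
  td <- c(5 + 6 * c(0, 1.5, 3, 6, 8), 95)  # 15 Gy saturated
  curve <- fit_linear(make_points(doses, td))
  expect_equal(curve$excluded_doses, 15)
  expect_equal(curve$slope, 6)  # unchanged by the excluded point
  expect_equal(curve$intercept, 5)

  expect_error(fit_linear(make_points(c(0, 3), c(2, 20))),
               class = "cometcal_insufficient_points_error")
  expect_error(fit_linear(make_points(c(0, 3, 6), c(85, 90, 95))),
               class = "cometcal_insufficient_points_error")
})

test_that("the fit equals the closed-form least-squares solution", {
  for (seed in 1:5) {
    set.seed(seed)
    doses <- c(0, 1.5, 3, 6, 8)
    td <- 4 + 5.5 * doses + rnorm(5, 0, 2)
    curve <- fit_linear(make_points(doses, td))
    # normal-equation oracle
    sxx <- sum((doses - mean(doses))^2)
    sxy <- sum((doses - mean(doses)) * (td - mean(td)))
    slope <- sxy / sxx
    intercept <- mean(td) - slope * mean(doses)
    expect_equal(curve$slope, slope, tolerance = 1e-10)
    expect_equal(curve$intercept, intercept, tolerance = 1e-10)
  }
})

test_that("gray-equivalents invert the calibration", {
  curve <- fit_linear(make_points(c(0, 1.5, 3, 6, 8), 5 + 6 * c(0, 1.5, 3, 6, 8)))
  expect_equal(gy_equivalent(35, curve), 5)
  expect_equal(gy_equivalent(curve$intercept, curve), 0)
  expect_equal(gy_equivalent(2, curve), 0)  # below baseline floors at 0 Gy
  expect_error(gy_equivalent(95, curve), class = "cometcal_out_of_range_error")

  flat <- curve
  flat$slope <- -1
  expect_error(gy_equivalent(10, flat), class = "cometcal_invalid_curve_error")

  # noise-free doses round-trip exactly through the curve
  for (d in c(0, 1.5, 3, 6, 8)) {
    expect_equal(gy_equivalent(5 + 6 * d, curve), d)
  }
})

test_that("slope per genome mass compares populations per DNA target", {
  doses <- c(0, 1.5, 3, 6, 8)
  human <- fit_linear(make_points(doses, 5 + 6 * doses), genome_mass_pg = 3.50)
  fish <- fit_linear(make_points(doses, 5 + 6 * doses, population = "FE"),
                     genome_mass_pg = 0.86)
  expect_equal(slope_per_genome_mass(human) / slope_per_genome_mass(fish),
               0.86 / 3.50, tolerance = 1e-12)
  unit <- fit_linear(make_points(doses, 5 + 6 * doses), genome_mass_pg = 1)
  expect_equal(slope_per_genome_mass(unit), unit$slope)
  expect_error(slope_per_genome_mass(fit_linear(make_points(doses, 5 + 6 * doses))),
               class = "cometcal_missing_parameter_error")
})

test_that("lesion conversion requires an explicit yield", {
  expect_equal(lesions_from_gy(0, 1000), 0)
  expect_equal(lesions_from_gy(2, 1000), 2000)
  expect_error(lesions_from_gy(2), class = "cometcal_missing_parameter_error")
  expect_error(lesions_from_gy(2, 0), class = "cometcal_parameter_error")

  curve <- fit_linear(make_points(c(0, 1.5, 3, 6, 8), 5 + 6 * c(0, 1.5, 3, 6, 8)))
  tds <- seq(5, 50, by = 5)
  lesions <- vapply(tds, function(td) {
    lesions_from_gy(gy_equivalent(td, curve), 1000)
  }, numeric(1))
  expect_false(is.unsorted(lesions))  # monotone on the linear range
})

test_that("TFI shows no dose trend unless one is injected", {
  mix <- label_by_gap(simulate_mixture_dose_series(seed = 9,
                                                   n_per_dose_per_pop = 150))
  qc <- tfi_dose_invariance(mix, n_boot = 99, seed = 1)
  expect_true(all(abs(qc$relative_slope) < 0.01))  # < 1% of baseline per Gy

  drift <- mix
  drift$tfi <- drift$tfi * (1 + 0.05 * drift$dose_gy)
  qc_drift <- tfi_dose_invariance(drift, n_boot = 99, seed = 1)
  expect_equal(qc_drift$relative_slope, rep(0.05, 2), tolerance = 0.2)

  flat <- make_ds(rep(12345, 60), dose_gy = rep(c(0, 3, 6), 20),
                  class_label = "PBMN")
  qc_flat <- tfi_dose_invariance(flat, n_boot = 19, seed = 1)
  expect_equal(qc_flat$relative_slope, 0, tolerance = 1e-12)

  single <- make_ds(runif(10, 1, 2), dose_gy = 3, class_label = "PBMN")
  expect_error(tfi_dose_invariance(single),
               class = "cometcal_degenerate_trend_error")
})
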
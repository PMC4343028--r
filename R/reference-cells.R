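#' Genome specification of a cell population
#'
#' Haploid genome mass (C-value, picograms) plus a ploidy factor giving the
#' DNA mass per cell; the integrated staining intensity of an unsaturated
#' comet is proportional to this mass, which is what makes small-genome fish
#' erythrocytes usable as internal reference cells among human cells.
#'
#' @param species_name text label.
#' @param haploid_genome_pg haploid genome mass in pg (> 0).
#' @param ploidy_factor genome copies per cell (2 for diploid somatic cells).
#' @return A `genome_spec`.
#' @examples
#' genome_spec("turbot", 0.86)
#' @export
genome_spec <- function(species_name, haploid_genome_pg, ploidy_factor = 2) {
  stopifnot_number(haploid_genome_pg, "haploid_genome_pg", positive = TRUE)
  stopifnot_number(ploidy_factor, "ploidy_factor", positive = TRUE)
  structure(list(species_name = as.character(species_name),
                 haploid_genome_pg = haploid_genome_pg,
                 ploidy_factor = ploidy_factor),
            class = "genome_spec")
}

#' Built-in haploid genome sizes
#'
#' Small reference table of C-values (pg) for the species relevant to
#' reference-cell work: turbot and polar cod are small-genomed candidates,
#' rainbow trout illustrates a genome too close to human for intensity
#' separation (2.4-2.7 pg, tabulated at the 2.55 midpoint), human is the
#' sample species.
#'
#' @return data.frame with `species`, `haploid_genome_pg`, `note`.
#' @export
builtin_genomes <- function() {
  data.frame(
    species = c("turbot", "polar_cod", "rainbow_trout", "human"),
    haploid_genome_pg = c(0.86, 0.88, 2.55, 3.50),
    note = c("Scophthalmus maximus", "Boreogadus saida",
             "Oncorhynchus mykiss; range 2.4-2.7 pg, midpoint used",
             "Homo sapiens"),
    stringsAsFactors = FALSE
  )
}

#' Locate the empty TFI interval separating reference and sample cells
#'
#' In a gel where small-genome reference cells are mixed with sample cells,
#' the two TFI distributions should leave a band of intensities containing
#' no comets at all (e.g. no cells between 70 000 and 100 000 a.u. in a
#' turbot/human mixture). `find_gap` scans the sorted TFI values between the
#' `trim` and `1 - trim` quantiles (outermost 1% excluded on each side so a
#' lone outlier can neither fabricate nor destroy a gap) and returns the
#' widest empty interval, provided it is wider than `min_gap_fraction` of
#' the trimmed TFI range. Failure to find one signals that the two
#' populations overlap and intensity gating is unsafe — the situation seen
#' when the reference genome is too close to the sample's.
#'
#' @param dataset a [comet_dataset()] with >= 50 records.
#' @param min_gap_fraction minimum gap width as a fraction of the trimmed
#'   TFI range (default 0.05).
#' @param reference_class which side of the gap holds the reference cells,
#'   `"below"` (default: smaller-genomed reference) or `"above"`.
#' @param trim fraction of records ignored at each extreme (default 0.01).
#' @return A `gap_gate`: list with `gap_low`, `gap_high`, `split_point`
#'   (midpoint) and `reference_class`.
#' @export
find_gap <- function(dataset, min_gap_fraction = 0.05,
                     reference_class = c("below", "above"), trim = 0.01) {
  reference_class <- match.arg(reference_class)
  if (!inherits(dataset, "comet_dataset") || nrow(dataset) < 50L) {
    abort_cometcal("`dataset` must be a comet_dataset with >= 50 records",
                   "cometcal_parameter_error")
  }
  q <- stats::quantile(dataset$tfi, c(trim, 1 - trim), names = FALSE, type = 7)
  x <- sort(dataset$tfi[dataset$tfi >= q[1] & dataset$tfi <= q[2]])
  widths <- diff(x)
  i <- which.max(widths)
  rng <- x[length(x)] - x[1]
  if (length(widths) == 0L || widths[i] <= min_gap_fraction * rng) {
    abort_cometcal(
      "no empty TFI interval wide enough; populations overlap and intensity gating is unsafe",
      "cometcal_no_gap_error")
  }
  structure(list(gap_low = x[i], gap_high = x[i + 1L],
                 split_point = (x[i] + x[i + 1L]) / 2,
                 reference_class = reference_class),
            class = "gap_gate")
}

#' @export
print.gap_gate <- function(x, ...) {
  cat(sprintf("<gap_gate> empty TFI interval (%s, %s), split at %s; reference cells %s\n",
              format(x$gap_low), format(x$gap_high), format(x$split_point),
              x$reference_class))
  invisible(x)
}

#' Split a mixed gel into reference and sample subsets
#'
#' Partitions a dataset at the gap gate's split point. Both subsets keep all
#' record fields and together conserve the record count. An empty side only
#' raises a warning: a pure sample may legitimately contain no reference
#' cells.
#'
#' @param dataset a [comet_dataset()].
#' @param gate a `gap_gate` from [find_gap()].
#' @return List with elements `reference` and `sample`, both `comet_dataset`.
#' @export
split_reference_sample <- function(dataset, gate) {
  if (!inherits(gate, "gap_gate")) {
    abort_cometcal("`gate` must be a gap_gate", "cometcal_parameter_error")
  }
  below <- dataset$tfi < gate$split_point
  ref_side <- if (gate$reference_class == "below") below else !below
  reference <- dataset[ref_side, , drop = FALSE]
  sample <- dataset[!ref_side, , drop = FALSE]
  if (nrow(reference) == 0L || nrow(sample) == 0L) {
    warn_cometcal("one side of the split is empty",
                  "cometcal_empty_partition_warning")
  }
  list(reference = restore_dataset(reference, dataset),
       sample = restore_dataset(sample, dataset))
}

# subsetting a classed data.frame keeps the class but we re-attach metadata
restore_dataset <- function(subset, parent) {
  attr(subset, "units_note") <- attr(parent, "units_note")
  attr(subset, "provenance") <- attr(parent, "provenance")
  class(subset) <- c("comet_dataset", "data.frame")
  rownames(subset) <- NULL
  subset
}

#' Expected TFI ratio between two cell types
#'
#' Under unsaturated staining, integrated comet intensity is proportional to
#' DNA mass per cell, so the expected intensity ratio of two cell types is
#' the ratio of (haploid genome mass x ploidy factor). Human lymphocytes
#' (3.50 pg, diploid) over turbot erythrocytes (0.86 pg, diploid) gives
#' about 4.07, matching the observed 3-4x separation.
#'
#' @param a,b [genome_spec()] objects (numerator, denominator).
#' @return Positive number: expected `TFI(a) / TFI(b)`.
#' @export
expected_intensity_ratio <- function(a, b) {
  if (!inherits(a, "genome_spec") || !inherits(b, "genome_spec")) {
    abort_cometcal("`a` and `b` must be genome_spec objects",
                   "cometcal_parameter_error")
  }
  (a$haploid_genome_pg * a$ploidy_factor) /
    (b$haploid_genome_pg * b$ploidy_factor)
}

#' Warn when two genomes are too similar for intensity separation
#'
#' Intensity gating of a reference/sample mixture needs the expected
#' intensity ratio (larger over smaller) to be comfortably above 1; rainbow
#' trout (2.4-2.7 pg) versus human (3.50 pg) fails this and yields a single
#' merged cloud. Emits a `cometcal_separability_warning` when the fold
#' difference falls below `min_ratio`.
#'
#' @param a,b [genome_spec()] objects.
#' @param min_ratio minimum acceptable fold difference (default 2).
#' @return The fold difference (>= 1), invisibly.
#' @export
check_separability <- function(a, b, min_ratio = 2) {
  r <- expected_intensity_ratio(a, b)
  fold <- max(r, 1 / r)
  if (fold < min_ratio) {
    warn_cometcal(
      sprintf("expected intensity ratio %.2f is below %.1f; %s and %s are unlikely to separate by TFI",
              fold, min_ratio, a$species_name, b$species_name),
      "cometcal_separability_warning")
  }
  invisible(fold)
}

#' Rescale TFI so the internal reference median hits a target
#'
#' Absolute TFI varies between experiments with lamp intensity and staining;
#' the internal reference cells absorb that drift. Every TFI in the dataset
#' is multiplied by `target_reference_median / median(reference TFI)`, so all
#' intensity ratios within the dataset are preserved exactly and, after
#' normalization, reference medians agree across experiments. The median
#' (not the mean) drives the factor so heavily damaged or atypical reference
#' comets cannot skew it.
#'
#' @param dataset a [comet_dataset()] (typically reference + sample cells of
#'   one experiment).
#' @param reference non-empty `comet_dataset` of this experiment's reference
#'   cells.
#' @param target_reference_median TFI value the reference median is mapped to.
#' @return The dataset with rescaled `tfi`; the factor applied is stored in
#'   the `normalization_factor` attribute.
#' @export
normalize_intensity <- function(dataset, reference, target_reference_median) {
  stopifnot_number(target_reference_median, "target_reference_median",
                   positive = TRUE)
  if (!inherits(reference, "comet_dataset") || nrow(reference) == 0L) {
    abort_cometcal("`reference` must be a non-empty comet_dataset",
                   "cometcal_invalid_reference_error")
  }
  m <- stats::median(reference$tfi)
  if (!is.finite(m) || m <= 0) {
    abort_cometcal("reference median TFI must be > 0",
                   "cometcal_invalid_reference_error")
  }
  factor <- target_reference_median / m
  dataset$tfi <- dataset$tfi * factor
  attr(dataset, "normalization_factor") <- factor
  dataset
}
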
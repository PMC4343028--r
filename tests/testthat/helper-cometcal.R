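# small builders used across test files

make_ds <- function(tfi, ...) {
  comet_dataset(data.frame(tfi = tfi, ..., stringsAsFactors = FALSE))
}

# randomized but valid dataset for round-trip / property tests
random_dataset <- function(n, seed) {
  set.seed(seed)
  df <- data.frame(
    experiment_id = sample(c("expA", "expB"), n, replace = TRUE),
    sample_id = sample(paste0("s", 1:3), n, replace = TRUE),
    cell_index = seq_len(n),
    tfi = exp(rnorm(n, 11, 0.5)),
    tail_dna_pct = ifelse(runif(n) < 0.2, NA, runif(n, 0, 100)),
    tail_moment = ifelse(runif(n) < 0.2, NA, rexp(n, 1 / 3)),
    dose_gy = ifelse(runif(n) < 0.5, NA, sample(c(0, 1.5, 3), n, replace = TRUE)),
    class_label = ifelse(runif(n) < 0.5, NA, sample(c("1n", "2n"), n,
                                                    replace = TRUE)),
    true_population = sample(c("FE", "PBMN"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  comet_dataset(df)
}

fig1_thresholds <- function() {
  threshold_set(c(350000, 600000, 950000), c("1n", "2n", "4c"))
}

# label a mixture dataset through the reference-cell pipeline (not ground truth)
label_by_gap <- function(mix) {
  gate <- find_gap(mix)
  parts <- split_reference_sample(mix, gate)
  parts$reference$class_label <- "FE"
  parts$sample$class_label <- "PBMN"
  out <- rbind(as.data.frame(parts$reference), as.data.frame(parts$sample))
  comet_dataset(out)
}
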
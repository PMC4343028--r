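test_that("classification follows the left-closed interval convention", {
  th <- fig1_thresholds()
  ds <- make_ds(c(255000, 761000, 350000, 1000000, 349999.999, 950000))
  out <- classify_by_tfi(ds, th)
  expect_equal(out$class_label,
               c("1n", "4c", "2n", NA, "1n", NA))  # >= top cut excluded
  top <- classify_by_tfi(ds, threshold_set(th$cut_points, th$class_names,
                                           overflow_policy = "assign-top"))
  expect_equal(top$class_label[4], "4c")
  expect_error(classify_by_tfi(make_ds(numeric(0)), th),
               class = "cometcal_empty_input_error")
})

test_that("classification is idempotent, order-independent and monotone", {
  ds <- simulate_testicular(400, seed = 7)
  th <- fig1_thresholds()
  once <- classify_by_tfi(ds, th)
  twice <- classify_by_tfi(once, th)
  expect_identical(once$class_label, twice$class_label)

  perm <- sample(nrow(ds))
  shuffled <- classify_by_tfi(comet_dataset(as.data.frame(ds)[perm, ]), th)
  expect_identical(shuffled$class_label, once$class_label[perm])

  ord <- order(once$tfi)
  lab_rank <- match(once$class_label[ord], th$class_names)
  expect_false(is.unsorted(lab_rank[!is.na(lab_rank)]))
})

test_that("merging two adjacent classes never shrinks any class proportion", {
  ds <- simulate_testicular(800, seed = 21)
  th <- fig1_thresholds()
  before <- class_summary(classify_by_tfi(ds, th), "tail_moment")$summary
  merged <- threshold_set(th$cut_points[c(1, 3)], c("1n", "2n+4c"))
  after <- class_summary(classify_by_tfi(ds, merged), "tail_moment")$summary
  expect_gte(after$proportion[after$class_label == "1n"],
             before$proportion[before$class_label == "1n"])
  expect_gte(after$proportion[after$class_label == "2n+4c"],
             max(before$proportion[before$class_label %in% c("2n", "4c")]))
})

test_that("mixture thresholds land in the zero-misclassification interval", {
  lo <- population_spec("A", 0.5, 50000)
  hi <- population_spec("B", 0.5, 200000)
  model <- damage_model(beta = 0.06)
  a <- simulate_population(lo, model, 0, 500, seed = 42)$tfi
  b <- simulate_population(hi, model, 0, 500, seed = 43)$tfi
  ds <- make_ds(c(a, b))

  for (method in c("mixture", "valley")) {
    th <- find_thresholds(ds, 2, method = method, seed = 1)
    cut <- th$cut_points[1]
    # brute-force oracle: any cut inside (max A, min B) misclassifies nothing
    expect_gt(cut, max(a))
    expect_lt(cut, min(b))
    expect_gt(cut, 70000)
    expect_lt(cut, 150000)
    expect_length(th$cut_points, 2L)  # separating cut + upper exclusion cut
  }
})

test_that("the EM fit agrees with an independent mixture implementation", {
  lo <- population_spec("A", 0.5, 50000)
  hi <- population_spec("B", 0.5, 200000)
  model <- damage_model(beta = 0.06)
  x <- log(c(simulate_population(lo, model, 0, 400, seed = 51)$tfi,
             simulate_population(hi, model, 0, 400, seed = 52)$tfi))
  ours <- cometcal:::em_normal_mixture(x, 2)
  suppressMessages(library(mclust))
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$mu), sort(unname(ref$parameters$mean)),
               tolerance = 1e-3)
  expect_equal(sort(ours$pro), sort(ref$parameters$pro), tolerance = 0.02)
})

test_that("a single tight mode cannot be split into two classes", {
  set.seed(14)
  ds <- make_ds(exp(rnorm(200, log(50000), 0.05)))
  for (method in c("mixture", "valley")) {
    expect_error(find_thresholds(ds, 2, method = method, seed = 1),
                 class = "cometcal_degenerate_separation_error")
  }
  expect_error(find_thresholds(make_ds(rep(c(1e4, 1e5), 15)), 4,
                               method = "valley"),
               class = "cometcal_parameter_error")  # too few records
})

test_that("mixture gating of trimodal testicular data recovers class structure", {
  for (seed in c(2, 5, 11)) {
    ds <- simulate_testicular(1600, seed = seed)
    th <- find_thresholds(ds, 3, method = "mixture", seed = seed)
    res <- class_summary(classify_by_tfi(ds, th), "tail_moment")$summary
    expect_equal(res$mean_tfi, c(255000, 471000, 761000), tolerance = 0.05,
                 info = paste("seed", seed))
  }
})

test_that("class_summary matches hand arithmetic and conserves counts", {
  ds <- make_ds(c(100, 200, 400, 500, 800, 2000),
                tail_dna_pct = c(2, 4, 6, 8, 10, 12))
  th <- threshold_set(c(300, 600, 1000), c("lo", "mid", "hi"))
  res <- class_summary(classify_by_tfi(ds, th), "tail_dna_pct")
  s <- res$summary
  expect_equal(s$count, c(2L, 2L, 1L))
  expect_equal(res$excluded_count, 1L)
  expect_equal(sum(s$count) + res$excluded_count, res$n_total)
  expect_equal(s$proportion, c(0.4, 0.4, 0.2))
  expect_equal(sum(s$proportion), 1, tolerance = 1e-9)
  expect_equal(s$mean_damage, c(3, 7, 10))
  expect_equal(s$mean_tfi, c(150, 450, 800))
  expect_equal(s$median_damage, c(3, 7, 10))

  only <- classify_by_tfi(make_ds(c(100, 120), tail_dna_pct = c(1, 2)),
                          threshold_set(300, "only"))
  expect_equal(class_summary(only, "tail_dna_pct")$summary$proportion, 1.0)
})

test_that("summary demands a damage metric that exists", {
  ds <- classify_by_tfi(make_ds(c(100, 200)), threshold_set(300, "only"))
  expect_error(class_summary(ds, "tail_moment"),
               class = "cometcal_missing_metric_error")
  expect_error(class_summary(make_ds(100), "tail_dna_pct"),
               class = "cometcal_parameter_error")  # never classified
})

test_that("permutation p-value matches exhaustive enumeration on a toy table", {
  ds <- make_ds(c(100, 100, 500, 500), tail_dna_pct = c(1, 2, 10, 11))
  ds <- classify_by_tfi(ds, threshold_set(c(300, 1000), c("A", "B")))
  res <- compare_class_damage(ds, "tail_dna_pct", n_permutations = 999)
  expect_true(res$exact)

  # independent oracle: enumerate the 6 ways to choose class A's members
  dmg <- c(1, 2, 10, 11)
  stats_all <- apply(utils::combn(4, 2), 2, function(idx) {
    abs(mean(dmg[idx]) - mean(dmg[-idx]))
  })
  obs <- abs(mean(dmg[1:2]) - mean(dmg[3:4]))
  p_oracle <- (1 + sum(stats_all >= obs)) / (1 + length(stats_all))
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$statistic, 9)
})

test_that("clear separation forces an extreme p-value", {
  set.seed(8)
  dmg <- runif(200, 10, 20)
  ds <- make_ds(c(runif(200, 50, 90), runif(200, 150, 190)),
                tail_dna_pct = c(dmg, dmg + 10))
  ds <- classify_by_tfi(ds, threshold_set(c(100, 1000), c("A", "B")))
  res <- compare_class_damage(ds, "tail_dna_pct", n_permutations = 999, seed = 1)
  expect_lte(res$p_value, 0.001)
  expect_equal(res$statistic, 10, tolerance = 0.2)
})

test_that("under the null the permutation test rejects at close to its level", {
  over_threshold <- vapply(1:100, function(run) {
    set.seed(run + 1000)
    ds <- make_ds(c(runif(200, 50, 90), runif(200, 150, 190)),
                  tail_dna_pct = runif(400, 2, 8))
    ds <- classify_by_tfi(ds, threshold_set(c(100, 1000), c("A", "B")))
    compare_class_damage(ds, "tail_dna_pct", n_permutations = 199,
                         seed = run)$p_value > 0.05
  }, logical(1))
  expect_gte(mean(over_threshold), 0.9)
})

test_that("a single class cannot be compared", {
  ds <- classify_by_tfi(make_ds(c(10, 20, 30), tail_dna_pct = c(1, 2, 3)),
                        threshold_set(100, "only"))
  expect_error(compare_class_damage(ds, "tail_dna_pct"),
               class = "cometcal_degenerate_comparison_error")
})
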
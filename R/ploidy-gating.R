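#' Intensity thresholds for DNA-content classes
#'
#' A `threshold_set` partitions the total-fluorescence-intensity (TFI) axis
#' into left-closed, right-open intervals `[0, c1), [c1, c2), ...`, one class
#' per interval below each cut point. A comet with TFI at or above the last
#' cut is handled by `overflow_policy`: `"exclude"` (default) leaves it
#' unassigned — the last cut acts as an upper exclusion bound — while
#' `"assign-top"` folds it into the top class. For human testicular
#' suspensions the conventional three cuts are 350 000 / 600 000 / 950 000
#' a.u., separating haploid spermatids (1n), diploid cells (2n) and
#' premeiotic 4c spermatocytes, with the third line excluding rare
#' super-bright objects.
#'
#' @param cut_points strictly increasing positive TFI values.
#' @param class_names one name per interval below each cut point.
#' @param overflow_policy `"exclude"` or `"assign-top"`.
#' @return A `threshold_set`.
#' @examples
#' threshold_set(c(350000, 600000, 950000), c("1n", "2n", "4c"))
#' @export
threshold_set <- function(cut_points, class_names,
                          overflow_policy = c("exclude", "assign-top")) {
  overflow_policy <- match.arg(overflow_policy)
  cut_points <- as.numeric(cut_points)
  if (length(cut_points) < 1L || anyNA(cut_points) || any(cut_points <= 0) ||
      is.unsorted(cut_points, strictly = TRUE)) {
    abort_cometcal("`cut_points` must be strictly increasing and > 0",
                   "cometcal_parameter_error")
  }
  if (length(class_names) != length(cut_points)) {
    abort_cometcal("need exactly one class name per cut point",
                   "cometcal_parameter_error")
  }
  structure(list(cut_points = cut_points,
                 class_names = as.character(class_names),
                 overflow_policy = overflow_policy),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  lo <- c(0, x$cut_points[-length(x$cut_points)])
  cat(sprintf("  [%s, %s) -> %s\n",
              format(lo, big.mark = " "), format(x$cut_points, big.mark = " "),
              x$class_names), sep = "")
  cat(sprintf("  >= %s -> %s\n", format(x$cut_points[length(x$cut_points)]),
              if (x$overflow_policy == "exclude") "excluded" else
                x$class_names[length(x$class_names)]))
  invisible(x)
}

#' Classify comets into DNA-content classes by TFI
#'
#' Assigns each comet the class of the threshold interval its TFI falls in.
#' Classification is deterministic, idempotent and a monotone non-decreasing
#' function of TFI; a TFI exactly on a cut point belongs to the interval
#' above it (left-closed convention), never resolved randomly.
#'
#' @param dataset a non-empty [comet_dataset()].
#' @param thresholds a [threshold_set()].
#' @return The dataset with `class_label` filled in (`NA` for comets above
#'   the top cut under the `"exclude"` policy) and the thresholds stored in
#'   the `thresholds` attribute.
#' @export
classify_by_tfi <- function(dataset, thresholds) {
  if (!inherits(dataset, "comet_dataset") || nrow(dataset) == 0L) {
    abort_cometcal("`dataset` must be a non-empty comet_dataset",
                   "cometcal_empty_input_error")
  }
  if (!inherits(thresholds, "threshold_set")) {
    abort_cometcal("`thresholds` must be a threshold_set",
                   "cometcal_parameter_error")
  }
  cuts <- thresholds$cut_points
  k <- length(cuts)
  # idx = number of cut points <= tfi, so [0,c1) -> 0, [c1,c2) -> 1, ...
  idx <- findInterval(dataset$tfi, cuts)
  lab <- ifelse(idx < k, thresholds$class_names[idx + 1L],
                if (thresholds$overflow_policy == "assign-top")
                  thresholds$class_names[k] else NA_character_)
  dataset$class_label <- lab
  attr(dataset, "thresholds") <- thresholds
  dataset
}

#' Find TFI thresholds separating DNA-content classes
#'
#' Locates `n_classes - 1` separating cut points on the TFI axis from the
#' data themselves, plus an upper exclusion cut at a high quantile, so the
#' result can be fed straight to [classify_by_tfi()].
#'
#' Two methods are offered. `"mixture"` fits an `n_classes`-component
#' Gaussian mixture with unequal variances to `log(TFI)` (intensities are
#' positive and right-skewed) by expectation-maximization and places each cut
#' where the posterior probabilities of adjacent components are equal.
#' `"valley"` computes a kernel density estimate of `log(TFI)` (Silverman
#' bandwidth, 512-point grid) and places cuts at the deepest density minima
#' between the `n_classes` highest modes. Both return cut points on the
#' original TFI scale, strictly increasing.
#'
#' @param dataset a [comet_dataset()] with at least `10 * n_classes` records.
#' @param n_classes number of DNA-content classes sought (>= 2).
#' @param method `"mixture"` or `"valley"`.
#' @param seed integer seed (EM and any stochastic initialization).
#' @param class_names names for the classes, lowest TFI first; default
#'   `"C1"..."Ck"`, or `"1n","2n","4c"` when `n_classes = 3`.
#' @param top_cut_quantile quantile of TFI at which the upper exclusion cut
#'   is placed (default 0.995).
#' @return A [threshold_set()] with `n_classes` cut points (the last one the
#'   upper exclusion bound) and `overflow_policy = "exclude"`.
#' @export
find_thresholds <- function(dataset, n_classes, method = c("mixture", "valley"),
                            seed = 1L, class_names = NULL,
                            top_cut_quantile = 0.995) {
  method <- match.arg(method)
  if (!inherits(dataset, "comet_dataset")) {
    abort_cometcal("`dataset` must be a comet_dataset", "cometcal_parameter_error")
  }
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) {
    abort_cometcal("`n_classes` must be >= 2", "cometcal_parameter_error")
  }
  if (nrow(dataset) < 10L * n_classes) {
    abort_cometcal(sprintf("need at least %d records for %d classes",
                           10L * n_classes, n_classes),
                   "cometcal_parameter_error")
  }
  if (is.null(class_names)) {
    class_names <- if (n_classes == 3L) c("1n", "2n", "4c") else
      paste0("C", seq_len(n_classes))
  }
  x <- log(dataset$tfi)
  cuts_log <- switch(method,
                     mixture = mixture_cuts(x, n_classes, seed),
                     valley = valley_cuts(x, n_classes))
  top <- stats::quantile(dataset$tfi, top_cut_quantile, names = FALSE, type = 7)
  cuts <- c(exp(cuts_log), top)
  if (is.unsorted(cuts, strictly = TRUE)) {
    abort_cometcal(
      "upper-quantile cut does not lie above the separating cuts; populations are not separable at the requested quantile",
      "cometcal_degenerate_separation_error")
  }
  threshold_set(cuts, class_names, overflow_policy = "exclude")
}

# EM mixture cuts on the log scale; the unequal-variance 1-D EM is fitted
# here (quantile-moment initialization plus seeded random restarts, which is
# far more reliable on strongly unbalanced ploidy mixtures than generic
# hierarchical initialization), and posterior-equality cut points are solved
# from the fitted components.
mixture_cuts <- function(x, k, seed) {
  set.seed(as.integer(seed))
  # model selection over 1..k components: if BIC prefers fewer than k, the
  # requested classes are not separable in this sample (e.g. a forced split
  # of one tight mode, which raw likelihood would happily accept)
  fits <- lapply(seq_len(k), function(g) em_normal_mixture(x, g))
  bic <- vapply(seq_len(k), function(g) {
    2 * fits[[g]]$loglik - (3 * g - 1) * log(length(x))
  }, numeric(1))
  achieved <- which.max(bic)
  if (achieved < k) {
    abort_cometcal(
      sprintf("only %d separable component(s) found where %d classes were requested",
              achieved, k),
      "cometcal_degenerate_separation_error")
  }
  fit <- fits[[k]]
  ord <- order(fit$mu)
  mu <- fit$mu[ord]
  sigma <- fit$sigma[ord]
  pro <- fit$pro[ord]
  vapply(seq_len(k - 1L), function(i) {
    posterior_equality_cut(pro[i], mu[i], sigma[i],
                           pro[i + 1L], mu[i + 1L], sigma[i + 1L])
  }, numeric(1))
}

# Expectation-maximization for a 1-D unequal-variance Gaussian mixture.
# First start: moments of a k-way quantile split; further starts perturb it.
# Convergence: log-likelihood change < 1e-8, at most 500 iterations.
em_normal_mixture <- function(x, k, n_restarts = 5L, tol = 1e-8,
                              max_iter = 500L) {
  n <- length(x)
  if (k == 1L) {
    return(list(mu = mean(x), sigma = max(stats::sd(x), 1e-6), pro = 1,
                loglik = sum(stats::dnorm(x, mean(x),
                                          max(stats::sd(x), 1e-6),
                                          log = TRUE))))
  }
  moment_init <- function(br, jitter) {
    if (jitter > 0) {
      br[2:k] <- br[2:k] + stats::rnorm(k - 1L, 0, jitter * stats::sd(x))
      br <- sort(br)
    }
    bin <- cut(x, unique(c(-Inf, br[2:k], Inf)), labels = FALSE)
    mu <- vapply(split(x, bin), mean, numeric(1))
    sigma <- vapply(split(x, bin), stats::sd, numeric(1))
    sigma[!is.finite(sigma) | sigma < 1e-6] <- stats::sd(x) / k
    pro <- tabulate(bin, k) / n
    if (length(mu) < k || any(pro == 0)) return(NULL)
    list(mu = mu, sigma = sigma, pro = pro)
  }
  run_em <- function(init) {
    mu <- init$mu; sigma <- init$sigma; pro <- init$pro
    ll_old <- -Inf
    for (iter in seq_len(max_iter)) {
      dens <- vapply(seq_len(k),
                     function(j) pro[j] * stats::dnorm(x, mu[j], sigma[j]),
                     numeric(n))
      tot <- rowSums(dens)
      tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
      ll <- sum(log(tot))
      resp <- dens / tot
      nk <- colSums(resp)
      if (any(nk < 1e-8)) return(NULL)  # component died
      mu <- colSums(resp * x) / nk
      sigma <- sqrt(vapply(seq_len(k), function(j) {
        sum(resp[, j] * (x - mu[j])^2) / nk[j]
      }, numeric(1)))
      sigma <- pmax(sigma, 1e-6)
      pro <- nk / n
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(mu = mu, sigma = sigma, pro = pro, loglik = ll)
  }
  # two deterministic starts (quantile split for balanced mixtures, equal-
  # width split for unbalanced ones) plus jittered variants of each
  br_quant <- stats::quantile(x, seq(0, 1, length.out = k + 1L), names = FALSE)
  br_width <- seq(min(x), max(x), length.out = k + 1L)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    for (br in list(br_quant, br_width)) {
      init <- moment_init(br, jitter = if (r == 1L) 0 else 0.5)
      if (is.null(init)) next
      fit <- run_em(init)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
  }
  if (is.null(best)) {
    abort_cometcal(sprintf("mixture fit with %d components failed", k),
                   "cometcal_degenerate_separation_error")
  }
  best
}

# pi_1 N(x; m1, s1) = pi_2 N(x; m2, s2): quadratic in x; take the root
# between the two means, falling back to the density valley if none lies there.
posterior_equality_cut <- function(p1, m1, s1, p2, m2, s2) {
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(p1 / p2) + log(s2 / s1)
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inside <- roots[roots > m1 & roots < m2]
  if (length(inside) >= 1L) return(inside[1L])
  grid <- seq(m1, m2, length.out = 512L)
  grid[which.min(p1 * stats::dnorm(grid, m1, s1) +
                   p2 * stats::dnorm(grid, m2, s2))]
}

valley_cuts <- function(x, k) {
  d <- stats::density(x, bw = "nrd0", n = 512L)
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n], FALSE)
  peaks <- which(is_max)
  if (length(peaks) < k) {
    abort_cometcal(
      sprintf("only %d separable mode(s) found where %d classes were requested",
              length(peaks), k),
      "cometcal_degenerate_separation_error")
  }
  top <- sort(peaks[order(y[peaks], decreasing = TRUE)][seq_len(k)])
  vapply(seq_len(k - 1L), function(i) {
    span <- seq(top[i], top[i + 1L])
    d$x[span[which.min(y[span])]]
  }, numeric(1))
}

#' Per-class composition and damage summary
#'
#' Summarizes a gated dataset: per class the comet count, the proportion of
#' classified comets, mean and median TFI, and mean, median and SD of the
#' chosen damage metric. Proportions are computed over classified comets
#' only; excluded comets (above the top cut) are counted separately so that
#' class counts plus `excluded_count` always reproduce the total.
#'
#' @param dataset a [comet_dataset()] previously passed through
#'   [classify_by_tfi()].
#' @param damage_metric `"tail_dna_pct"` or `"tail_moment"`.
#' @return A `gating_result`: list with `summary` (one row per class),
#'   `thresholds`, `excluded_count` and `n_total`.
#' @export
class_summary <- function(dataset,
                          damage_metric = c("tail_dna_pct", "tail_moment")) {
  damage_metric <- match.arg(damage_metric)
  thresholds <- attr(dataset, "thresholds")
  if (is.null(thresholds)) {
    abort_cometcal("dataset has not been classified; run classify_by_tfi() first",
                   "cometcal_parameter_error")
  }
  dmg <- dataset[[damage_metric]]
  if (all(is.na(dmg))) {
    abort_cometcal(sprintf("damage metric '%s' is absent from all records",
                           damage_metric),
                   "cometcal_missing_metric_error")
  }
  classes <- thresholds$class_names[thresholds$class_names %in%
                                      dataset$class_label]
  classified <- !is.na(dataset$class_label)
  n_classified <- sum(classified)
  rows <- lapply(classes, function(cl) {
    sel <- classified & dataset$class_label == cl
    data.frame(
      class_label = cl,
      count = sum(sel),
      proportion = sum(sel) / n_classified,
      mean_tfi = mean(dataset$tfi[sel]),
      median_tfi = stats::median(dataset$tfi[sel]),
      mean_damage = mean(dmg[sel], na.rm = TRUE),
      median_damage = stats::median(dmg[sel], na.rm = TRUE),
      sd_damage = stats::sd(dmg[sel], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  structure(list(summary = do.call(rbind, rows),
                 thresholds = thresholds,
                 damage_metric = damage_metric,
                 excluded_count = sum(!classified),
                 n_total = nrow(dataset)),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("<gating_result> %d comets (%d excluded), damage metric: %s\n",
              x$n_total, x$excluded_count, x$damage_metric))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Permutation test for equality of damage between classes
#'
#' Tests whether mean DNA damage differs between the gated classes, the
#' question behind reporting that damage in 1n/2n/4c control classes is
#' "low and very similar". The observed statistic is the maximum absolute
#' pairwise difference of class mean damage; the null distribution is built
#' by permuting class labels. When the number of distinct relabelings does
#' not exceed `n_permutations` the test enumerates them all (exact test);
#' otherwise it samples `n_permutations` random permutations. Either way the
#' +1-corrected estimate `p = (1 + #\{permuted >= observed\}) / (1 + N)` is
#' returned, so p is never exactly zero.
#'
#' @param dataset a classified [comet_dataset()].
#' @param damage_metric `"tail_dna_pct"` or `"tail_moment"`.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation draws.
#' @return List with `p_value`, `statistic` (observed max pairwise mean
#'   difference), `n_permutations` used and `exact` flag.
#' @export
compare_class_damage <- function(dataset,
                                 damage_metric = c("tail_dna_pct", "tail_moment"),
                                 n_permutations = 999L, seed = 1L) {
  damage_metric <- match.arg(damage_metric)
  keep <- !is.na(dataset$class_label) & !is.na(dataset[[damage_metric]])
  lab <- dataset$class_label[keep]
  dmg <- dataset[[damage_metric]][keep]
  tab <- table(lab)
  if (length(tab) < 2L || any(tab < 2L)) {
    abort_cometcal("need >= 2 classes with >= 2 records each",
                   "cometcal_degenerate_comparison_error")
  }
  max_pairwise <- function(labels) {
    m <- vapply(split(dmg, labels), mean, numeric(1))
    max(stats::dist(m))
  }
  observed <- max_pairwise(lab)
  n_distinct <- multiset_permutation_count(tab)
  if (!is.na(n_distinct) && n_distinct <= n_permutations) {
    perms <- multiset_permutations(lab)
    stats_null <- apply(perms, 1L, max_pairwise)
    exact <- TRUE
    used <- nrow(perms)
  } else {
    set.seed(as.integer(seed))
    stats_null <- vapply(seq_len(n_permutations),
                         function(i) max_pairwise(sample(lab)), numeric(1))
    exact <- FALSE
    used <- n_permutations
  }
  p <- (1 + sum(stats_null >= observed - 1e-12)) / (1 + used)
  list(p_value = p, statistic = observed, n_permutations = used, exact = exact)
}

multiset_permutation_count <- function(tab) {
  n <- sum(tab)
  if (n > 12L) return(NA_real_)  # would overflow usefulness anyway
  factorial(n) / prod(factorial(tab))
}

# All distinct orderings of a label multiset, one per row.
multiset_permutations <- function(lab) {
  rec <- function(remaining) {
    if (length(remaining) <= 1L) return(matrix(remaining, nrow = 1L))
    out <- list()
    for (v in unique(remaining)) {
      rest <- remaining[-match(v, remaining)]
      sub <- rec(rest)
      out[[length(out) + 1L]] <- cbind(v, sub, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  rec(lab)
}
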
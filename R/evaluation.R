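#' ROC analysis of a pathogenicity predictor
#'
#' Builds the receiver-operating-characteristic curve by sweeping a
#' threshold over the unique scores and computes the AUC as the normalised
#' Mann-Whitney U statistic: the probability that a random pathogenic
#' variant outscores a random benign one, ties credited one half.
#'
#' @param df Tibble with a score column and a label column.
#' @param score,label Column names (defaults `"score"`, `"label"`). The
#'   label column may be logical (`TRUE` = pathogenic) or the strings
#'   `"pathogenic"` / `"non_pathogenic"`.
#' @param higher_is_damaging Orientation flag: does a larger score mean
#'   more damaging? Scores are flipped internally when `FALSE` so curves
#'   and AUCs are comparable across predictors.
#' @return An object of class `roc_result`: list with `curve` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pathogenic`, `n_benign`,
#'   `n_missing` (rows dropped for missing scores).
#' @export
roc_curve <- function(df, score = "score", label = "label",
                      higher_is_damaging = TRUE) {
  s <- df[[score]]
  lab <- df[[label]]
  if (!is.logical(lab)) lab <- lab %in% c("pathogenic", "TRUE", "1")
  keep <- is.finite(s) & !is.na(lab)
  n_missing <- sum(!keep)
  s <- s[keep]
  lab <- lab[keep]
  if (!any(lab) || all(lab)) abort("need both pathogenic and benign variants")
  if (!higher_is_damaging) s <- -s
  n1 <- sum(lab)
  n0 <- sum(!lab)

  r <- rank(s) # midranks handle ties -> half credit
  u <- sum(r[lab]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)

  thr <- sort(unique(s), decreasing = TRUE)
  curve <- tibble(
    threshold = c(Inf, thr),
    tpr = vapply(c(Inf, thr), function(t) mean(s[lab] >= t), numeric(1)),
    fpr = vapply(c(Inf, thr), function(t) mean(s[!lab] >= t), numeric(1))
  )
  structure(
    list(
      curve = curve, auc = auc,
      n_pathogenic = n1, n_benign = n0, n_missing = n_missing
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f (%d pathogenic vs %d benign%s)\n",
    x$auc, x$n_pathogenic, x$n_benign,
    if (x$n_missing) sprintf(", %d unscored dropped", x$n_missing) else ""
  ))
  invisible(x)
}

#' @param object A `roc_result`.
#' @param ... Unused.
#' @rdname roc_curve
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    theme_minimal()
}

classify_at <- function(s, t) s >= t # ties classify to the pathogenic side

balanced_accuracy <- function(s, lab, t) {
  pred <- classify_at(s, t)
  (mean(pred[lab]) + mean(!pred[!lab])) / 2
}

#' Leave-one-out threshold classification accuracy
#'
#' For each variant in turn: a single decision threshold is chosen to
#' maximise balanced accuracy on all *other* variants, and the held-out
#' variant is classified against it (score at or above threshold =
#' pathogenic). Candidate thresholds are the observed scores, midpoints
#' between adjacent distinct scores, and +Inf. Returns the fraction
#' classified correctly together with the per-variant record. Among
#' equally good thresholds the smallest is used; this conservative tie
#' rule favours calling variants pathogenic, appropriate for a screening
#' context.
#'
#' @inheritParams roc_curve
#' @return A list: `accuracy`, and `predictions` (tibble with `score`,
#'   `label`, `threshold`, `predicted`, `correct`).
#' @export
loo_accuracy <- function(df, score = "score", label = "label",
                         higher_is_damaging = TRUE) {
  s <- df[[score]]
  lab <- df[[label]]
  if (!is.logical(lab)) lab <- lab %in% c("pathogenic", "TRUE", "1")
  keep <- is.finite(s) & !is.na(lab)
  s <- s[keep]
  lab <- lab[keep]
  n <- length(s)
  if (n < 3) abort("need at least 3 labeled variants")
  if (!higher_is_damaging) s <- -s

  pick_threshold <- function(st, lt) {
    u <- sort(unique(st))
    mid <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric()
    cand <- sort(unique(c(u, mid, Inf)))
    acc <- vapply(cand, function(t) balanced_accuracy(st, lt, t), numeric(1))
    cand[which.max(acc)] # which.max takes the first = smallest maximiser
  }
  thr <- vapply(seq_len(n), function(i) pick_threshold(s[-i], lab[-i]), numeric(1))
  pred <- classify_at(s, thr)
  res <- tibble(
    score = s, label = lab, threshold = thr,
    predicted = pred, correct = pred == lab
  )
  list(accuracy = mean(res$correct), predictions = res)
}

#' Bootstrap test for a difference in group means
#'
#' Resamples each group independently with replacement `n_resamples` times
#' and reports the one-sided p-value: the fraction of resamples in which
#' the claimed ordering fails, i.e. `mean(a*) <= mean(b*)` under the
#' alternative that group a's mean exceeds group b's.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param n_resamples Number of bootstrap draws (default 10000).
#' @param seed Integer seed.
#' @return A list of class `group_test`: observed means, `statistic`
#'   (mean difference a - b), `p_value`, `n_resamples`, `seed`,
#'   `sidedness`.
#' @export
bootstrap_group_diff <- function(values_a, values_b, n_resamples = 10000L,
                                 seed = 1L) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values")
  }
  set.seed(seed)
  na <- length(values_a)
  nb <- length(values_b)
  fails <- vapply(seq_len(n_resamples), function(r) {
    mean(values_a[sample.int(na, na, replace = TRUE)]) <=
      mean(values_b[sample.int(nb, nb, replace = TRUE)])
  }, logical(1))
  structure(
    list(
      mean_a = mean(values_a), mean_b = mean(values_b),
      statistic = mean(values_a) - mean(values_b),
      statistic_type = "mean_diff",
      p_value = mean(fails),
      n_resamples = n_resamples, seed = seed,
      sidedness = "one_sided (mean_a > mean_b)"
    ),
    class = "group_test"
  )
}

#' Permutation test for a difference in group location
#'
#' Two-sided by default. When the number of distinct group-a assignments
#' `choose(n_a + n_b, n_a)` is at most `exact_limit` the permutation
#' distribution is enumerated exhaustively; otherwise a seeded Monte-Carlo
#' sample of label shuffles is used (with the add-one correction).
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param statistic `"mean_diff"` or `"median_diff"`.
#' @param n_permutations Monte-Carlo draws when enumeration is infeasible.
#' @param seed Integer seed (Monte-Carlo only).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @param exact_limit Enumeration cutoff (default 1e5 arrangements).
#' @return A `group_test` list; `exact` records which route was taken.
#' @export
permutation_group_diff <- function(values_a, values_b,
                                   statistic = c("mean_diff", "median_diff"),
                                   n_permutations = 10000L, seed = 1L,
                                   alternative = c("two_sided", "greater", "less"),
                                   exact_limit = 1e5) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values")
  }
  fun <- if (statistic == "mean_diff") mean else median
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  n <- length(pooled)
  obs <- fun(values_a) - fun(values_b)

  stat_for <- function(idx_a) fun(pooled[idx_a]) - fun(pooled[-idx_a])
  n_arrangements <- choose(n, na)
  if (n_arrangements <= exact_limit) {
    combos <- combn(n, na)
    stats <- apply(combos, 2, stat_for)
    exact <- TRUE
    count <- switch(alternative,
      two_sided = sum(abs(stats) >= abs(obs) - 1e-12),
      greater = sum(stats >= obs - 1e-12),
      less = sum(stats <= obs + 1e-12)
    )
    p <- count / n_arrangements
  } else {
    set.seed(seed)
    stats <- vapply(seq_len(n_permutations), function(r) {
      stat_for(sample.int(n, na))
    }, numeric(1))
    exact <- FALSE
    count <- switch(alternative,
      two_sided = sum(abs(stats) >= abs(obs) - 1e-12),
      greater = sum(stats >= obs - 1e-12),
      less = sum(stats <= obs + 1e-12)
    )
    p <- (count + 1) / (n_permutations + 1)
  }
  structure(
    list(
      mean_a = mean(values_a), mean_b = mean(values_b),
      median_a = median(values_a), median_b = median(values_b),
      statistic = obs, statistic_type = statistic,
      p_value = p, exact = exact,
      n_resamples = if (exact) n_arrangements else n_permutations,
      seed = seed, sidedness = alternative
    ),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf(
    "group test (%s, %s): statistic = %.4g, p = %.4g (n = %d resamples)\n",
    x$statistic_type, x$sidedness, x$statistic, x$p_value, x$n_resamples
  ))
  invisible(x)
}

#' Squared Pearson correlation with significance
#'
#' @param x,y Numeric vectors of equal length (n >= 3, non-degenerate).
#' @return A one-row tibble: `r_squared`, `p_value`, `n` (two-sided p from
#'   the t transform of the correlation).
#' @export
correlation_r2 <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in input")
  ct <- cor.test(x, y, method = "pearson")
  tibble(
    r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value,
    n = length(x)
  )
}

#' Stability quartiles across allele-frequency bins
#'
#' Joins per-variant allele frequencies to ddG predictions and summarises
#' each frequency bin by its 25/50/75% ddG quartiles — the standard way to
#' show that common (likely benign) alleles are predicted stable.
#'
#' @param freqs Tibble with `variant`, `allele_frequency`.
#' @param ddg_df Tibble with `variant`, `ddg`.
#' @param bins Frequency bin edges (ascending, covering the data).
#' @return A tibble per bin: `bin`, `lower`, `upper`, `n`, `q25`, `median`,
#'   `q75` (quartiles `NA` for empty bins).
#' @export
frequency_vs_ddg <- function(freqs, ddg_df,
                             bins = c(0, 1e-5, 1e-4, 1e-3, 1e-2, 1)) {
  joined <- inner_join(
    select(freqs, "variant", "allele_frequency"),
    select(ddg_df, "variant", "ddg"),
    by = "variant"
  )
  if (nrow(joined) == 0) abort("no overlap between frequency and ddG tables")
  joined$bin <- cut(joined$allele_frequency, bins, include.lowest = TRUE)
  levels_all <- levels(joined$bin)
  out <- purrr::map_dfr(seq_along(levels_all), function(k) {
    v <- joined$ddg[joined$bin == levels_all[k] & !is.na(joined$bin)]
    if (length(v) == 0) {
      tibble(
        bin = levels_all[k], lower = bins[k], upper = bins[k + 1],
        n = 0L, q25 = NA_real_, median = NA_real_, q75 = NA_real_
      )
    } else {
      qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      tibble(
        bin = levels_all[k], lower = bins[k], upper = bins[k + 1],
        n = length(v), q25 = qs[1], median = qs[2], q75 = qs[3]
      )
    }
  })
  out
}
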
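test_that("AUC is the pairwise win probability with ties half-credited", {
  df <- tibble::tibble(
    score = c(3, 4, 5, 1, 2, 3),
    label = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  # oracle: brute force over all 9 pathogenic-benign pairs
  wins <- 0
  for (p in c(3, 4, 5)) {
    for (b in c(1, 2, 3)) {
      wins <- wins + (p > b) + 0.5 * (p == b)
    }
  }
  r <- roc_curve(df)
  expect_equal(r$auc, wins / 9)
  expect_equal(r$auc, 8.5 / 9)
})

test_that("ROC curves are anchored, monotone, and orientation-aware", {
  set.seed(41)
  df <- tibble::tibble(
    score = c(rnorm(30, 2), rnorm(40, 0)),
    label = rep(c(TRUE, FALSE), c(30, 40))
  )
  r <- roc_curve(df)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))

  sep <- tibble::tibble(score = c(5, 6, 1, 2), label = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_curve(sep)$auc, 1)

  flipped <- dplyr::mutate(df, label = !label)
  expect_equal(roc_curve(flipped)$auc, 1 - r$auc)

  low_is_bad <- dplyr::mutate(df, score = -score)
  expect_equal(roc_curve(low_is_bad, higher_is_damaging = FALSE)$auc, r$auc)

  # invariance under strictly monotone score transforms
  expect_equal(roc_curve(dplyr::mutate(df, score = exp(score)))$auc, r$auc)

  expect_error(roc_curve(sep[1:2, ]), "both")
})

test_that("AUC equals the normalised Mann-Whitney U from an external oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n1 <- sample(5:30, 1)
    n0 <- sample(5:30, 1)
    sc <- round(c(rnorm(n1, 1), rnorm(n0)), sample(c(0, 1, 3), 1)) # force ties sometimes
    df <- tibble::tibble(score = sc, label = rep(c(TRUE, FALSE), c(n1, n0)))
    w <- suppressWarnings(
      wilcox.test(sc[df$label], sc[!df$label], exact = FALSE)$statistic
    )
    expect_equal(roc_curve(df)$auc, unname(w) / (n1 * n0))
  }
})

test_that("shuffled labels give chance-level AUC", {
  set.seed(43)
  df <- tibble::tibble(
    score = rnorm(2000),
    label = sample(c(TRUE, FALSE), 2000, replace = TRUE)
  )
  expect_equal(roc_curve(df)$auc, 0.5, tolerance = 0.05)
})

test_that("leave-one-out accuracy behaves on the edge cases", {
  sep <- tibble::tibble(
    score = c(10, 9, 8, 1, 2, 3),
    label = rep(c(TRUE, FALSE), each = 3)
  )
  expect_equal(loo_accuracy(sep)$accuracy, 1)

  # identical scores: the tie rule classifies everything pathogenic
  ties <- tibble::tibble(score = rep(2, 5), label = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(loo_accuracy(ties)$accuracy, 3 / 5)

  expect_error(loo_accuracy(sep[1:2, ]), "at least 3")
})

test_that("leave-one-out thresholds match exhaustive enumeration", {
  df <- tibble::tibble(
    score = c(0.5, 2, 3, 3, 4.5, 6),
    label = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  )
  res <- loo_accuracy(df)
  # oracle: for each hold-out, try every candidate threshold directly
  bal <- function(s, l, t) (mean(s[l] >= t) + mean(s[!l] < t)) / 2
  preds <- vapply(seq_len(nrow(df)), function(i) {
    st <- df$score[-i]; lt <- df$label[-i]
    u <- sort(unique(st))
    cand <- sort(unique(c(u, (u[-1] + u[-length(u)]) / 2, Inf)))
    accs <- vapply(cand, function(t) bal(st, lt, t), numeric(1))
    t_star <- cand[which.max(accs)]
    df$score[i] >= t_star
  }, logical(1))
  expect_equal(res$predictions$predicted, preds)
  expect_equal(res$accuracy, mean(preds == df$label))
})

test_that("bootstrap group test is symmetric under identical groups and sharp under separation", {
  set.seed(44)
  vals <- rnorm(12)
  p_same <- bootstrap_group_diff(vals, vals, n_resamples = 4000, seed = 2)$p_value
  expect_equal(p_same, 0.5, tolerance = 0.05)

  p_sep <- bootstrap_group_diff(c(10, 10, 10), c(1, 1, 1),
    n_resamples = 10000, seed = 3
  )$p_value
  expect_lt(p_sep, 1e-3)

  expect_error(bootstrap_group_diff(1, c(1, 2)), "at least 2")

  # seeded: identical reruns give identical p-values
  x <- rnorm(8); y <- rnorm(8, 0.5)
  expect_identical(
    bootstrap_group_diff(x, y, n_resamples = 500, seed = 9)$p_value,
    bootstrap_group_diff(x, y, n_resamples = 500, seed = 9)$p_value
  )
})

test_that("exact permutation p-values match enumeration and Monte-Carlo", {
  g <- permutation_group_diff(c(1, 2), c(3, 4), statistic = "mean_diff")
  expect_true(g$exact)
  expect_equal(g$p_value, 2 / 6)

  same <- permutation_group_diff(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p_value, 1)

  set.seed(46)
  a <- rnorm(6)
  b <- rnorm(6, 1)
  ex <- permutation_group_diff(a, b, n_permutations = 10000, seed = 1)
  mc <- permutation_group_diff(a, b,
    n_permutations = 10000, seed = 1,
    exact_limit = 1 # force Monte-Carlo
  )
  expect_true(ex$exact)
  expect_false(mc$exact)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 10000)
  expect_lt(abs(ex$p_value - mc$p_value), 3 * se + 2e-4)

  med <- permutation_group_diff(c(1, 2, 10), c(3, 4, 5), statistic = "median_diff")
  expect_equal(med$statistic, 2 - 4)
})

test_that("MSH6-interaction groups differ in stability in the right direction", {
  t1 <- msh2_variants(include_wt = FALSE)
  reduced <- t1$ddg[t1$msh6_interaction %in% c("weak", "no")]
  normal <- t1$ddg[t1$msh6_interaction == "yes"]
  g <- permutation_group_diff(reduced, normal, statistic = "mean_diff")
  expect_gt(g$statistic, 0) # reduced-interaction variants are less stable
  expect_lt(g$p_value, 0.05)
})

test_that("squared correlation follows the closed form", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(correlation_r2(x, 2 * x + 1)$r_squared, 1)

  y <- c(2.0, 1.1, 3.9, 3.2, 6.1, 4.8)
  res <- correlation_r2(x, y)
  # oracle: direct covariance arithmetic
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r_squared, r_manual^2)
  tstat <- r_manual * sqrt(4 / (1 - r_manual^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 4))

  set.seed(47)
  big <- correlation_r2(rnorm(5000), rnorm(5000))
  expect_lt(big$r_squared, 0.01)

  expect_error(correlation_r2(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlation_r2(1:2, 2:3), "at least 3")
})

test_that("frequency bins summarise ddG by quartiles", {
  freqs <- tibble::tibble(
    variant = paste0("A", 1:5, "V"),
    allele_frequency = c(0.2, 0.4, 0.5, 0.6, 0.9)
  )
  ddg <- tibble::tibble(variant = paste0("A", 1:5, "V"), ddg = c(1, 2, 3, 4, 5))
  one <- frequency_vs_ddg(freqs, ddg, bins = c(0, 1))
  expect_equal(one$n, 5L)
  expect_equal(c(one$q25, one$median, one$q75), c(2, 3, 4))

  with_empty <- frequency_vs_ddg(freqs, ddg, bins = c(0, 1e-6, 1))
  expect_equal(with_empty$n, c(0L, 5L))
  expect_true(is.na(with_empty$median[1]))

  expect_error(
    frequency_vs_ddg(freqs, tibble::tibble(variant = "Q9R", ddg = 1)),
    "no overlap"
  )
})

test_that("common synthetic alleles look stable across frequency bins", {
  cfg <- synthetic_config(seed = 19, n_positions = 200)
  mat <- gen_ddg_matrix(cfg)
  fr <- gen_frequencies(mat, cfg)
  bins <- frequency_vs_ddg(fr, mat, bins = c(0, 1e-5, 1e-3, 1))
  med <- bins$median[bins$n > 0]
  expect_true(med[length(med)] < med[1])
})
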
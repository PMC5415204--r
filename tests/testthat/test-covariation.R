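test_that("identity weights match their definition on the worked examples", {
  aln <- msa(c("ACDEF", "ACDEF", "ACDEF"))
  w <- compute_weights(aln, theta = 0.8)
  expect_equal(w$weights, rep(1 / 3, 3))
  expect_equal(w$m_eff, 1)

  aln2 <- msa(c("ACDE", "APDF")) # 50% identity
  w2 <- compute_weights(aln2, theta = 0.8)
  expect_equal(w2$weights, c(1, 1))
  expect_equal(w2$m_eff, 2)
})

test_that("weights equal a brute-force pairwise-identity count", {
  set.seed(31)
  chars <- matrix(sample(c("A", "C", "G", "-"), 20 * 30, replace = TRUE), 20, 30)
  aln <- msa(chars, alphabet = c("A", "C", "G", "-"))
  w <- compute_weights(aln, theta = 0.5)

  oracle <- vapply(1:20, function(s) {
    nbr <- vapply(1:20, function(t) {
      mean(chars[s, ] == chars[t, ]) >= 0.5
    }, logical(1))
    1 / sum(nbr)
  }, numeric(1))
  expect_equal(w$weights, oracle)
  expect_equal(w$m_eff, sum(oracle))
})

test_that("independent-site fields are log weighted frequencies", {
  # 4-sequence toy with unequal weights: hand-computed frequency table
  aln <- msa(c("AA", "AA", "AV", "VV"), alphabet = c("A", "V", "-"))
  w <- compute_weights(aln, theta = 1) # duplicates share weight 1/2
  expect_equal(w$weights, c(0.5, 0.5, 1, 1))
  lambda <- 1e-9
  m <- fit_independent(aln, w, pseudocount = lambda)
  # column 1 weighted counts: A = 0.5 + 0.5 + 1 = 2, V = 1, Meff = 3
  expect_equal(m$h[1, 1] - m$h[1, 2], log(2 / 1), tolerance = 1e-6)
  # column 2 weighted counts: A = 0.5 + 0.5 = 1, V = 1 + 1 = 2
  expect_equal(m$h[2, 1] - m$h[2, 2], log(1 / 2), tolerance = 1e-6)
  expect_true(all(m$J == 0))

  # a uniform column has all fields equal (zero after gauge fixing)
  u <- msa(c("AC", "VC", "-C"), alphabet = c("A", "V", "C", "-"))
  mu <- fit_independent(u, uniform_weights(u), pseudocount = 0.1)
  expect_equal(mu$h[2, 3], max(mu$h[2, ]))
})

test_that("independent-model scores are log column-frequency ratios", {
  h <- matrix(log(c(0.9, 0.05, 0.05)), 1, 3, byrow = TRUE)
  m <- potts_model(h, alphabet = c("A", "V", "-"))
  aln <- msa(c("A", "A"), alphabet = c("A", "V", "-"))
  sc <- score_variants(m, aln, tibble::tibble(
    wt_aa = "A", position = 1L, mut_aa = "V"
  ))
  expect_equal(sc$score, log(0.9 / 0.05))
  expect_equal(round(sc$score, 2), 2.89)
})

test_that("the site pseudolikelihood matches direct enumeration on a toy MSA", {
  # 3 columns, 2 states; conditional probabilities computable by hand
  aln <- msa(c("AAB", "ABA", "BAA", "AAA"), alphabet = c("A", "B"))
  X <- aln$states
  q <- 2L
  Z <- cellstab:::one_hot(X, q)
  w <- rep(1, 4)
  set.seed(8)
  par <- rnorm(q + 3 * q * q, 0, 0.3)
  val <- cellstab:::site_nll(par, 2L, X, Z, w, 4, q, 0.01, 0.02)

  # direct: P(x_2 = a | x_1, x_3) from the same parameters
  p <- cellstab:::unpack_site_par(par, 2L, 3L, q)
  nll <- 0
  for (s in 1:4) {
    logits <- p$h
    for (j in c(1L, 3L)) {
      logits <- logits + p$Jm[(j - 1L) * q + X[s, j], ]
    }
    nll <- nll - (logits[X[s, 2]] - log(sum(exp(logits))))
  }
  expected <- nll / 4 + 0.01 * sum(p$h^2) + 0.02 * sum(p$Jm^2)
  expect_equal(val, expected)

  # analytic gradient agrees with finite differences
  g <- cellstab:::site_nll(par, 2L, X, Z, w, 4, q, 0.01, 0.02, gradient = TRUE)
  num <- vapply(seq_along(par), function(k) {
    e <- rep(0, length(par)); e[k] <- 1e-6
    (cellstab:::site_nll(par + e, 2L, X, Z, w, 4, q, 0.01, 0.02) -
      cellstab:::site_nll(par - e, 2L, X, Z, w, 4, q, 0.01, 0.02)) / 2e-6
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("a perfectly co-varying column pair carries the top coupling norm", {
  set.seed(14)
  # columns 1 and 2 always agree in pattern (AB or CD); columns 3-4 random
  n <- 120
  pick <- sample(c(TRUE, FALSE), n, replace = TRUE)
  chars <- cbind(
    ifelse(pick, "A", "C"),
    ifelse(pick, "B", "D"),
    sample(c("A", "B", "C", "D"), n, replace = TRUE),
    sample(c("A", "B", "C", "D"), n, replace = TRUE)
  )
  aln <- msa(chars, alphabet = c("A", "B", "C", "D"))
  fit <- fit_potts(aln, uniform_weights(aln), lambda_h = 0.01, lambda_J = 0.01)
  norms <- coupling_norms(fit)
  expect_equal(unlist(norms[1, c("i", "j")], use.names = FALSE), c(1L, 2L))
  expect_gt(norms$norm[1], 2 * norms$norm[2])
})

test_that("coupling norms shrink with the penalty when the truth is independent", {
  set.seed(15)
  ind <- potts_model(
    matrix(rnorm(6 * 3, 0, 0.7), 6, 3),
    alphabet = c("A", "B", "C")
  )
  aln <- sample_msa(ind, 400, burn_in = 50, thin = 2, seed = 9)
  w <- uniform_weights(aln)
  f_small <- fit_potts(aln, w, lambda_J = 0.01)
  f_large <- fit_potts(aln, w, lambda_J = 1)
  expect_lt(
    sum(coupling_norms(f_large)$norm),
    sum(coupling_norms(f_small)$norm)
  )
})

test_that("scores equal brute-force energy differences and ignore the gauge", {
  truth <- toy_potts()
  aln <- sample_msa(truth, 40, burn_in = 50, thin = 2, seed = 3)
  vars <- all_query_variants(aln)
  sc <- score_variants(truth, aln, vars)

  qry <- aln$states[aln$query_index, ]
  oracle <- vapply(seq_len(nrow(vars)), function(k) {
    mut_seq <- qry
    mut_seq[vars$position[k]] <- match(vars$mut_aa[k], truth$alphabet)
    sequence_energy(truth, qry) - sequence_energy(truth, mut_seq)
  }, numeric(1))
  expect_equal(sc$score, oracle)

  regauged <- gauge_zero_sum(truth)
  sc2 <- score_variants(regauged, aln, vars)
  expect_equal(sc2$score, sc$score, tolerance = 1e-10)

  # the zero-sum gauge actually holds
  expect_equal(rowSums(regauged$h), rep(0, truth$L), tolerance = 1e-10)
  expect_equal(sum(abs(rowSums(regauged$J[, , 2, 5]))), 0, tolerance = 1e-10)
  expect_equal(sum(abs(colSums(regauged$J[, , 2, 5]))), 0, tolerance = 1e-10)

  # self-substitution scores zero; unmapped positions get NA
  same <- score_variants(
    truth, aln,
    tibble::tibble(
      wt_aa = truth$alphabet[qry[1]], position = 1L,
      mut_aa = truth$alphabet[qry[1]]
    )
  )
  expect_equal(same$score, 0)
  off <- score_variants(
    truth, aln,
    tibble::tibble(wt_aa = "A", position = 99L, mut_aa = "B")
  )
  expect_true(is.na(off$score))
  expect_error(
    score_variants(
      truth, aln,
      tibble::tibble(
        wt_aa = truth$alphabet[(qry[1]) %% 4 + 1], position = 1L,
        mut_aa = truth$alphabet[(qry[1] + 1) %% 4 + 1]
      )
    ),
    "does not match"
  )
})

test_that("the Gibbs sampler reproduces model statistics and is seeded", {
  set.seed(16)
  h <- matrix(rnorm(4 * 3, 0, 1), 4, 3)
  ind <- potts_model(h, alphabet = c("A", "B", "C"))
  aln <- sample_msa(ind, 5000, burn_in = 100, thin = 1, seed = 4)
  probs <- exp(h) / rowSums(exp(h))
  for (i in 1:4) {
    emp <- tabulate(aln$states[, i], 3) / 5000
    se <- sqrt(probs[i, ] * (1 - probs[i, ]) / 5000)
    expect_true(all(abs(emp - probs[i, ]) <= 3 * se + 1e-3))
  }

  # a strong positive coupling makes the favoured joint state over-represented
  J <- array(0, dim = c(2, 2, 2, 2))
  J[1, 1, 1, 2] <- 2
  J[1, 1, 2, 1] <- 2
  cpl <- potts_model(matrix(0, 2, 2), J, alphabet = c("A", "B"))
  aln2 <- sample_msa(cpl, 3000, burn_in = 100, thin = 1, seed = 5)
  f1 <- mean(aln2$states[, 1] == 1)
  f2 <- mean(aln2$states[, 2] == 1)
  f12 <- mean(aln2$states[, 1] == 1 & aln2$states[, 2] == 1)
  expect_gt(f12, f1 * f2)

  expect_identical(
    sample_msa(ind, 50, burn_in = 20, thin = 2, seed = 11)$states,
    sample_msa(ind, 50, burn_in = 20, thin = 2, seed = 11)$states
  )
})

test_that("A2M input collapses insert states and maps query positions", {
  skip_if_not_installed("Biostrings")
  path <- withr::local_tempfile(fileext = ".a2m")
  writeLines(c(
    ">query", "MK-E",
    ">homolog1", "MRvaVE", # lowercase insert states collapse away
    ">homolog2", "M-.GE"
  ), path)
  aln <- read_msa(path)
  expect_equal(ncol(aln$states), 4)
  expect_equal(aln$column_map, c(1L, 2L, NA_integer_, 3L))
})
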
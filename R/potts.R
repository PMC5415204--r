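#' Construct a pairwise maximum-entropy (Potts) sequence model
#'
#' A global statistical model of an alignment: per-column fields `h` and
#' per-column-pair couplings `J` define an unnormalised log-probability
#' ("energy" here, higher = more likely)
#' `E(s) = sum_i h_i(s_i) + sum_{i<j} J_ij(s_i, s_j)`.
#' The independent-site special case (all `J = 0`) is the conventional
#' conservation model.
#'
#' @param h Numeric matrix, L x q: field for state a at column i.
#' @param J Numeric array, q x q x L x L, with `J[, , i, j]` the coupling
#'   block of columns i and j; must satisfy `J[, , j, i] == t(J[, , i, j])`
#'   and have zero diagonal blocks. Omit (or `NULL`) for an independent
#'   model.
#' @param alphabet State alphabet the state indices refer to.
#' @param gauge Name of the gauge convention the parameters are in.
#' @param lambda_h,lambda_J Regularisation strengths used during fitting
#'   (stored for provenance).
#' @return An object of class `potts_model`.
#' @export
potts_model <- function(h, J = NULL, alphabet, gauge = "none",
                        lambda_h = NA_real_, lambda_J = NA_real_) {
  L <- nrow(h)
  q <- ncol(h)
  if (is.null(J)) J <- array(0, dim = c(q, q, L, L))
  stopifnot(all(dim(J) == c(q, q, L, L)))
  for (i in seq_len(L)) {
    if (any(J[, , i, i] != 0)) abort("diagonal coupling blocks must be zero")
  }
  structure(
    list(
      h = h, J = J, alphabet = alphabet, gauge = gauge,
      lambda_h = lambda_h, lambda_J = lambda_J,
      L = L, q = q
    ),
    class = "potts_model"
  )
}

#' @export
print.potts_model <- function(x, ...) {
  coupled <- any(x$J != 0)
  cat(sprintf(
    "Potts model: L = %d columns, q = %d states, %s, gauge '%s'\n",
    x$L, x$q, if (coupled) "pairwise couplings" else "independent sites", x$gauge
  ))
  invisible(x)
}

#' Unnormalised log-probability of sequences under a Potts model
#'
#' @param model A [potts_model()].
#' @param states Integer vector (one sequence) or matrix (rows = sequences)
#'   of state indices into the model's alphabet.
#' @return Numeric vector of energies (higher = more probable).
#' @export
sequence_energy <- function(model, states) {
  if (is.vector(states)) states <- matrix(states, nrow = 1)
  L <- model$L
  apply(states, 1, function(s) {
    e <- sum(model$h[cbind(seq_len(L), s)])
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        e <- e + model$J[s[i], s[j], i, j]
      }
    }
    e
  })
}

#' Transform a Potts model to the zero-sum gauge
#'
#' Re-parameterises fields and couplings so that every field and every
#' coupling row/column sums to zero. Gauge transformations change no
#' energy *difference* between sequences, so mutation scores are invariant.
#'
#' @param model A [potts_model()].
#' @return The re-gauged `potts_model`.
#' @export
gauge_zero_sum <- function(model) {
  L <- model$L
  q <- model$q
  h <- model$h
  J <- model$J
  h_new <- h
  J_new <- array(0, dim = dim(J))
  for (i in seq_len(L)) {
    corr <- 0
    for (j in seq_len(L)) {
      if (j == i) next
      K <- J[, , i, j] # K[a, b] = J_ij(a, b)
      corr <- corr + rowMeans(K) - mean(K)
    }
    h_new[i, ] <- h[i, ] - mean(h[i, ]) + corr
  }
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      K <- J[, , i, j]
      K2 <- K - outer(rowMeans(K), rep(1, q)) -
        outer(rep(1, q), colMeans(K)) + mean(K)
      J_new[, , i, j] <- K2
      J_new[, , j, i] <- t(K2)
    }
  }
  potts_model(h_new, J_new, model$alphabet,
    gauge = "zero_sum",
    lambda_h = model$lambda_h, lambda_J = model$lambda_J
  )
}

weighted_frequencies <- function(aln, weights, pseudocount) {
  X <- aln$states
  q <- length(aln$alphabet)
  L <- ncol(X)
  w <- weights$weights
  f <- matrix(0, L, q)
  for (i in seq_len(L)) {
    cnt <- vapply(seq_len(q), function(a) sum(w[X[, i] == a]), numeric(1))
    f[i, ] <- (pseudocount + cnt) / (q * pseudocount + weights$m_eff)
  }
  f
}

#' Fit the independent-site (conservation) model
#'
#' Fields are log smoothed weighted column frequencies,
#' `h_i(a) = log f_i(a)` with
#' `f_i(a) = (lambda + c_i(a)) / (q lambda + Meff)` where `c_i(a)` is the
#' weighted count; couplings are identically zero. The result is gauge-fixed
#' to zero-sum (which leaves all mutation scores unchanged).
#'
#' @param aln An [msa()] object.
#' @param weights A [compute_weights()] result (computed at theta 0.8 if
#'   omitted).
#' @param pseudocount Smoothing pseudocount lambda (default 0.01 effective
#'   counts per state).
#' @return A `potts_model` with `J = 0`.
#' @export
fit_independent <- function(aln, weights = NULL, pseudocount = 0.01) {
  weights <- weights %||% compute_weights(aln)
  f <- weighted_frequencies(aln, weights, pseudocount)
  if (any(f == 0)) abort("zero-weight column state; increase the pseudocount")
  m <- potts_model(log(f),
    alphabet = aln$alphabet, gauge = "none",
    lambda_h = pseudocount, lambda_J = 0
  )
  gauge_zero_sum(m)
}

one_hot <- function(X, q) {
  n <- nrow(X)
  L <- ncol(X)
  Z <- matrix(0, n, L * q)
  for (j in seq_len(L)) {
    Z[cbind(seq_len(n), (j - 1L) * q + X[, j])] <- 1
  }
  Z
}

# Unpack one site's parameter vector: q field entries followed by the
# flattened (L*q) x q coupling matrix, with the site's own block forced 0.
unpack_site_par <- function(par, r, L, q) {
  h <- par[seq_len(q)]
  Jm <- matrix(par[-seq_len(q)], nrow = L * q, ncol = q)
  Jm[(r - 1L) * q + seq_len(q), ] <- 0
  list(h = h, Jm = Jm)
}

# Weighted, L2-regularised negative log pseudolikelihood of one site's
# conditional model (and its analytic gradient). Internal, but kept as a
# standalone so the objective can be checked against direct enumeration.
site_nll <- function(par, r, X, Z, w, m_eff, q, lambda_h, lambda_J,
                     gradient = FALSE) {
  n <- nrow(X)
  L <- ncol(X)
  y <- X[, r]
  p <- unpack_site_par(par, r, L, q)
  logits <- sweep(Z %*% p$Jm, 2, p$h, `+`)
  mx <- apply(logits, 1, max)
  E <- exp(logits - mx)
  rs <- rowSums(E)
  if (!gradient) {
    lse <- mx + log(rs)
    nll <- -sum(w * (logits[cbind(seq_len(n), y)] - lse)) / m_eff
    return(nll + lambda_h * sum(p$h^2) + lambda_J * sum(p$Jm^2))
  }
  Y <- matrix(0, n, q)
  Y[cbind(seq_len(n), y)] <- 1
  P <- E / rs
  G <- (P - Y) * w / m_eff
  gh <- colSums(G) + 2 * lambda_h * p$h
  gJ <- crossprod(Z, G) + 2 * lambda_J * p$Jm
  gJ[(r - 1L) * q + seq_len(q), ] <- 0
  c(gh, as.vector(gJ))
}

# Fit the conditional model of one site given all others: a weighted,
# L2-regularised multinomial logistic regression on one-hot encodings of
# the remaining columns.
fit_site_plm <- function(r, X, Z, w, m_eff, q, lambda_h, lambda_J,
                         tol, max_iter) {
  L <- ncol(X)
  fn <- function(par) {
    site_nll(par, r, X, Z, w, m_eff, q, lambda_h, lambda_J)
  }
  gr <- function(par) {
    site_nll(par, r, X, Z, w, m_eff, q, lambda_h, lambda_J, gradient = TRUE)
  }
  par0 <- numeric(q + L * q * q)
  res <- optim(par0, fn, gr,
    method = "L-BFGS-B",
    control = list(maxit = max_iter, pgtol = tol, factr = 10)
  )
  if (res$convergence != 0 && res$convergence != 52) {
    g <- gr(res$par)
    abort(sprintf(
      "pseudolikelihood fit for column %d did not converge (code %d, max |grad| %.3g)",
      r, res$convergence, max(abs(g))
    ))
  }
  unpack_site_par(res$par, r, L, q)
}

#' Fit a pairwise Potts model by regularised pseudolikelihood
#'
#' Maximises the weighted, L2-regularised pseudolikelihood: for each column
#' the conditional likelihood of its states given all other columns is a
#' multinomial logistic regression, fit independently per column
#' (asymmetric pseudolikelihood); coupling blocks are then symmetrised as
#' `J_ij = (J_ij^(i) + t(J_ji^(j))) / 2` and the model gauge-fixed to
#' zero-sum. Deterministic given the data and settings.
#'
#' @param aln An [msa()] object with at least 2 columns.
#' @param weights A [compute_weights()] result (computed at theta 0.8 if
#'   omitted); Meff must exceed 1.
#' @param lambda_h,lambda_J L2 penalties on fields and on each coupling
#'   block (defaults 0.01).
#' @param tol Projected-gradient tolerance for convergence (default 1e-5).
#' @param max_iter Iteration cap per column (default 500); non-convergence
#'   raises an error carrying the residual gradient norm.
#' @return A `potts_model` in the zero-sum gauge.
#' @export
fit_potts <- function(aln, weights = NULL, lambda_h = 0.01, lambda_J = 0.01,
                      tol = 1e-5, max_iter = 500L) {
  stopifnot(inherits(aln, "msa"))
  X <- aln$states
  L <- ncol(X)
  q <- length(aln$alphabet)
  if (L < 2) abort("need at least 2 columns to fit couplings")
  weights <- weights %||% compute_weights(aln)
  if (weights$m_eff <= 1) abort("effective sequence number must exceed 1")
  Z <- one_hot(X, q)

  fits <- lapply(seq_len(L), function(r) {
    fit_site_plm(
      r, X, Z, weights$weights, weights$m_eff, q,
      lambda_h, lambda_J, tol, max_iter
    )
  })
  h <- do.call(rbind, lapply(fits, `[[`, "h"))
  J <- array(0, dim = c(q, q, L, L))
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      # site i's regression: J^(i)_ij[a, b] = coefficient of (x_j = b) on
      # (x_i = a) lives in rows of block j, columns a
      Ji <- t(fits[[i]]$Jm[(j - 1L) * q + seq_len(q), , drop = FALSE]) # a x b
      Jj <- fits[[j]]$Jm[(i - 1L) * q + seq_len(q), , drop = FALSE] # a x b
      K <- (Ji + Jj) / 2
      J[, , i, j] <- K
      J[, , j, i] <- t(K)
    }
  }
  m <- potts_model(h, J, aln$alphabet,
    gauge = "none",
    lambda_h = lambda_h, lambda_J = lambda_J
  )
  gauge_zero_sum(m)
}

#' Frobenius norms of all coupling blocks
#'
#' A standard summary of interaction strength between column pairs; the
#' strongest co-varying pairs carry the largest norms.
#'
#' @param model A `potts_model`.
#' @return A tibble with columns `i`, `j` (`i < j`) and `norm`, sorted
#'   decreasing.
#' @export
coupling_norms <- function(model) {
  L <- model$L
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  out <- tibble(
    i = pairs[, 1], j = pairs[, 2],
    norm = vapply(
      seq_len(nrow(pairs)),
      function(k) sqrt(sum(model$J[, , pairs[k, 1], pairs[k, 2]]^2)),
      numeric(1)
    )
  )
  arrange(out, desc(.data$norm))
}

#' Score missense variants by wild-type-minus-mutant log-likelihood
#'
#' The covariation mutation-effect score: the energy difference between the
#' query sequence and the query with one substitution, all other positions
#' fixed. Positive scores mean the wild type is more probable than the
#' mutant, i.e. the substitution is predicted damaging. For an
#' independent-site model the score reduces to the log column-frequency
#' ratio `h_i(wt) - h_i(mut)`.
#'
#' @param model A `potts_model`.
#' @param aln The [msa()] the model was fit to (supplies the query sequence
#'   and the column map from reference positions to columns).
#' @param variants Tibble with columns `wt_aa`, `position`, `mut_aa` (see
#'   [parse_variant()]), positions in reference numbering.
#' @return The `variants` tibble with a `score` column added. Positions not
#'   covered by the alignment get `NA` ("no prediction"); a wild-type
#'   residue that contradicts the query raises an error.
#' @export
score_variants <- function(model, aln, variants) {
  stopifnot(inherits(model, "potts_model"), inherits(aln, "msa"))
  qry <- aln$states[aln$query_index, ]
  L <- model$L
  col_of <- match(variants$position, aln$column_map)
  wt_idx <- match(variants$wt_aa, model$alphabet)
  mut_idx <- match(variants$mut_aa, model$alphabet)
  if (any(is.na(wt_idx) | is.na(mut_idx))) {
    abort("variant residues outside the model alphabet")
  }
  covered <- !is.na(col_of)
  mism <- covered & qry[ifelse(covered, col_of, 1L)] != wt_idx
  if (any(mism)) {
    abort(paste0(
      "wild-type residue does not match the query at: ",
      paste(variants$position[mism], collapse = ", ")
    ))
  }
  score_one <- function(ci, wt, mut) {
    if (wt == mut) return(0)
    d <- model$h[ci, wt] - model$h[ci, mut]
    for (j in seq_len(L)) {
      if (j == ci) next
      d <- d + model$J[wt, qry[j], ci, j] - model$J[mut, qry[j], ci, j]
    }
    d
  }
  scores <- rep(NA_real_, nrow(variants))
  for (k in which(covered)) {
    scores[k] <- score_one(col_of[k], wt_idx[k], mut_idx[k])
  }
  mutate(variants, score = scores)
}

#' Gibbs-sample synthetic alignments from a Potts model
#'
#' Draws sequences from the model distribution by single-site Gibbs
#' sampling on one chain: after `burn_in` full sweeps, every `thin`-th
#' sweep's state is recorded until `n_sequences` rows are collected.
#' Seeded and reproducible.
#'
#' @param model A `potts_model`.
#' @param n_sequences Number of rows to return.
#' @param burn_in Discarded initial sweeps (default 200).
#' @param thin Sweeps between recorded samples (default 5).
#' @param seed Integer seed.
#' @return An [msa()] object over the model's alphabet (the first sampled
#'   sequence serves as query row).
#' @export
sample_msa <- function(model, n_sequences, burn_in = 200L, thin = 5L,
                       seed = 1L) {
  L <- model$L
  q <- model$q
  set.seed(seed)
  s <- sample.int(q, L, replace = TRUE)
  # J flattened so that the contribution of all partner columns to site i's
  # conditional logits is a row-indexed sum
  Jflat <- lapply(seq_len(L), function(i) {
    matrix(model$J[, , i, ], nrow = q) # q x (q * L), blocks by partner j
  })
  out <- matrix(0L, n_sequences, L)
  kept <- 0L
  sweep_no <- 0L
  while (kept < n_sequences) {
    sweep_no <- sweep_no + 1L
    for (i in seq_len(L)) {
      idx <- (seq_len(L) - 1L) * q + s
      idx <- idx[-i]
      logits <- model$h[i, ] + rowSums(Jflat[[i]][, idx, drop = FALSE])
      p <- exp(logits - max(logits))
      s[i] <- sample.int(q, 1L, prob = p)
    }
    if (sweep_no > burn_in && (sweep_no - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- s
    }
  }
  msa(
    matrix(model$alphabet[out], nrow = n_sequences),
    query_index = 1L, alphabet = model$alphabet
  )
}
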
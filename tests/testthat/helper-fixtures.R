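# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures.

# A small Potts model with one strongly coupled column pair (2, 5).
toy_potts <- function(L = 8, q = 4, coupling_sd = 1.2, field_sd = 0.5,
                      seed = 42) {
  set.seed(seed)
  alphabet <- LETTERS[seq_len(q)]
  h <- matrix(rnorm(L * q, 0, field_sd), L, q)
  J <- array(0, dim = c(q, q, L, L))
  K <- matrix(rnorm(q * q, 0, coupling_sd), q, q)
  J[, , 2, 5] <- K
  J[, , 5, 2] <- t(K)
  potts_model(h, J, alphabet)
}

# All single substitutions of an msa's query sequence, as a variant tibble.
all_query_variants <- function(aln) {
  qry <- aln$states[aln$query_index, ]
  L <- length(qry)
  q <- length(aln$alphabet)
  grid <- expand.grid(position = seq_len(L), mut = seq_len(q))
  grid <- grid[grid$mut != qry[grid$position], ]
  tibble::tibble(
    wt_aa = aln$alphabet[qry[grid$position]],
    position = grid$position,
    mut_aa = aln$alphabet[grid$mut]
  )
}

# Long-format replicate/chain ddG records for a handful of variants.
toy_ddg_long <- function(n_variants = 6, n_replicates = 5, n_chains = 2,
                         seed = 1) {
  set.seed(seed)
  wt <- sample(cellstab:::AA_ALPHABET, n_variants, replace = TRUE)
  mut <- vapply(wt, function(a) {
    sample(setdiff(cellstab:::AA_ALPHABET, a), 1)
  }, character(1))
  base <- tibble::tibble(
    variant = paste0(wt, seq_len(n_variants), mut),
    wt_aa = wt, position = seq_len(n_variants), mut_aa = mut
  )
  tidyr::expand_grid(
    base,
    replicate = seq_len(n_replicates),
    chain = LETTERS[seq_len(n_chains)]
  ) |>
    dplyr::mutate(ddg = rnorm(dplyr::n(), mean = 2, sd = 1.5))
}
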
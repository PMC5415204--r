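#' Configuration for the synthetic-data generators
#'
#' Collects every knob of the simulated study in one place so that each
#' generator is a pure function of (config, seed). The ddG distribution is
#' a two-component mixture — a near-zero bulk of tolerated substitutions
#' plus a destabilising right tail — with buried positions drawing from the
#' tail more often and substitutions to proline paying a fixed extra
#' penalty. Phenotypes are generated from the two-state model itself, so
#' parameter-recovery experiments close the loop.
#'
#' @param seed Integer seed (mandatory; every generator derives its random
#'   stream from it).
#' @param n_positions Number of resolved residues (default 855).
#' @param burial_fraction Fraction of positions treated as buried
#'   (default 0.3, typical of a globular protein core).
#' @param bulk_mean,bulk_sd Normal bulk component, kcal/mol (0.5, 0.8).
#' @param tail_shape,tail_scale,tail_shift Gamma destabilising tail,
#'   shifted right (shape 2, scale 3, shift +2 kcal/mol).
#' @param tail_prob_buried,tail_prob_exposed Tail mixing probabilities
#'   (0.35 buried, 0.08 exposed).
#' @param proline_penalty Extra ddG for substitutions to proline (+2).
#' @param dg_wt_true True effective wild-type stability used to generate
#'   phenotypes (-3.0 kcal/mol).
#' @param level_noise_sigma Lognormal sd of multiplicative abundance noise
#'   (0.15).
#' @param half_life_wt Wild-type half-life in hours (19).
#' @param half_life_noise_sigma Lognormal sd on half-lives (0.2).
#' @param s_folded,s_unfolded Survival anchors in percent: fully folded
#'   protein is functional so cells die under the challenge (0); unfolded
#'   protein is non-functional so cells survive (100).
#' @param survival_noise_sd Additive Gaussian noise on survival,
#'   percentage points (5).
#' @param label_noise Probability of flipping a pathogenicity label (0.1).
#' @param pathogenic_cutoff ddG above which a variant is labelled
#'   pathogenic before noise (3 kcal/mol).
#' @param freq_log10_base,freq_log10_slope,freq_log10_sd Allele-frequency
#'   model: `log10 f = base - slope * max(ddg, 0) + Normal(0, sd)`,
#'   clipped to at most 1.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_positions = 855L,
                             burial_fraction = 0.3,
                             bulk_mean = 0.5, bulk_sd = 0.8,
                             tail_shape = 2, tail_scale = 3, tail_shift = 2,
                             tail_prob_buried = 0.35, tail_prob_exposed = 0.08,
                             proline_penalty = 2,
                             dg_wt_true = -3.0,
                             level_noise_sigma = 0.15,
                             half_life_wt = 19,
                             half_life_noise_sigma = 0.2,
                             s_folded = 0, s_unfolded = 100,
                             survival_noise_sd = 5,
                             label_noise = 0.1,
                             pathogenic_cutoff = 3,
                             freq_log10_base = -3,
                             freq_log10_slope = 0.5,
                             freq_log10_sd = 1) {
  if (missing(seed)) abort("synthetic_config requires an explicit seed")
  cfg <- as.list(environment())
  probs <- c(
    burial_fraction, tail_prob_buried, tail_prob_exposed, label_noise
  )
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic saturation-mutagenesis ddG matrix
#'
#' Draws a full 19-substitutions-per-position matrix over a random
#' wild-type sequence. Most substitutions fall in the near-zero bulk; a
#' position-dependent fraction draws from the destabilising tail (buried
#' positions more often), and substitutions to proline receive the extra
#' structural penalty. Reproducible from the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A tibble (`variant`, `wt_aa`, `position`, `mut_aa`, `ddg`) with
#'   a `buried` logical column.
#' @export
gen_ddg_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  p <- config$n_positions
  wt <- sample(AA_ALPHABET, p, replace = TRUE)
  buried <- runif(p) < config$burial_fraction
  grid <- saturation_variants(wt)
  grid$buried <- buried[match(grid$position, seq_len(p))]
  n <- nrow(grid)
  tail_p <- ifelse(grid$buried, config$tail_prob_buried, config$tail_prob_exposed)
  from_tail <- runif(n) < tail_p
  ddg <- ifelse(
    from_tail,
    config$tail_shift + rgamma(n, shape = config$tail_shape, scale = config$tail_scale),
    rnorm(n, config$bulk_mean, config$bulk_sd)
  )
  ddg <- ddg + ifelse(grid$mut_aa == "P", config$proline_penalty, 0)
  mutate(grid, ddg = ddg)
}

#' Generate phenotypes from a ddG matrix under the two-state model
#'
#' Steady-state levels are `predicted_level(dg_wt_true, ddg)` times
#' multiplicative lognormal noise; half-lives follow a monotone map from
#' fraction folded (`t_half = t_half_WT * (0.15 + 0.85 * level)`) with
#' lognormal noise; survival interpolates between the folded and unfolded
#' anchors with additive Gaussian noise clipped to [0, 100]. A wild-type
#' reference row (ddg = 0) is included when `include_wt` is `TRUE`.
#'
#' @param ddg_df Tibble with `variant` and `ddg` columns (e.g. a subset of
#'   [gen_ddg_matrix()] output).
#' @param config A [synthetic_config()].
#' @param include_wt Add the wild-type row (default `TRUE`).
#' @return A phenotype tibble: `variant`, `ddg`, `level`, `half_life_h`,
#'   `survival_pct`, `wildtype`.
#' @export
gen_phenotypes <- function(ddg_df, config, include_wt = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  df <- select(ddg_df, "variant", "ddg")
  if (include_wt) {
    df <- bind_rows(tibble(variant = "WT", ddg = 0), df)
  }
  n <- nrow(df)
  m <- thermo_model(config$dg_wt_true)
  lvl <- predicted_level(m, df$ddg)
  noise <- if (config$level_noise_sigma > 0) {
    rlnorm(n, 0, config$level_noise_sigma)
  } else {
    rep(1, n)
  }
  hl_noise <- if (config$half_life_noise_sigma > 0) {
    rlnorm(n, 0, config$half_life_noise_sigma)
  } else {
    rep(1, n)
  }
  surv <- config$s_unfolded + (config$s_folded - config$s_unfolded) * lvl
  if (config$survival_noise_sd > 0) {
    surv <- surv + rnorm(n, 0, config$survival_noise_sd)
  }
  tibble(
    variant = df$variant,
    ddg = df$ddg,
    level = lvl * noise,
    half_life_h = config$half_life_wt * (0.15 + 0.85 * lvl) * hl_noise,
    survival_pct = pmin(pmax(surv, 0), 100),
    wildtype = df$variant == "WT"
  )
}

#' Generate noisy pathogenicity labels from true ddG values
#'
#' A variant is labelled pathogenic when its true ddG exceeds the cutoff
#' (default 3 kcal/mol — the destabilisation at which degradation sets in),
#' then each label is flipped independently with probability `label_noise`.
#'
#' @inheritParams gen_phenotypes
#' @return A tibble: `variant`, `ddg`, `label` (`"pathogenic"` /
#'   `"non_pathogenic"`), `true_label`.
#' @export
gen_labels <- function(ddg_df, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  truth <- ddg_df$ddg > config$pathogenic_cutoff
  flip <- runif(nrow(ddg_df)) < config$label_noise
  lab <- xor(truth, flip)
  tibble(
    variant = ddg_df$variant,
    ddg = ddg_df$ddg,
    label = ifelse(lab, "pathogenic", "non_pathogenic"),
    true_label = ifelse(truth, "pathogenic", "non_pathogenic")
  )
}

#' Generate allele frequencies anti-correlated with destabilisation
#'
#' Expected log10 frequency decreases linearly with (positive) ddG, so
#' common alleles are predicted stable, mirroring what population databases
#' show for benign variation.
#'
#' @inheritParams gen_phenotypes
#' @return A tibble: `variant`, `ddg`, `allele_frequency` in (0, 1].
#' @export
gen_frequencies <- function(ddg_df, config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 3L)
  n <- nrow(ddg_df)
  lg <- config$freq_log10_base -
    config$freq_log10_slope * pmax(ddg_df$ddg, 0) +
    rnorm(n, 0, config$freq_log10_sd)
  tibble(
    variant = ddg_df$variant,
    ddg = ddg_df$ddg,
    allele_frequency = pmin(10^lg, 1)
  )
}
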
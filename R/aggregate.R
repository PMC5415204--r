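#' Enumerate a full saturation-mutagenesis variant grid
#'
#' All 19 possible single-residue substitutions at every position of a
#' wild-type sequence: a protein of P resolved residues yields exactly
#' 19 * P variants.
#'
#' @param wt_sequence Wild-type amino-acid sequence, either a single string
#'   or a character vector of one-letter codes.
#' @param positions Optional integer vector of residue numbers (defaults to
#'   `1:length(sequence)`); use this when the structure's author numbering
#'   does not start at 1 or has gaps.
#' @return A tibble with columns `variant`, `wt_aa`, `position`, `mut_aa`.
#' @examples
#' nrow(saturation_variants("MAVQ")) # 4 * 19
#' @export
saturation_variants <- function(wt_sequence, positions = NULL) {
  aa <- if (length(wt_sequence) == 1L) {
    strsplit(toupper(wt_sequence), "")[[1]]
  } else {
    toupper(wt_sequence)
  }
  if (!all(aa %in% AA_ALPHABET)) {
    abort("wild-type sequence contains non-canonical residues")
  }
  positions <- positions %||% seq_along(aa)
  if (length(positions) != length(aa)) {
    abort("positions must match sequence length")
  }
  grid <- tidyr::expand_grid(
    idx = seq_along(aa),
    mut_aa = AA_ALPHABET
  ) |>
    mutate(wt_aa = aa[.data$idx], position = positions[.data$idx]) |>
    filter(.data$mut_aa != .data$wt_aa) |>
    transmute(
      variant = paste0(.data$wt_aa, .data$position, .data$mut_aa),
      wt_aa = .data$wt_aa, position = .data$position, mut_aa = .data$mut_aa
    )
  grid
}

#' Aggregate replicate- and chain-resolved ddG predictions
#'
#' Reduces raw per-run stability predictions to one ddG value per variant.
#' Two aggregation schemes are supported, matching the conventions of the
#' two widely used structure-based calculators:
#'
#' * `"mean_replicates_chains"` (FoldX-style): arithmetic mean over
#'   replicate runs within each chain, then the mean across chains. With
#'   balanced data this equals a grand mean; the two-stage order matters for
#'   unbalanced input and is therefore fixed.
#' * `"lowest_k_of_n"` (Rosetta-style): the mean of the `k` lowest of `n`
#'   replicate model energies per variant.
#'
#' @param df Long tibble as returned by [read_ddg_long()]: columns `variant`,
#'   `wt_aa`, `position`, `mut_aa`, `ddg`, and optionally `replicate`,
#'   `chain`.
#' @param scheme Aggregation scheme (see above).
#' @param k,n For `"lowest_k_of_n"`: take the mean of the `k` smallest of
#'   exactly `n` values per variant. Defaults 3 of 15.
#' @return A tibble with one row per variant (`variant`, `wt_aa`, `position`,
#'   `mut_aa`, `ddg`) carrying the scheme in the `"provenance"` attribute.
#' @export
aggregate_ddg <- function(df,
                          scheme = c("mean_replicates_chains", "lowest_k_of_n"),
                          k = 3L, n = 15L) {
  scheme <- match.arg(scheme)
  if (nrow(df) == 0) abort("empty ddG table")
  if (!"chain" %in% names(df)) df$chain <- "A"
  if (!"replicate" %in% names(df)) df$replicate <- 1L

  dup <- df |>
    count(.data$variant, .data$chain, .data$replicate) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "duplicate (variant, chain, replicate) cells for: ",
      paste(unique(dup$variant), collapse = ", ")
    ))
  }
  wt_conflict <- df |>
    distinct(.data$position, .data$wt_aa) |>
    count(.data$position) |>
    filter(.data$n > 1)
  if (nrow(wt_conflict) > 0) {
    abort(paste0(
      "conflicting wild-type residues at position(s): ",
      paste(wt_conflict$position, collapse = ", ")
    ))
  }

  if (scheme == "mean_replicates_chains") {
    out <- df |>
      group_by(.data$variant, .data$wt_aa, .data$position, .data$mut_aa, .data$chain) |>
      summarise(ddg = mean(.data$ddg), .groups = "drop") |>
      group_by(.data$variant, .data$wt_aa, .data$position, .data$mut_aa) |>
      summarise(ddg = mean(.data$ddg), .groups = "drop")
  } else {
    counts <- df |> count(.data$variant)
    if (any(counts$n != n)) {
      abort(paste0(
        "lowest_k_of_n requires exactly ", n, " values per variant; offending: ",
        paste(head(counts$variant[counts$n != n], 5), collapse = ", ")
      ))
    }
    out <- df |>
      group_by(.data$variant, .data$wt_aa, .data$position, .data$mut_aa) |>
      summarise(ddg = mean(sort(.data$ddg)[seq_len(k)]), .groups = "drop")
  }
  out <- arrange(out, .data$position, .data$mut_aa)
  attr(out, "provenance") <- list(
    scheme = scheme,
    k = if (scheme == "lowest_k_of_n") k else NA_integer_,
    n = if (scheme == "lowest_k_of_n") n else NA_integer_
  )
  out
}

#' Summarise a ddG dataset against stability thresholds
#'
#' Counts variants, reports the mean ddG, and for each threshold the
#' percentage of variants satisfying it (over all stored variants).
#'
#' @param df Aggregated ddG tibble (columns `variant`, `ddg`).
#' @param thresholds Character vector of comparator-cutoff expressions such
#'   as `c("< -1", "> 5")` (kcal/mol).
#' @return A list with `n`, `mean_ddg`, and a tibble `thresholds` with
#'   columns `threshold`, `n_satisfying`, `percent`.
#' @export
summarize_ddg <- function(df, thresholds = c("< -1", "> 5")) {
  if (nrow(df) == 0) abort("empty ddG table")
  parsed <- lapply(thresholds, function(t) {
    m <- regexec("^\\s*(<=|>=|<|>)\\s*(-?[0-9.]+)\\s*$", t)[[1]]
    p <- regmatches(t, regexec("^\\s*(<=|>=|<|>)\\s*(-?[0-9.]+)\\s*$", t))[[1]]
    if (length(p) != 3) abort(paste0("cannot parse threshold: ", t))
    list(op = p[2], cut = as.numeric(p[3]))
  })
  th <- purrr::map_dfr(seq_along(parsed), function(i) {
    op <- match.fun(parsed[[i]]$op)
    ok <- op(df$ddg, parsed[[i]]$cut)
    tibble(
      threshold = thresholds[i],
      n_satisfying = sum(ok),
      percent = 100 * mean(ok)
    )
  })
  list(n = nrow(df), mean_ddg = mean(df$ddg), thresholds = th)
}

#' Mean ddG (with SEM) over a phenotype-defined subset
#'
#' Computes the arithmetic mean and standard error (sample sd / sqrt(n)) of
#' ddG over the variants selected by a filter expression, e.g. the
#' patient-found variants or those retaining MSH6 interaction.
#'
#' @param df Tibble with a `ddg` column plus whatever phenotype columns the
#'   predicate uses (the wild-type reference row, if present, is excluded
#'   first — group means are statements about variants).
#' @param predicate Filter expression evaluated with data masking, e.g.
#'   `patient_found` or `msh6_interaction == "yes"`.
#' @return A one-row tibble: `n`, `mean_ddg`, `sem_ddg`.
#' @examples
#' msh2_variants() |> subset_mean_ddg(patient_found)
#' @export
subset_mean_ddg <- function(df, predicate) {
  if ("wildtype" %in% names(df)) df <- filter(df, !.data$wildtype)
  sel <- filter(df, {{ predicate }})
  if (nrow(sel) < 2) abort("predicate selects fewer than 2 variants")
  tibble(
    n = nrow(sel),
    mean_ddg = mean(sel$ddg),
    sem_ddg = sd(sel$ddg) / sqrt(nrow(sel))
  )
}

#' Lay a ddG dataset out as a position-by-residue heat-map grid
#'
#' Produces the 20-residue-by-position grid used for heat-map rendering.
#' Displayed values are clipped at `+cap` kcal/mol (a display convention:
#' very destabilising substitutions saturate the colour scale); raw values
#' are carried alongside untouched. Wild-type cells are marked, not valued.
#'
#' @param df Aggregated ddG tibble (`wt_aa`, `position`, `mut_aa`, `ddg`).
#' @param cap Upper display clip in kcal/mol (default 7). One-sided:
#'   stabilising (negative) values are never clipped.
#' @return A tibble with one row per (position, residue) cell: `position`,
#'   `aa`, `ddg` (raw, `NA` at wild-type cells), `display_ddg` (clipped),
#'   `is_wt`.
#' @export
ddg_heatmap_grid <- function(df, cap = 7) {
  wt <- df |> distinct(.data$position, .data$wt_aa)
  grid <- tidyr::expand_grid(
    position = sort(unique(df$position)),
    aa = AA_ALPHABET
  ) |>
    left_join(wt, by = "position") |>
    mutate(is_wt = .data$aa == .data$wt_aa) |>
    left_join(
      df |> select("position", aa = "mut_aa", "ddg"),
      by = c("position", "aa")
    ) |>
    mutate(display_ddg = pmin(.data$ddg, cap)) |>
    select("position", "aa", "ddg", "display_ddg", "is_wt")
  grid
}

#' Write a heat-map grid as TSV
#'
#' Rows are the 20 residues, columns the positions; wild-type cells are
#' written as `WT`. Values are the display-clipped ddGs.
#'
#' @param grid Output of [ddg_heatmap_grid()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(grid, path) {
  wide <- grid |>
    mutate(cell = ifelse(.data$is_wt, "WT", formatC(.data$display_ddg, digits = 6, format = "g"))) |>
    select("position", "aa", "cell") |>
    tidyr::pivot_wider(names_from = "position", values_from = "cell")
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heat-map plot of a saturation-mutagenesis ddG grid
#'
#' @param df Aggregated ddG tibble.
#' @param cap Display clip in kcal/mol passed to [ddg_heatmap_grid()].
#' @return A ggplot object.
#' @export
plot_ddg_heatmap <- function(df, cap = 7) {
  grid <- ddg_heatmap_grid(df, cap = cap)
  ggplot(grid, aes(x = .data$position, y = .data$aa, fill = .data$display_ddg)) +
    geom_tile() +
    geom_point(data = filter(grid, .data$is_wt), size = 0.4, colour = "black") +
    scale_fill_gradient2(
      low = "steelblue", mid = "turquoise", high = "red3",
      midpoint = 0, na.value = "grey90",
      name = expression(Delta * Delta * G ~ "(kcal/mol)")
    ) +
    labs(x = "residue position", y = "substituted residue") +
    theme_minimal()
}
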
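#' Parse missense variant strings
#'
#' Parses variant strings in the conventional `<wt><position><mut>` notation
#' (e.g. `"L187P"`) into their components. Positions are 1-based and follow
#' the numbering of whatever structure or sequence produced the input table;
#' no renumbering is attempted.
#'
#' @param x Character vector of variant strings.
#' @return A tibble with one row per input and columns `variant`, `wt_aa`,
#'   `position` (integer), `mut_aa`.
#' @details The wild-type and mutant residues must be distinct members of the
#'   20-letter canonical amino-acid alphabet. Malformed strings raise an error
#'   naming the offending token.
#' @examples
#' parse_variant(c("L187P", "A54Y"))
#' @export
parse_variant <- function(x) {
  if (length(x) == 0) {
    return(tibble(
      variant = character(), wt_aa = character(),
      position = integer(), mut_aa = character()
    ))
  }
  x <- as.character(x)
  m <- regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x)
  parts <- regmatches(x, m)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    abort(paste0(
      "malformed variant string(s): ",
      paste(unique(x[bad]), collapse = ", ")
    ))
  }
  wt <- toupper(vapply(parts, `[[`, character(1), 2L))
  pos <- as.integer(vapply(parts, `[[`, character(1), 3L))
  mut <- toupper(vapply(parts, `[[`, character(1), 4L))
  bad_aa <- !(wt %in% AA_ALPHABET) | !(mut %in% AA_ALPHABET)
  if (any(bad_aa)) {
    abort(paste0(
      "non-canonical residue in variant(s): ",
      paste(unique(x[bad_aa]), collapse = ", ")
    ))
  }
  same <- wt == mut
  if (any(same)) {
    abort(paste0(
      "wild-type and mutant residue identical in: ",
      paste(unique(x[same]), collapse = ", ")
    ))
  }
  if (any(pos < 1L)) {
    abort("variant positions must be >= 1")
  }
  tibble(
    variant = paste0(wt, pos, mut),
    wt_aa = wt, position = pos, mut_aa = mut
  )
}

#' Format variant components back into strings
#'
#' Inverse of [parse_variant()]: `format_variant(parse_variant(x))` returns
#' `x` (upper-cased).
#'
#' @param df Data frame with columns `wt_aa`, `position`, `mut_aa`.
#' @return Character vector of variant strings.
#' @export
format_variant <- function(df) {
  paste0(df$wt_aa, df$position, df$mut_aa)
}

#' Read a long-format ddG table
#'
#' Reads per-variant stability predictions from CSV with columns `variant`,
#' `ddg` and optionally `replicate`, `chain`, `calculator`. Each row is one
#' raw prediction (one replicate run on one chain); use [aggregate_ddg()] to
#' reduce to one value per variant.
#'
#' @param path Path to a CSV file.
#' @return A tibble with parsed variant columns plus `ddg` and any provenance
#'   columns present in the file.
#' @export
read_ddg_long <- function(path) {
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE, comment.char = "#"))
  if (!all(c("variant", "ddg") %in% names(raw))) {
    abort("ddG table must have columns 'variant' and 'ddg'")
  }
  if (any(!is.finite(raw$ddg))) {
    abort("non-finite ddg values in input")
  }
  keys <- parse_variant(raw$variant)
  bind_cols(keys, raw[setdiff(names(raw), "variant")])
}

#' Read a per-variant phenotype table
#'
#' Reads cellular measurements keyed by variant: relative steady-state level,
#' half-life (hours) with standard deviation, MSH6-interaction category
#' (`yes`/`weak`/`no`), patient-found flag, nuclear localisation and optional
#' survival percentage. Only `variant` is mandatory; absent columns are left
#' out. A row whose variant field is `"WT"` (case-insensitive) is kept as the
#' wild-type reference and flagged `wildtype = TRUE` with `NA` key columns.
#'
#' @param path Path to a CSV file with a `variant` column.
#' @return A tibble keyed by variant, with a logical `wildtype` column.
#' @export
read_phenotypes <- function(path) {
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE, comment.char = "#"))
  if (!"variant" %in% names(raw)) {
    abort("phenotype table must have a 'variant' column")
  }
  is_wt <- toupper(raw$variant) == "WT"
  keys <- tibble(
    variant = toupper(raw$variant),
    wt_aa = NA_character_, position = NA_integer_, mut_aa = NA_character_
  )
  if (any(!is_wt)) {
    keys[!is_wt, ] <- parse_variant(raw$variant[!is_wt])
  }
  out <- bind_cols(keys, raw[setdiff(names(raw), "variant")])
  out$wildtype <- is_wt
  if ("level" %in% names(out) && any(out$level < 0, na.rm = TRUE)) {
    abort("steady-state levels must be non-negative")
  }
  if ("half_life_h" %in% names(out) && any(out$half_life_h <= 0, na.rm = TRUE)) {
    abort("half-lives must be positive")
  }
  if ("survival_pct" %in% names(out) &&
      any(out$survival_pct < 0 | out$survival_pct > 100, na.rm = TRUE)) {
    abort("survival_pct must lie in [0, 100]")
  }
  dup <- duplicated(out$variant)
  if (any(dup)) {
    abort(paste0("duplicate variants: ", paste(unique(out$variant[dup]), collapse = ", ")))
  }
  out
}

#' Read a predictor score table
#'
#' Long-format scores from one or more predictors. Columns: `variant`,
#' `predictor`, `score`, `higher_is_damaging` (logical orientation flag,
#' constant within predictor).
#'
#' @param path Path to a CSV file.
#' @return A tibble with parsed variant keys and score columns.
#' @export
read_scores <- function(path) {
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE, comment.char = "#"))
  need <- c("variant", "predictor", "score", "higher_is_damaging")
  if (!all(need %in% names(raw))) {
    abort(paste0("score table must have columns: ", paste(need, collapse = ", ")))
  }
  ori <- raw |>
    distinct(.data$predictor, .data$higher_is_damaging) |>
    count(.data$predictor)
  if (any(ori$n > 1)) {
    abort("orientation flag must be constant within each predictor")
  }
  bind_cols(parse_variant(raw$variant), raw[setdiff(names(raw), "variant")])
}

#' Read an allele-frequency table
#'
#' @param path Path to a CSV file with columns `variant`, `allele_frequency`.
#' @return A tibble with parsed variant keys and `allele_frequency` in [0, 1].
#' @export
read_frequencies <- function(path) {
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE, comment.char = "#"))
  if (!all(c("variant", "allele_frequency") %in% names(raw))) {
    abort("frequency table must have columns 'variant' and 'allele_frequency'")
  }
  if (any(raw$allele_frequency < 0 | raw$allele_frequency > 1, na.rm = TRUE)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  bind_cols(parse_variant(raw$variant), raw[setdiff(names(raw), "variant")])
}

#' The bundled MSH2 variant panel
#'
#' A curated panel of 24 missense variants of human MSH2 (plus the wild-type
#' reference row) with structure-based FoldX ddG predictions (kcal/mol,
#' positive = destabilising), solvent accessibility of the mutated residue,
#' cellular half-life under translation shut-off (hours, with standard
#' deviation), nuclear localisation, MSH6-interaction category, whether the
#' variant has been reported in Lynch-syndrome patients, and temperature
#' sensitivity of its degradation.
#'
#' @param include_wt Keep the wild-type reference row (default `TRUE`).
#' @return A tibble with one row per variant.
#' @examples
#' msh2_variants() |> dplyr::filter(patient_found)
#' @export
msh2_variants <- function(include_wt = TRUE) {
  path <- system.file("extdata", "msh2_variants.csv", package = "cellstab")
  out <- read_phenotypes(path)
  out$ddg <- as.numeric(out$ddg)
  if (!include_wt) out <- filter(out, !.data$wildtype)
  out
}
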
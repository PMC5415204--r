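#' Two-state thermodynamic model constants
#'
#' Bundles the effective wild-type folding free energy with the gas constant
#' and temperature. The folding convention is dG = RT ln([Unf]/[Fold]):
#' negative dG means mostly folded, and a destabilising mutation (ddg > 0)
#' shifts the equilibrium towards the unfolded state.
#'
#' @param dg_wt Effective wild-type folding free energy, kcal/mol (negative
#'   = stable). The default -3.1 is the effective cellular stability
#'   estimated for MSH2 from steady-state abundance data.
#' @param gas_constant Gas constant R in kcal/(mol K).
#' @param temperature Absolute temperature in kelvin; default 310.15 K
#'   (37 C, the culture temperature). Use 302.15 for 29 C experiments.
#' @return An object of class `thermo_model`.
#' @export
thermo_model <- function(dg_wt = -3.1,
                         gas_constant = 1.987e-3,
                         temperature = 310.15) {
  if (temperature <= 0 || gas_constant <= 0) {
    abort("temperature and gas constant must be positive")
  }
  structure(
    list(dg_wt = dg_wt, gas_constant = gas_constant, temperature = temperature),
    class = "thermo_model"
  )
}

#' @export
print.thermo_model <- function(x, ...) {
  cat(sprintf(
    "Two-state folding model: dG_WT = %.3g kcal/mol, T = %.2f K (RT = %.4g kcal/mol)\n",
    x$dg_wt, x$temperature, x$gas_constant * x$temperature
  ))
  invisible(x)
}

#' Equilibrium fraction folded under the two-state model
#'
#' f(ddg) = 1 / (1 + exp((dG_WT + ddg) / RT)). Strictly decreasing in ddg,
#' 0.5 when the mutant's total folding free energy is zero, and saturating
#' smoothly at 0 and 1.
#'
#' @param model A [thermo_model()].
#' @param ddg Stability change(s) in kcal/mol (vectorised).
#' @return Numeric vector of fractions in (0, 1).
#' @examples
#' fraction_folded(thermo_model(dg_wt = -3.1), 0)
#' @export
fraction_folded <- function(model, ddg) {
  stopifnot(inherits(model, "thermo_model"))
  rt <- model$gas_constant * model$temperature
  1 / (1 + exp((model$dg_wt + ddg) / rt))
}

#' Predicted steady-state abundance relative to wild type
#'
#' Under the assumption that the cellular steady-state level is proportional
#' to the fraction folded, the level relative to wild type is
#' `fraction_folded(ddg) / fraction_folded(0)`: exactly 1 at ddg = 0 and
#' monotone decreasing.
#'
#' @inheritParams fraction_folded
#' @return Numeric vector of relative abundances.
#' @export
predicted_level <- function(model, ddg) {
  fraction_folded(model, ddg) / fraction_folded(model, 0)
}

fit_dg_wt_point <- function(ddg, level, gas_constant, temperature, bounds) {
  obj <- function(g) {
    m <- thermo_model(g, gas_constant, temperature)
    sum((level - predicted_level(m, ddg))^2)
  }
  opt <- optimize(obj, interval = bounds, tol = 1e-8)
  opt$minimum
}

resample_indices <- function(n, resampling, fraction) {
  if (resampling == "bootstrap") {
    function() sample.int(n, n, replace = TRUE)
  } else {
    k <- max(3L, round(fraction * n))
    function() sample.int(n, k)
  }
}

new_thermo_fit <- function(kind, estimate, boot, seed, bounds, data, fitted,
                           extra = list()) {
  at_bound <- min(abs(estimate - bounds)) < 1e-4
  structure(
    c(list(
      kind = kind,
      dg_wt = estimate,
      se = if (length(boot)) sd(boot) else NA_real_,
      bootstrap = boot,
      n_bootstrap = length(boot),
      band_50 = quantile(boot, c(0.25, 0.75), names = FALSE),
      band_95 = quantile(boot, c(0.025, 0.975), names = FALSE),
      seed = seed,
      bounds = bounds,
      at_bound = at_bound,
      data = data,
      fitted = fitted,
      residuals = data$observed - fitted
    ), extra),
    class = "thermo_fit"
  )
}

#' Fit the effective wild-type stability from abundance data
#'
#' Estimates dG_WT by ordinary least squares on the linear abundance scale:
#' the observed relative steady-state levels are fit to
#' [predicted_level()] as a function of the variants' ddg values. Uncertainty
#' comes from a nonparametric case-resampling bootstrap (resample variants
#' with replacement at full dataset size, refit; the reported error is the
#' standard deviation of the bootstrap estimates, and 25-75 and 2.5-97.5
#' percentile bands are stored).
#'
#' @param df Tibble with columns `ddg` and `level` (steady-state abundance
#'   relative to wild type). Include a wild-type row (ddg 0, level 1) only
#'   if you want it as a data point; it is never injected silently.
#' @param n_bootstrap Number of bootstrap refits (default 5000).
#' @param seed Integer seed for the bootstrap resampling.
#' @param resampling `"bootstrap"` (default): case resampling with
#'   replacement at full dataset size; `"subsample"`: random subsets
#'   without replacement of `subsample_fraction` of the data.
#' @param subsample_fraction Subset fraction for `resampling =
#'   "subsample"` (default 0.8).
#' @param bounds Search interval for dG_WT in kcal/mol.
#' @param gas_constant,temperature Model constants, see [thermo_model()].
#' @return A `thermo_fit` object; see [tidy.thermo_fit()] and
#'   [glance.thermo_fit()].
#' @export
fit_dg_wt <- function(df, n_bootstrap = 5000, seed = 1L,
                      resampling = c("bootstrap", "subsample"),
                      subsample_fraction = 0.8,
                      bounds = c(-15, 5),
                      gas_constant = 1.987e-3, temperature = 310.15) {
  resampling <- match.arg(resampling)
  if (!all(c("ddg", "level") %in% names(df))) {
    abort("fit_dg_wt needs columns 'ddg' and 'level'")
  }
  df <- filter(df, is.finite(.data$ddg), is.finite(.data$level))
  if (nrow(df) < 3) abort("need at least 3 variants to fit dG_WT")
  if (any(df$level < 0)) abort("levels must be non-negative")
  if (sd(df$level) == 0) abort("all levels identical; dG_WT is not identifiable")

  est <- fit_dg_wt_point(df$ddg, df$level, gas_constant, temperature, bounds)
  set.seed(seed)
  nobs <- nrow(df)
  draw <- resample_indices(nobs, resampling, subsample_fraction)
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    idx <- draw()
    fit_dg_wt_point(df$ddg[idx], df$level[idx], gas_constant, temperature, bounds)
  }, numeric(1))
  model <- thermo_model(est, gas_constant, temperature)
  new_thermo_fit(
    kind = "abundance", estimate = est, boot = boot, seed = seed,
    bounds = bounds,
    data = tibble(ddg = df$ddg, observed = df$level),
    fitted = predicted_level(model, df$ddg),
    extra = list(gas_constant = gas_constant, temperature = temperature)
  )
}

#' Fit the effective wild-type stability from residual-function data
#'
#' Uses cell-survival percentages under a DNA-damaging challenge as a proxy
#' for residual mismatch-repair function. Two anchor variants pin the scale:
#' the folded anchor (typically wild type, fully functional, so the cells
#' die) and the unfolded anchor (a variant destabilised enough to be
#' non-functional, so the cells survive). The model
#' `s(ddg) = s_unf + (s_fold - s_unf) * predicted_level(ddg)`
#' is then fit for dG_WT by least squares, with the same bootstrap scheme
#' as [fit_dg_wt()] (anchor survival values stay fixed at their observed
#' values across resamples).
#'
#' @param df Tibble with columns `variant`, `ddg`, `survival_pct`.
#' @param folded_anchor,unfolded_anchor Variant names (or `"WT"`) whose
#'   observed survivals define the fully folded / unfolded endpoints.
#' @inheritParams fit_dg_wt
#' @return A `thermo_fit` object.
#' @export
fit_survival <- function(df, folded_anchor = "WT", unfolded_anchor,
                         n_bootstrap = 5000, seed = 1L,
                         resampling = c("bootstrap", "subsample"),
                         subsample_fraction = 0.8,
                         bounds = c(-15, 5),
                         gas_constant = 1.987e-3, temperature = 310.15) {
  resampling <- match.arg(resampling)
  need <- c("variant", "ddg", "survival_pct")
  if (!all(need %in% names(df))) {
    abort("fit_survival needs columns 'variant', 'ddg', 'survival_pct'")
  }
  df <- filter(df, is.finite(.data$ddg), is.finite(.data$survival_pct))
  i_f <- match(folded_anchor, df$variant)
  i_u <- match(unfolded_anchor, df$variant)
  if (is.na(i_f) || is.na(i_u)) abort("anchor variant missing from the data")
  s_fold <- df$survival_pct[i_f]
  s_unf <- df$survival_pct[i_u]
  if (s_fold == s_unf) abort("anchors have equal survival; model is degenerate")
  if (nrow(df) < 3) abort("need at least 3 variants to fit dG_WT")

  predict_surv <- function(g, ddg) {
    m <- thermo_model(g, gas_constant, temperature)
    s_unf + (s_fold - s_unf) * predicted_level(m, ddg)
  }
  point <- function(ddg, surv) {
    opt <- optimize(function(g) sum((surv - predict_surv(g, ddg))^2),
      interval = bounds, tol = 1e-8
    )
    opt$minimum
  }
  est <- point(df$ddg, df$survival_pct)
  set.seed(seed)
  nobs <- nrow(df)
  draw <- resample_indices(nobs, resampling, subsample_fraction)
  boot <- vapply(seq_len(n_bootstrap), function(b) {
    idx <- draw()
    point(df$ddg[idx], df$survival_pct[idx])
  }, numeric(1))
  new_thermo_fit(
    kind = "survival", estimate = est, boot = boot, seed = seed,
    bounds = bounds,
    data = tibble(ddg = df$ddg, observed = df$survival_pct),
    fitted = predict_surv(est, df$ddg),
    extra = list(
      gas_constant = gas_constant, temperature = temperature,
      s_folded = s_fold, s_unfolded = s_unf,
      anchors = c(folded = folded_anchor, unfolded = unfolded_anchor)
    )
  )
}

#' The destabilisation sufficient to halve the steady-state level
#'
#' Solves `predicted_level(ddg) = 0.5` for ddg given a fitted dG_WT: the
#' loss of stability at which half the wild-type abundance remains, a
#' practical threshold for degradation by protein quality control. The
#' bootstrap band is propagated by solving the same root for every
#' bootstrap dG_WT estimate.
#'
#' @param fit A `thermo_fit` from [fit_dg_wt()] (or a bare dG_WT number).
#' @param gas_constant,temperature Model constants, used only when `fit` is
#'   a bare number.
#' @return A one-row tibble: `threshold_ddg`, `lo_95`, `hi_95` (bands `NA`
#'   for bare-number input), plus `boundary` flagging the degenerate case
#'   of a wild type that is not mostly folded (dG_WT >= 0), where the root
#'   collapses to ~0.
#' @export
degradation_threshold <- function(fit, gas_constant = 1.987e-3,
                                  temperature = 310.15) {
  root_for <- function(g, R, temp) {
    m <- thermo_model(g, R, temp)
    f <- function(d) predicted_level(m, d) - 0.5
    stats::uniroot(f, lower = -50, upper = 100, tol = 1e-9)$root
  }
  if (inherits(fit, "thermo_fit")) {
    g <- fit$dg_wt
    R <- fit$gas_constant
    temp <- fit$temperature
    boot_roots <- vapply(fit$bootstrap, root_for, numeric(1), R = R, temp = temp)
    lo <- quantile(boot_roots, 0.025, names = FALSE)
    hi <- quantile(boot_roots, 0.975, names = FALSE)
  } else {
    g <- fit
    R <- gas_constant
    temp <- temperature
    lo <- NA_real_
    hi <- NA_real_
  }
  tibble(
    threshold_ddg = root_for(g, R, temp),
    lo_95 = lo, hi_95 = hi,
    boundary = g >= 0
  )
}

#' @rdname fit_dg_wt
#' @param x,object A `thermo_fit`.
#' @param ... Unused.
#' @export
print.thermo_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit: dG_WT = %.2f +/- %.2f kcal/mol (bootstrap sd, n = %d, seed %d)\n",
    x$kind, x$dg_wt, x$se, x$n_bootstrap, x$seed
  ))
  cat(sprintf(
    "  25-75%%: [%.2f, %.2f]   2.5-97.5%%: [%.2f, %.2f]\n",
    x$band_50[1], x$band_50[2], x$band_95[1], x$band_95[2]
  ))
  if (x$at_bound) cat("  warning: estimate at search bound\n")
  invisible(x)
}

#' Tidiers for thermodynamic fits
#'
#' `tidy()` returns the parameter estimate with its bootstrap uncertainty;
#' `glance()` returns one-row fit diagnostics; `augment()` returns the data
#' with fitted values and residuals.
#'
#' @param x,object A `thermo_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.thermo_fit <- function(x, ...) {
  tibble(
    term = "dg_wt",
    estimate = x$dg_wt,
    std.error = x$se,
    conf.low = x$band_95[1],
    conf.high = x$band_95[2],
    q25 = x$band_50[1],
    q75 = x$band_50[2]
  )
}

#' @rdname tidy.thermo_fit
#' @exportS3Method generics::glance
glance.thermo_fit <- function(x, ...) {
  tibble(
    kind = x$kind,
    dg_wt = x$dg_wt,
    std.error = x$se,
    n_obs = nrow(x$data),
    n_bootstrap = x$n_bootstrap,
    seed = x$seed,
    rss = sum(x$residuals^2),
    at_bound = x$at_bound
  )
}

#' @rdname tidy.thermo_fit
#' @exportS3Method generics::augment
augment.thermo_fit <- function(x, ...) {
  tibble(
    ddg = x$data$ddg,
    observed = x$data$observed,
    .fitted = x$fitted,
    .resid = x$residuals
  )
}

#' Plot a thermodynamic fit with its bootstrap band
#'
#' Observed values against ddg, the fitted curve, and the pointwise 25-75
#' percentile band obtained by evaluating the curve at every bootstrap
#' dG_WT estimate.
#'
#' @param object A `thermo_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.thermo_fit <- function(object, ...) {
  grid <- seq(min(object$data$ddg), max(object$data$ddg), length.out = 200)
  curve_for <- function(g) {
    m <- thermo_model(g, object$gas_constant, object$temperature)
    lev <- predicted_level(m, grid)
    if (object$kind == "survival") {
      object$s_unfolded + (object$s_folded - object$s_unfolded) * lev
    } else {
      lev
    }
  }
  boot_curves <- vapply(object$bootstrap, curve_for, numeric(length(grid)))
  band <- tibble(
    ddg = grid,
    fit = curve_for(object$dg_wt),
    lo = apply(boot_curves, 1, quantile, 0.25),
    hi = apply(boot_curves, 1, quantile, 0.75)
  )
  ylab <- if (object$kind == "survival") "survival (%)" else "level relative to WT"
  ggplot(band, aes(x = .data$ddg)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), fill = "grey80") +
    geom_line(aes(y = .data$fit), colour = "red3") +
    geom_point(
      data = tibble(ddg = object$data$ddg, y = object$data$observed),
      aes(y = .data$y)
    ) +
    labs(
      x = expression(Delta * Delta * G ~ "(kcal/mol)"), y = ylab,
      title = sprintf("dG_WT = %.2f +/- %.2f kcal/mol", object$dg_wt, object$se)
    ) +
    theme_minimal()
}
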
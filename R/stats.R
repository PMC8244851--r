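# Bias statistics: normalized T1 errors, group summaries, two-way ANOVA,
# Tukey-Kramer pairwise comparisons, and bias/dispersion propagation to
# clinical T1 ranges.

#' Normalized T1 measurement error
#'
#' Percent deviation of a measured T1 from the NMR reference value:
#' \eqn{100 (T_1 - T_{1,NMR}) / T_{1,NMR}}.
#'
#' @param t1_measured_ms Measured T1 (ms), vectorised.
#' @param t1_nmr_ms Reference T1 (ms), positive.
#' @return Percent error(s).
#' @export
normalized_error <- function(t1_measured_ms, t1_nmr_ms) {
  if (any(t1_nmr_ms <= 0)) stop("reference T1 must be positive")
  100 * (t1_measured_ms - t1_nmr_ms) / t1_nmr_ms
}

#' Build a tidy table of bias records
#'
#' Joins per-sphere fitted T1 values with their reference values and computes
#' the normalized error, tagging each record with its grouping labels.
#'
#' @param fits Tibble with columns `sphere` and `t1_ms` (from [fit_rois()]).
#' @param layout Phantom layout supplying reference T1.
#' @param vendor,modality,system Labels for the record.
#' @return Tibble with `sphere`, `t1_measured_ms`, `t1_nmr_ms`,
#'   `normalized_error_pct`, `vendor`, `field_tesla`, `modality`, `system`.
#' @export
bias_records <- function(fits, layout, vendor, modality, system = vendor) {
  tibble::tibble(
    sphere = fits$sphere,
    t1_measured_ms = fits$t1_ms,
    t1_nmr_ms = layout$reference_t1_ms[fits$sphere],
    vendor = vendor,
    field_tesla = layout$field_tesla,
    modality = modality,
    system = system
  ) |>
    dplyr::mutate(normalized_error_pct =
                    normalized_error(.data$t1_measured_ms, .data$t1_nmr_ms),
                  .after = "t1_nmr_ms")
}

#' Per-group mean normalized error with 95% confidence intervals
#'
#' Student-t confidence intervals about the group mean normalized error, per
#' sphere per group (the quantities plotted as circles and error bars in
#' bias-versus-T1 figures). Singleton groups report the mean with an
#' undefined (NA) interval and are flagged.
#'
#' @param records Bias-record tibble (see [bias_records()]).
#' @param group_by Column name to group by (default "vendor").
#' @param conf_level Confidence level.
#' @return Tibble with per-sphere per-group `mean_error_pct`, `ci_lower`,
#'   `ci_upper`, `n`, `singleton`.
#' @export
group_summary <- function(records, group_by = "vendor", conf_level = 0.95) {
  records |>
    dplyr::group_by(.data$sphere, .data$t1_nmr_ms,
                    dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_error_pct = mean(.data$normalized_error_pct),
      se = stats::sd(.data$normalized_error_pct) / sqrt(.data$n),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      tcrit = ifelse(.data$n > 1,
                     stats::qt(1 - (1 - conf_level) / 2,
                               df = pmax(.data$n - 1, 1)),
                     NA_real_),
      ci_lower = .data$mean_error_pct - .data$tcrit * .data$se,
      ci_upper = .data$mean_error_pct + .data$tcrit * .data$se,
      singleton = .data$n == 1
    ) |>
    dplyr::select(-"tcrit", -"se")
}

#' Two-way ANOVA of normalized errors on vendor and field
#'
#' Fixed-effects two-way ANOVA of the normalized error on vendor, field and
#' their interaction, with Type III (marginal) sums of squares under sum
#' contrasts so that unbalanced designs are handled; switchable to Type II.
#' A significant interaction motivates analysing the two field strengths
#' separately (simple main effects).
#'
#' @param records Bias-record tibble with at least 2 levels of `vendor` and
#'   of `field_tesla`.
#' @param type Sum-of-squares type, "III" (default) or "II".
#' @return List with `interaction_p`, `vendor_p`, `field_p`, and the
#'   underlying `anova_table`.
#' @export
two_way_anova <- function(records, type = c("III", "II")) {
  type <- match.arg(type)
  v <- factor(records$vendor)
  f <- factor(records$field_tesla)
  if (nlevels(v) < 2) stop("vendor must have at least 2 levels")
  if (nlevels(f) < 2) stop("field must have at least 2 levels")
  dat <- data.frame(err = records$normalized_error_pct, vendor = v, field = f)
  fit <- stats::lm(err ~ vendor * field, data = dat,
                   contrasts = list(vendor = "contr.sum",
                                    field = "contr.sum"))
  tab <- car::Anova(fit, type = type)
  p <- tab[["Pr(>F)"]]
  rn <- rownames(tab)
  list(
    interaction_p = p[rn == "vendor:field"],
    vendor_p = p[rn == "vendor"],
    field_p = p[rn == "field"],
    anova_table = tab
  )
}

#' Per-sphere vendor comparisons with Tukey-Kramer adjustment
#'
#' For one field strength and one modality: a one-way ANOVA of normalized
#' error across vendors for each sphere individually, followed by all
#' pairwise vendor comparisons with Tukey-Kramer honestly-significant-
#' difference adjustment (valid for unequal group sizes). Spheres observed
#' for fewer than two vendors are skipped with a warning.
#'
#' @param records Bias-record tibble.
#' @param field_tesla Field strength to restrict to (optional if records are
#'   already restricted).
#' @param modality Modality to restrict to (optional likewise).
#' @param alpha Significance level used for the `significant` flag.
#' @return A `t1_stat_result`: list of tibbles `anova` (per-sphere one-way
#'   ANOVA p) and `pairwise` (per-sphere vendor-pair adjusted p, difference
#'   and confidence bounds).
#' @export
per_sphere_pairwise <- function(records, field_tesla = NULL, modality = NULL,
                                alpha = 0.05) {
  if (!is.null(field_tesla)) {
    records <- dplyr::filter(records, .data$field_tesla == !!field_tesla)
  }
  if (!is.null(modality)) {
    records <- dplyr::filter(records, .data$modality == !!modality)
  }
  if (dplyr::n_distinct(records$vendor) < 2) {
    stop("at least 2 vendors are required")
  }
  spheres <- sort(unique(records$sphere))
  anova_rows <- list()
  pair_rows <- list()
  for (s in spheres) {
    dat <- dplyr::filter(records, .data$sphere == s)
    if (dplyr::n_distinct(dat$vendor) < 2) {
      warning("sphere ", s, " observed for fewer than 2 vendors; skipped")
      next
    }
    dat$vendor <- factor(dat$vendor)
    fit <- stats::aov(normalized_error_pct ~ vendor, data = dat)
    pval <- summary(fit)[[1]][["Pr(>F)"]][1]
    anova_rows[[length(anova_rows) + 1]] <- tibble::tibble(
      sphere = s, t1_nmr_ms = dat$t1_nmr_ms[1], anova_p = pval
    )
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$vendor
    pair_rows[[length(pair_rows) + 1]] <- tibble::tibble(
      sphere = s,
      t1_nmr_ms = dat$t1_nmr_ms[1],
      comparison = rownames(tk),
      difference = tk[, "diff"],
      ci_lower = tk[, "lwr"],
      ci_upper = tk[, "upr"],
      p_adj = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha
    )
  }
  structure(
    list(anova = dplyr::bind_rows(anova_rows),
         pairwise = dplyr::bind_rows(pair_rows),
         alpha = alpha),
    class = "t1_stat_result"
  )
}

#' @export
print.t1_stat_result <- function(x, ...) {
  cat("<t1_stat_result>", nrow(x$anova), "spheres;",
      sum(x$pairwise$significant), "of", nrow(x$pairwise),
      "pairwise comparisons significant at alpha =", x$alpha, "\n")
  invisible(x)
}

#' @export
tidy.t1_stat_result <- function(x, ...) x$pairwise

#' @export
glance.t1_stat_result <- function(x, ...) {
  tibble::tibble(
    n_spheres = nrow(x$anova),
    n_pairwise = nrow(x$pairwise),
    n_significant = sum(x$pairwise$significant),
    alpha = x$alpha
  )
}

#' Propagate measurement bias and dispersion to a tissue T1 range
#'
#' Applies a relative bias and dispersion (both in percent) multiplicatively
#' to a tissue T1 range mean +/- sd, returning the widest measured range
#' consistent with bias +/- dispersion:
#' \deqn{[(1 + (b - d)/100)(\mu - s),\; (1 + (b + d)/100)(\mu + s)].}
#'
#' @param tissue_mean_ms,tissue_sd_ms Tissue T1 mean and spread (ms).
#' @param bias_pct Relative bias in percent (signed).
#' @param dispersion_pct Relative dispersion in percent (nonnegative).
#' @return Named numeric vector `c(lower, upper)` in ms.
#' @export
propagate_bias <- function(tissue_mean_ms, tissue_sd_ms, bias_pct,
                           dispersion_pct) {
  if (tissue_mean_ms <= 0) stop("tissue_mean_ms must be positive")
  if (dispersion_pct < 0) stop("dispersion_pct must be nonnegative")
  c(lower = (1 + (bias_pct - dispersion_pct) / 100) *
      (tissue_mean_ms - tissue_sd_ms),
    upper = (1 + (bias_pct + dispersion_pct) / 100) *
      (tissue_mean_ms + tissue_sd_ms))
}
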
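# Reference-database statistics: subgroup summaries, coefficient of
# variation, Pearson correlation panels, two-way type-II ANOVA per thickness
# coefficient and eye side, and Bonferroni-adjusted significance banding.
# Left and right eyes are never pooled into one model (fellow eyes of one
# animal are not independent); they are analyzed as separate tables.

MEASURE_COLS <- c(paste0("T", 1:9), paste0("A", 1:8), "TUn", "TUt", "AUn", "AUt")

#' Subgroup summary statistics
#'
#' Mean, standard deviation (sample, n-1), minimum and maximum of each measure
#' within each covariate subgroup, optionally with the coefficient of
#' variation. Empty groups are dropped with a warning.
#'
#' @param table measurement table (one row per eye), e.g. from
#'   [measure_cohort()] or a cohort truth table.
#' @param group_by character vector of covariate columns to group by (use
#'   `character(0)` for overall statistics).
#' @param measures measure columns to summarize.
#' @param cv include the CV (percent) per group and measure.
#' @return tidy `data.frame`: grouping columns, `measure`, `n`, `mean`, `std`,
#'   `min`, `max` (and `cv`).
#' @export
summarize_cohort <- function(table, group_by = c("sex", "origin"),
                             measures = intersect(MEASURE_COLS, names(table)),
                             cv = FALSE) {
  if (!nrow(table)) stop("summarize_cohort: empty table")
  long <- do.call(rbind, lapply(measures, function(m) {
    d <- table[c(group_by)]
    d$measure <- m
    d$value <- table[[m]]
    d
  }))
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_by, "measure")))) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     std = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
                     min = min(.data$value),
                     max = max(.data$value), .groups = "drop")
  if (cv) out$cv <- 100 * out$std / out$mean
  out$measure <- factor(out$measure, levels = measures)
  out <- out[order(out$measure), , drop = FALSE]
  as.data.frame(out)
}

#' Coefficient of variation
#'
#' Relative dispersion: the ratio of the sample standard deviation (n-1
#' denominator) to the mean, as a percentage.
#'
#' @param values numeric vector, at least two values, positive mean.
#' @param digits optional rounding of the returned percentage (e.g. 1 for
#'   report output); `NULL` keeps full precision.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(90, 110))  # 14.14214
#' @export
coefficient_of_variation <- function(values, digits = NULL) {
  if (length(values) < 2L) stop("coefficient_of_variation: need n >= 2")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("coefficient_of_variation: mean must be > 0")
  out <- 100 * stats::sd(values) / m
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Covariate frequencies
#'
#' Counts and percentages per level of a covariate, from either a factor-like
#' vector or a named count vector (percentages rounded to 2 decimals, the
#' reporting convention for cohort composition).
#'
#' @param x character/factor vector of per-eye covariate values, or a named
#'   numeric vector of counts.
#' @return `data.frame` with `level`, `count`, `pct`.
#' @examples
#' covariate_frequencies(c(female = 147, male = 227))  # 39.30 / 60.70 %
#' @export
covariate_frequencies <- function(x) {
  counts <- if (is.numeric(x) && !is.null(names(x))) x else table(x)
  total <- sum(counts)
  data.frame(level = names(counts), count = as.numeric(counts),
             pct = round(100 * as.numeric(counts) / total, 2),
             stringsAsFactors = FALSE)
}

#' Pearson correlation panel
#'
#' Pairwise Pearson correlation coefficients between two sets of measure
#' columns (e.g. the T1-T9 x T1-T9 triangle, or the thickness-vs-area and
#' T5-vs-umbo panels). Zero-variance variables yield `NA` entries with a
#' warning rather than a silent zero.
#'
#' @param table measurement table.
#' @param vars_a,vars_b column name vectors; `vars_b` defaults to `vars_a`.
#' @return numeric matrix `length(vars_a) x length(vars_b)` of correlations.
#' @export
pearson_matrix <- function(table, vars_a, vars_b = vars_a) {
  if (nrow(table) < 3L) stop("pearson_matrix: need at least 3 rows")
  a <- as.matrix(table[vars_a])
  b <- as.matrix(table[vars_b])
  degen <- c(vars_a[apply(a, 2, stats::sd) == 0],
             vars_b[apply(b, 2, stats::sd) == 0])
  if (length(degen))
    warning("pearson_matrix: zero variance in ", paste(unique(degen), collapse = ", "),
            "; entries set to NA")
  suppressWarnings(stats::cor(a, b))
}

#' Two-way type-II ANOVA for one thickness coefficient
#'
#' Fits the additive model `response ~ sex + origin` (no interaction) on one
#' eye side's table and computes type-II sums of squares: each factor's SS is
#' the residual-SS reduction from adding that factor to the model already
#' containing the other, making the result invariant to factor order in
#' unbalanced designs. Rows with unknown origin are excluded before fitting.
#'
#' @param table measurement table for one eye side.
#' @param response measure column to analyze (e.g. `"T5"`).
#' @param factors character length 2: the two categorical covariates.
#' @param unknown_levels factor values treated as missing and dropped (with a
#'   message) before fitting.
#' @return `data.frame` of class `anova_result`: rows per factor plus
#'   `Residuals`, columns `term`, `sumsq`, `df`, `statistic`, `p.value`.
#' @export
anova_two_way_type2 <- function(table, response, factors = c("sex", "origin"),
                                unknown_levels = "unknown") {
  keep <- !Reduce(`|`, lapply(factors, function(f) table[[f]] %in% unknown_levels))
  if (any(!keep))
    message("anova_two_way_type2: excluding ", sum(!keep),
            " rows with unknown factor levels")
  d <- table[keep, , drop = FALSE]
  d[factors] <- lapply(d[factors], factor)
  if (any(is.na(d[[response]])))
    stop("anova_two_way_type2: missing values in ", response)
  for (f in factors)
    if (nlevels(d[[f]]) < 2L)
      stop("anova_two_way_type2: factor ", f, " has fewer than 2 observed levels")
  fml <- stats::reformulate(factors, response)
  fit <- stats::lm(fml, data = d)
  if (fit$rank < ncol(stats::model.matrix(fit)))
    stop("anova_two_way_type2: rank-deficient design (empty factor cell)")
  a2 <- car::Anova(fit, type = 2)
  out <- data.frame(term = rownames(a2), sumsq = a2[["Sum Sq"]],
                    df = a2[["Df"]], statistic = a2[["F value"]],
                    p.value = a2[["Pr(>F)"]], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "response") <- response
  attr(out, "n") <- nrow(d)
  class(out) <- c("anova_result", class(out))
  out
}

#' Bonferroni significance banding
#'
#' Classifies raw p-values against Bonferroni-corrected thresholds obtained by
#' dividing the 0.01 and 0.05 significance levels by the number of tests `m`
#' (nine per eye side for the T1-T9 battery): `p < 0.01/m` is significant,
#' `0.01/m <= p < 0.05/m` weakly significant, otherwise not significant.
#'
#' @param p raw p-value(s) in (0, 1].
#' @param m number of tests.
#' @return `data.frame` with `p`, `m`, `band` (factor) and the two thresholds
#'   as attributes `threshold_significant`, `threshold_weak`.
#' @examples
#' bonferroni_band(0.00126, m = 9)  # weakly significant
#' @export
bonferroni_band <- function(p, m = 9L) {
  if (m < 1L) stop("bonferroni_band: m must be >= 1")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("bonferroni_band: p-values must lie in (0, 1]")
  thr_sig <- 0.01 / m
  thr_weak <- 0.05 / m
  band <- ifelse(p < thr_sig, "significant",
                 ifelse(p < thr_weak, "weakly significant", "not significant"))
  out <- data.frame(p = p, m = as.integer(m),
                    band = factor(band, levels = c("not significant",
                                                   "weakly significant",
                                                   "significant")))
  attr(out, "threshold_significant") <- thr_sig
  attr(out, "threshold_weak") <- thr_weak
  out
}

#' Full ANOVA battery over the nine thickness coefficients
#'
#' Runs [anova_two_way_type2()] for each of T1-T9 on each eye side separately
#' and bands the factor p-values with the Bonferroni correction for nine
#' tests per side.
#'
#' @param table measurement table with both sides.
#' @param responses measure columns to test.
#' @param m number of tests per eye side used for the Bonferroni correction.
#' @return `data.frame` with `response`, `side`, `term`, `sumsq`, `df`,
#'   `statistic`, `p.value`, `band`.
#' @export
anova_battery <- function(table, responses = paste0("T", 1:9), m = 9L) {
  out <- list()
  for (sd_ in unique(table$side)) {
    d <- table[table$side == sd_, , drop = FALSE]
    for (resp in responses) {
      a <- suppressMessages(anova_two_way_type2(d, resp))
      a <- a[a$term != "Residuals", , drop = FALSE]
      a$response <- resp
      a$side <- sd_
      out[[length(out) + 1L]] <- a
    }
  }
  res <- do.call(rbind, out)
  res$band <- bonferroni_band(res$p.value, m)$band
  res[c("response", "side", "term", "sumsq", "df", "statistic", "p.value", "band")]
}
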
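# Report layer: Tukey boxplot descriptors, subgroup boxplot figures, and the
# batched CSV/JSON outputs of the statistics stage.

#' Tukey boxplot descriptors for one group
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Whiskers extend to the last datum smaller than
#' `Q3 + 1.5 * IQR` and the first datum larger than `Q1 - 1.5 * IQR`; data
#' beyond the whiskers are outliers.
#'
#' @param values numeric vector.
#' @return list with `q1`, `median`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @examples
#' boxplot_spec(1:100)  # q1 = 25.75, q3 = 75.25, no outliers
#' @export
boxplot_spec <- function(values) {
  if (!length(values)) stop("boxplot_spec: empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  hi <- values[values < q[3] + 1.5 * iqr]
  lo <- values[values > q[1] - 1.5 * iqr]
  whisker_high <- if (length(hi)) max(hi) else q[3]
  whisker_low <- if (length(lo)) min(lo) else q[1]
  list(q1 = q[1], median = q[2], q3 = q[3], whisker_low = whisker_low,
       whisker_high = whisker_high,
       outliers = values[values > whisker_high | values < whisker_low],
       n = length(values))
}

#' Subgroup boxplot for one measure and eye side
#'
#' Distribution of one measure across the origin-by-sex subgroups (Mauritius
#' male/female, Asian male/female, ...), one box per subgroup.
#'
#' @param table measurement table.
#' @param measure measure column to plot.
#' @param side eye side to plot (`NULL` for all rows).
#' @return a `ggplot` object.
#' @export
plot_measure_boxplot <- function(table, measure, side = NULL) {
  d <- if (is.null(side)) table else table[table$side == side, , drop = FALSE]
  if (!nrow(d)) stop("plot_measure_boxplot: no rows for side ", side)
  d$group <- interaction(d$origin, d$sex, sep = " ", drop = TRUE)
  unit <- if (grepl("^A", measure)) "µm²" else "µm"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data[[measure]])) +
    ggplot2::geom_boxplot(coef = 1.5, fill = "lightblue") +
    ggplot2::labs(x = NULL, y = sprintf("%s (%s)", measure, unit),
                  title = if (is.null(side)) measure
                          else sprintf("%s, %s", measure, side)) +
    ggplot2::theme_minimal()
}

#' Write the full statistics report for a measurement table
#'
#' Produces, under `out_dir`: per-side subgroup summary tables
#' (`summary_OD.csv`, `summary_OS.csv`), the correlation panels
#' (`correlations.csv`: the T1-T9 triangle plus the thickness-vs-area and
#' T5-vs-umbo rows), the ANOVA battery with Bonferroni banding (`anova.csv`),
#' boxplot figures per measure and side, and a JSON sidecar of run
#' parameters. Summary means are rounded to integers and correlations to two
#' decimals in the CSVs; full precision stays in the returned objects.
#'
#' @param table measurement table (both eye sides).
#' @param out_dir output directory.
#' @param params list of run parameters recorded in the sidecar.
#' @param figures write boxplot PNGs (can be slow for many measures).
#' @param figure_measures measures to plot when `figures = TRUE`.
#' @return invisibly, a list with the unrounded `summaries`, `correlations`,
#'   `anova` objects.
#' @export
run_cohort_stats <- function(table, out_dir, params = list(), figures = TRUE,
                             figure_measures = c("T5", "A4", "A5")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list()
  for (sd_ in sort(unique(table$side))) {
    d <- table[table$side == sd_, , drop = FALSE]
    s <- summarize_cohort(d, group_by = c("sex", "origin"))
    summaries[[sd_]] <- s
    s_out <- s
    s_out[c("mean", "std", "min", "max")] <-
      lapply(s_out[c("mean", "std", "min", "max")], round)
    utils::write.csv(s_out, file.path(out_dir, paste0("summary_", sd_, ".csv")),
                     row.names = FALSE)
  }

  tcols <- paste0("T", 1:9)
  tt <- pearson_matrix(table, tcols)
  panel_b <- data.frame(
    var1 = c(tcols[-5], rep("T5", 4)),
    var2 = c(paste0("A", 1:8), "TUn", "TUt", "AUn", "AUt"),
    stringsAsFactors = FALSE)
  panel_b$r <- vapply(seq_len(nrow(panel_b)), function(i) {
    pearson_matrix(table, panel_b$var1[i], panel_b$var2[i])[1, 1]
  }, numeric(1))
  tri <- which(upper.tri(tt), arr.ind = TRUE)
  corr <- rbind(
    data.frame(var1 = tcols[tri[, 1]], var2 = tcols[tri[, 2]],
               r = tt[tri], stringsAsFactors = FALSE),
    panel_b)
  corr_out <- corr
  corr_out$r <- round(corr_out$r, 2)
  utils::write.csv(corr_out, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)

  anova <- anova_battery(table)
  utils::write.csv(anova, file.path(out_dir, "anova.csv"), row.names = FALSE)

  if (figures) {
    for (m in figure_measures) for (sd_ in sort(unique(table$side))) {
      p <- plot_measure_boxplot(table, m, sd_)
      ggplot2::ggsave(file.path(out_dir, sprintf("boxplot_%s_%s.png", m, sd_)),
                      p, width = 5, height = 4, dpi = 120)
    }
  }
  jsonlite::write_json(c(params, list(n_rows = nrow(table),
                                      sides = sort(unique(table$side)))),
                       file.path(out_dir, "params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(summaries = summaries, correlations = corr, anova = anova))
}
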
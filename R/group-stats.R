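# Exact small-sample Mann-Whitney U comparisons of CI vs CN per ROI and
# metric, and the report tables built from them.

#' Exact Mann-Whitney U test
#'
#' `U` is the smaller of the two one-sided statistics (`U_x` counts pairs with
#' `x_i > y_j`, half a point per tie; `U_x + U_y = n m`). For untied samples
#' with `n + m <= 16` the two-sided p-value is exact — the probability, over
#' all `choose(n+m, n)` equally likely group assignments, of a U at least as
#' extreme in either direction — computed from the exact null distribution.
#' Larger or tied samples use the mid-rank normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric vectors (both nonempty).
#' @return list with `u` (min-U), `u_x` (first-sample one-sided U), `p`
#'   (two-sided), `exact` (logical), `n_x`, `n_y`.
#' @export
mann_whitney_exact <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (anyNA(c(x, y))) stop("samples must not contain NA")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))                      # mid-ranks
  u_x <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  u_y <- n * m - u_x
  u <- min(u_x, u_y)
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && n + m <= 16) {
    p <- min(1, 2 * stats::pwilcox(u, n, m))
    exact <- TRUE
  } else {
    N <- n + m
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (u - n * m / 2 + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    exact <- FALSE
  }
  list(u = u, u_x = u_x, p = p, exact = exact, n_x = n, n_y = m)
}

#' Compare CI vs CN per ROI for one metric
#'
#' The per-subject ROI means are the test's observations: one Mann-Whitney
#' comparison per ROI present in both groups. The direction column is the
#' sign of `mean(CI) - mean(CN)`.
#'
#' @param table ROI table (see [roi_mean_map()]) with columns `subject_id`,
#'   `group` (values `"CI"`/`"CN"`), `roi_name`, `metric_name`, `value`.
#' @param metric metric name to compare.
#' @param u_convention `"min"` (report `min(U_x, U_y)`) or `"group1"` (report
#'   the CI-group one-sided U, which for a 4-vs-4 design with complete
#'   separation reads 0 or 16 depending on direction).
#' @return data.frame with one row per ROI: `metric_name`, `roi_name`,
#'   `u_statistic`, `p_value`, `ci_mean`, `cn_mean`, `n_ci`, `n_cn`,
#'   `direction`, `exact`.
#' @export
compare_groups <- function(table, metric, u_convention = c("min", "group1")) {
  u_convention <- match.arg(u_convention)
  tab <- table[table$metric_name == metric, , drop = FALSE]
  rows <- lapply(sort(unique(tab$roi_name)), function(roi) {
    sub <- tab[tab$roi_name == roi, ]
    ci <- sub$value[sub$group == "CI"]
    cn <- sub$value[sub$group == "CN"]
    if (!length(ci) || !length(cn)) {
      warning(sprintf("ROI '%s' lacks one group for metric '%s'; skipped",
                      roi, metric))
      return(NULL)
    }
    mw <- mann_whitney_exact(ci, cn)
    data.frame(
      metric_name = metric, roi_name = roi,
      u_statistic = if (u_convention == "min") mw$u else mw$u_x,
      p_value = mw$p, ci_mean = mean(ci), cn_mean = mean(cn),
      n_ci = mw$n_x, n_cn = mw$n_y,
      direction = sign(mean(ci) - mean(cn)), exact = mw$exact,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Assemble a comparison report
#'
#' @param comparisons data.frame of [compare_groups()] rows (possibly several
#'   metrics bound together).
#' @param alpha significance threshold for the filtered view (default 0.05).
#' @param correction `"none"` (the default; appropriate for exploratory pilot
#'   analyses) or `"benjamini-hochberg"`.
#' @return object of class `comparison_report`: list with `rows` (sorted by
#'   metric then ROI, with `p_adjusted` and `flagged`), `alpha`, `correction`.
#' @export
comparison_report <- function(comparisons, alpha = 0.05,
                              correction = c("none", "benjamini-hochberg")) {
  correction <- match.arg(correction)
  rows <- comparisons[order(comparisons$metric_name, comparisons$roi_name), ,
                      drop = FALSE]
  rows$p_adjusted <- if (correction == "benjamini-hochberg") {
    stats::p.adjust(rows$p_value, method = "BH")
  } else rows$p_value
  rows$flagged <- rows$p_adjusted < alpha
  structure(list(rows = rows, alpha = alpha, correction = correction),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d comparisons, %d flagged at alpha = %g (%s)\n",
              nrow(x$rows), sum(x$rows$flagged), x$alpha, x$correction))
  invisible(x)
}

#' Write a comparison report
#'
#' Emits `<prefix>_full.tsv` (all rows, p rounded to 3 decimals),
#' `<prefix>_significant.tsv` (flagged rows only) and `<prefix>.json` (full
#' precision). Empty reports produce valid header-only files.
#'
#' @param report a `comparison_report`.
#' @param prefix output path prefix.
#' @return invisibly, the written paths.
#' @export
write_report <- function(report, prefix) {
  rows <- report$rows
  fmt <- rows
  if (nrow(fmt)) {
    fmt$p_value <- round(fmt$p_value, 3)
    fmt$p_adjusted <- round(fmt$p_adjusted, 3)
  }
  full <- paste0(prefix, "_full.tsv")
  sig <- paste0(prefix, "_significant.tsv")
  js <- paste0(prefix, ".json")
  utils::write.table(fmt, full, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fmt[fmt$flagged, , drop = FALSE], sig, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(alpha = report$alpha, correction = report$correction, rows = rows),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(c(full, sig, js))
}

#' Join two report families on ROIs significant in both
#'
#' Reproduces the "common regions" view: ROIs flagged under both analysis
#' families (e.g. an MTR_asym offset and the matching Lorentzian pool
#' amplitude) appear once, with both sets of statistics side by side.
#'
#' @param report_a,report_b `comparison_report` objects.
#' @param metric_map named character vector mapping metrics of `report_a` to
#'   the corresponding metrics of `report_b` (e.g.
#'   `c(mtrasym_2 = "lorentzian_amine")`).
#' @return data.frame of joined rows (possibly empty).
#' @export
common_region_join <- function(report_a, report_b, metric_map) {
  a <- report_a$rows[report_a$rows$flagged, , drop = FALSE]
  b <- report_b$rows[report_b$rows$flagged, , drop = FALSE]
  out <- list()
  for (ma in names(metric_map)) {
    mb <- metric_map[[ma]]
    aa <- a[a$metric_name == ma, , drop = FALSE]
    bb <- b[b$metric_name == mb, , drop = FALSE]
    shared <- intersect(aa$roi_name, bb$roi_name)
    for (roi in shared) {
      ra <- aa[aa$roi_name == roi, ]
      rb <- bb[bb$roi_name == roi, ]
      out[[length(out) + 1L]] <- data.frame(
        roi_name = roi, metric_a = ma, u_a = ra$u_statistic, p_a = ra$p_value,
        ci_mean_a = ra$ci_mean, cn_mean_a = ra$cn_mean,
        metric_b = mb, u_b = rb$u_statistic, p_b = rb$p_value,
        ci_mean_b = rb$ci_mean, cn_mean_b = rb$cn_mean,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(roi_name = character(0), metric_a = character(0),
                      u_a = numeric(0), p_a = numeric(0),
                      ci_mean_a = numeric(0), cn_mean_a = numeric(0),
                      metric_b = character(0), u_b = numeric(0),
                      p_b = numeric(0), ci_mean_b = numeric(0),
                      cn_mean_b = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
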
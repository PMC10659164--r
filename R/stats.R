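#' Chi-square test of independence on a contingency table
#'
#' Pearson chi-square statistic \eqn{\sum (O - E)^2 / E} with expected
#' counts from the row/column margins, no continuity correction; degrees of
#' freedom \eqn{(r-1)(c-1)}; p-value from the chi-square upper tail. Used to
#' test whether error counts are distributed independently of institution.
#'
#' @param table Numeric matrix (or object coercible to one) with at least 2
#'   rows and 2 columns, non-negative integer cells, and no all-zero row or
#'   column margin.
#' @return A list with `statistic`, `dof`, `p_value`.
#' @export
chi_square_independence <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) {
    dq_abort("contingency table needs at least 2 rows and 2 columns",
             "dq_stats_error")
  }
  if (any(m < 0)) dq_abort("negative cell in contingency table",
                           "dq_stats_error")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    dq_abort("degenerate margins: all-zero row or column", "dq_stats_error")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), dof = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] that refuses silently undefined
#' results: both vectors must have at least 3 complete pairs and neither may
#' be constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The correlation coefficient, in \eqn{[-1, 1]}.
#' @export
pearson_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    dq_abort("x and y must have equal length", "dq_stats_error")
  }
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) dq_abort("need at least 3 complete pairs",
                            "dq_stats_error")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    dq_abort("correlation undefined for a constant vector",
             "dq_undefined_correlation")
  }
  stats::cor(x[ok], y[ok], method = method)
}

#' Correlate error counts with institutional factors
#'
#' For every (factor, target) pair -- targets being the total error count
#' and the four per-dimension counts -- computes the correlation across
#' institutions, dropping institutions with a missing factor value pairwise.
#' Pairs whose correlation is undefined (constant values, or fewer than 3
#' complete pairs) are reported with `r = NA` and a reason instead of a
#' silent zero.
#'
#' @param sev_table A [severity_table()] tibble (supplies `total`).
#' @param dim_table A [dimension_table()] tibble.
#' @param factors A tibble/data.frame with `institution_id` plus one numeric
#'   column per factor (see [read_factors()]).
#' @param method Correlation method, as in [pearson_correlation()].
#' @return A tibble with columns `factor`, `target`, `r`, `n`, `note`.
#' @export
correlate_factors <- function(sev_table, dim_table, factors,
                              method = "pearson") {
  merged <- merge(merge(sev_table[c("institution_id", "total")], dim_table,
                        by = "institution_id"),
                  factors, by = "institution_id")
  targets <- c("total", "completeness", "validity", "accuracy", "uniqueness")
  fnames <- setdiff(names(factors), "institution_id")
  rows <- list()
  for (f in fnames) {
    for (t in targets) {
      x <- as.numeric(merged[[f]])
      y <- as.numeric(merged[[t]])
      ok <- stats::complete.cases(x, y)
      r <- tryCatch(pearson_correlation(x[ok], y[ok], method = method),
                    dq_error = function(e) structure(NA_real_,
                      note = conditionMessage(e)))
      note <- attr(r, "note") %||% NA_character_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        factor = f, target = t, r = as.numeric(r), n = sum(ok), note = note)
    }
  }
  do.call(rbind, rows)
}

#' Read an institutional-factors table
#'
#' CSV or YAML with one row/entry per institution: `institution_id` plus
#' named numeric factor columns (e.g. biospecimen_count, hospital_level,
#' dedicated_staff, non_specialist_staff, it_infrastructure_level,
#' data_manager_count, years_in_network, bed_count, collection_sites).
#'
#' @param path File path (`.csv`, `.yml` or `.yaml`).
#' @return A tibble.
#' @export
read_factors <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    entries <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(entries, function(e)
      as.data.frame(e, stringsAsFactors = FALSE)))
    tibble::as_tibble(df)
  } else {
    tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  }
}

#' Scatter plot of a factor against an error count
#'
#' Base-graphics scatter of one institutional factor versus one error-count
#' target, with the fitted least-squares line and the correlation in the
#' title.
#'
#' @inheritParams correlate_factors
#' @param factor_name Column of `factors` to plot.
#' @param target One of `"total"`, `"completeness"`, `"validity"`,
#'   `"accuracy"`, `"uniqueness"`.
#' @return The correlation coefficient, invisibly.
#' @export
plot_factor_scatter <- function(sev_table, dim_table, factors, factor_name,
                                target = "total") {
  merged <- merge(merge(sev_table[c("institution_id", "total")], dim_table,
                        by = "institution_id"),
                  factors, by = "institution_id")
  x <- as.numeric(merged[[factor_name]])
  y <- as.numeric(merged[[target]])
  r <- pearson_correlation(x, y)
  graphics::plot(x, y, xlab = factor_name, ylab = paste(target, "error count"),
                 main = sprintf("%s vs %s (r = %.2f)", factor_name, target, r),
                 pch = 19)
  graphics::abline(stats::lm(y ~ x), lty = 2)
  invisible(r)
}
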
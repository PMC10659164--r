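#' Per-institution severity table
#'
#' One row per institution with its total violation count split into errors
#' (severity E) and warnings (severity W). Institutions that produced no
#' violations keep a row of zeros.
#'
#' @param vs A `dq_violations` object from [evaluate_catalog()].
#' @return A tibble with columns `institution_id`, `total`, `errors`,
#'   `warnings`; `errors + warnings == total` in every row.
#' @export
severity_table <- function(vs) {
  v <- vs$violations
  inst <- factor(v$institution_id, levels = vs$institutions)
  tot <- table(inst)
  err <- table(inst[v$severity == "E"])
  tibble::tibble(institution_id = vs$institutions,
                 total = as.integer(tot),
                 errors = as.integer(err),
                 warnings = as.integer(tot) - as.integer(err))
}

#' Per-institution dimension table
#'
#' One row per institution with violation counts split by quality dimension.
#' For any violation set, each row sums to the corresponding
#' [severity_table()] total (the two tables are two partitions of the same
#' violations).
#'
#' @param vs A `dq_violations` object.
#' @return A tibble with columns `institution_id`, `completeness`,
#'   `validity`, `accuracy`, `uniqueness`.
#' @export
dimension_table <- function(vs) {
  v <- vs$violations
  inst <- factor(v$institution_id, levels = vs$institutions)
  dims <- c("completeness", "validity", "accuracy", "uniqueness")
  out <- tibble::tibble(institution_id = vs$institutions)
  for (d in dims) {
    out[[d]] <- as.integer(table(inst[v$dimension == d]))
  }
  out
}

#' Overall error rate
#'
#' The headline quality metric: total violations divided by the number of
#' verification cases, i.e. records times rules, rendered as a percentage
#' with two decimals (round half up).
#'
#' @param total_violations Total violation count.
#' @param n_records Number of evaluated records (basic-table record count).
#' @param n_rules Number of rules in the applied catalog.
#' @return A list with `fraction` (numeric) and `percent` (string such as
#'   `"0.74%"`).
#' @export
error_rate <- function(total_violations, n_records, n_rules) {
  if (n_records <= 0 || n_rules <= 0) {
    dq_abort("error_rate requires positive record and rule counts",
             "dq_domain_error")
  }
  frac <- total_violations / (n_records * n_rules)
  pct <- floor(frac * 100 * 100 + 0.5 + 1e-9) / 100
  list(fraction = frac, percent = sprintf("%.2f%%", pct))
}

#' Profile an institution by its completeness/validity balance
#'
#' Compares omission errors (completeness) with mapping errors (validity).
#' A site whose validity errors exceed `ratio_threshold` times its
#' completeness errors is labelled `"mapping-dominant"` (few omissions, many
#' incorrect mappings); the reverse pattern is `"omission-dominant"` (correct
#' mappings, many missing values); anything else -- including a site with no
#' errors at all -- is `"balanced"`.
#'
#' @param completeness_count,validity_count Non-negative error counts.
#' @param ratio_threshold Dominance ratio; the default 2 means one class of
#'   error must at least double the other.
#' @return A list with `completeness_count`, `validity_count`, `label` and
#'   `ratio_threshold`.
#' @export
profile_institution <- function(completeness_count, validity_count,
                                ratio_threshold = 2) {
  if (completeness_count < 0 || validity_count < 0 || ratio_threshold <= 0) {
    dq_abort("counts must be non-negative and threshold positive",
             "dq_domain_error")
  }
  label <- if (validity_count > ratio_threshold * completeness_count) {
    "mapping-dominant"
  } else if (completeness_count > ratio_threshold * validity_count) {
    "omission-dominant"
  } else "balanced"
  list(completeness_count = completeness_count,
       validity_count = validity_count, label = label,
       ratio_threshold = ratio_threshold)
}

#' Profile every institution of a dimension table
#'
#' @param dim_table A [dimension_table()] tibble.
#' @param ratio_threshold Passed to [profile_institution()].
#' @return A tibble with `institution_id`, `completeness`, `validity`,
#'   `label`, `ratio_threshold`.
#' @export
institution_profiles <- function(dim_table, ratio_threshold = 2) {
  labels <- mapply(function(cc, vc) {
    profile_institution(cc, vc, ratio_threshold)$label
  }, dim_table$completeness, dim_table$validity)
  tibble::tibble(institution_id = dim_table$institution_id,
                 completeness = dim_table$completeness,
                 validity = dim_table$validity,
                 label = unname(labels),
                 ratio_threshold = ratio_threshold)
}

#' Write the full report to a directory
#'
#' Writes `severity_table.csv`, `dimension_table.csv`, `profiles.csv` and
#' `summary.json` (total violations, error rate, rule and record counts).
#'
#' @param vs A `dq_violations` object.
#' @param n_records Total basic-table record count across institutions.
#' @param out_dir Output directory (created if needed).
#' @param ratio_threshold Passed to [institution_profiles()].
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(vs, n_records, out_dir, ratio_threshold = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- severity_table(vs)
  dt <- dimension_table(vs)
  utils::write.csv(st, file.path(out_dir, "severity_table.csv"),
                   row.names = FALSE)
  utils::write.csv(dt, file.path(out_dir, "dimension_table.csv"),
                   row.names = FALSE)
  utils::write.csv(institution_profiles(dt, ratio_threshold),
                   file.path(out_dir, "profiles.csv"), row.names = FALSE)
  er <- error_rate(sum(st$total), n_records, length(vs$rule_ids))
  summ <- sprintf(
    '{"total_violations": %d, "n_records": %d, "n_rules": %d, "error_rate_fraction": %.10f, "error_rate_percent": "%s"}',
    sum(st$total), as.integer(n_records), length(vs$rule_ids), er$fraction,
    er$percent)
  writeLines(summ, file.path(out_dir, "summary.json"))
  invisible(out_dir)
}

#' Published per-institution error counts of the 2020 KBN assessment
#'
#' The per-institution severity and dimension counts reported by the 2020
#' multicenter quality assessment of the Korea Biobank Network (16 unit
#' biobanks, labels A-P, 55,316 donors, 104 final rules): total, error and
#' warning counts, and the same violations partitioned by quality dimension.
#' Useful as a reference input for the reporting and profiling layer and for
#' checking the table identities the published counts satisfy (row totals,
#' severity and dimension partitions, grand total 42,829).
#'
#' @return A tibble with one row per institution: `institution_id`, `total`,
#'   `errors`, `warnings`, `completeness`, `validity`, `accuracy`,
#'   `uniqueness`.
#' @export
kbn_reported_counts <- function() {
  tibble::tibble(
    institution_id = LETTERS[1:16],
    total    = c(1466L, 440L, 9102L, 2256L, 4714L, 13093L, 238L, 2045L,
                 3190L, 242L, 38L, 1461L, 0L, 2540L, 1890L, 114L),
    errors   = c(745L, 22L, 233L, 147L, 4712L, 8320L, 6L, 775L, 3165L, 236L,
                 35L, 209L, 0L, 59L, 1757L, 30L),
    warnings = c(721L, 418L, 8869L, 2109L, 2L, 4773L, 232L, 1270L, 25L, 6L,
                 3L, 1252L, 0L, 2481L, 133L, 84L),
    completeness = c(721L, 0L, 2220L, 62L, 1L, 2772L, 232L, 0L, 23L, 6L,
                     20L, 21L, 0L, 2479L, 124L, 81L),
    validity = c(745L, 21L, 387L, 148L, 4669L, 9957L, 6L, 230L, 3163L, 235L,
                 16L, 210L, 0L, 61L, 1741L, 15L),
    accuracy = c(0L, 419L, 6495L, 2046L, 31L, 71L, 0L, 1285L, 4L, 1L, 2L,
                 1208L, 0L, 0L, 24L, 18L),
    uniqueness = c(0L, 0L, 0L, 0L, 13L, 293L, 0L, 530L, 0L, 0L, 0L, 22L, 0L,
                   0L, 1L, 0L)
  )
}

#' @rdname kbn_reported_counts
#' @export
kbn_reported_scale <- function() {
  list(n_records = 55316L, n_rules = 104L)
}
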
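#' Evaluate one validation rule against a dataset
#'
#' Returns one violation per failing record. Evaluation follows a strict
#' precedence so that a single defective cell is counted under exactly one
#' dimension:
#'
#' * null values are the completeness dimension's business: format, range,
#'   parse, comparison and ordering predicates skip null cells entirely;
#' * unparseable values are the format sub-dimension's business: range
#'   checks, cross-field comparisons and date-order checks skip values that
#'   do not parse (as number or date);
#' * implausible values are the range sub-dimension's business: cross-field
#'   comparisons additionally skip values outside the schema's plausible
#'   range, so e.g. a weight recorded in grams is flagged once, by the
#'   weight range rule, not a second time by the height-versus-weight
#'   comparison;
#' * conditional rules fire only when the antecedent is non-null and
#'   satisfied; a conditional-presence rule fires on a null consequent, a
#'   conditional-valid rule on a consequent value outside its allowed set
#'   (a null consequent violates it unless the rule allows null);
#' * records failing the rule's applicability condition (e.g. a history flag
#'   of 9 = not investigated) are skipped, not passed.
#'
#' Supported predicate kinds: `not_null`, `range_check`,
#' `cross_field_compare`, `date_format`, `code_membership`, `numeric_parse`,
#' `date_order`, `conditional_presence`, `conditional_valid`, `unique_key`.
#'
#' @param rule A [rule_spec()] object.
#' @param dataset A `dq_dataset`.
#' @param schema Schema the dataset conforms to (used for record keys and
#'   plausible ranges); defaults to [default_schema()].
#' @return A tibble of violations (possibly empty) with columns `rule_id`,
#'   `institution_id`, `table`, `record_key`, `field`, `observed_value`,
#'   `dimension`, `severity`.
#' @export
evaluate_rule <- function(rule, dataset, schema = default_schema()) {
  df <- dataset$tables[[rule$target_table]]
  if (is.null(df)) {
    dq_abort(sprintf("%s: dataset has no table '%s'", rule$rule_id,
                     rule$target_table), "dq_engine_error")
  }
  n <- nrow(df)
  empty <- violation_tbl()
  if (n == 0L) return(empty)

  applicable <- rep(TRUE, n)
  if (!is.null(rule$applicability)) {
    a <- rule$applicability
    v <- df[[a$field]]
    applicable <- switch(a$comparator,
      eq = !is_null_value(v) & v == a$value,
      ne = !is_null_value(v) & v != a$value,
      dq_abort(sprintf("%s: unknown applicability comparator '%s'",
                       rule$rule_id, a$comparator), "dq_engine_error"))
  }

  p <- rule$predicate
  fld <- rule$target_fields[1]
  observed_field <- fld
  bad <- switch(p$kind,
    not_null = is_null_value(df[[fld]]),
    numeric_parse = {
      v <- df[[fld]]
      !is_null_value(v) & !parses_numeric(v)
    },
    range_check = {
      v <- df[[fld]]
      x <- as_num(v)
      ok_val <- !is_null_value(v) & parses_numeric(v)
      viol <- rep(FALSE, n)
      if (!is.null(p$min)) viol <- viol | (ok_val & x < p$min)
      if (!is.null(p$max)) viol <- viol | (ok_val & x > p$max)
      viol
    },
    cross_field_compare = {
      lv <- df[[p$left]]; rv <- df[[p$right]]
      lx <- as_num(lv); rx <- as_num(rv)
      lr <- schema_field(schema, rule$target_table, p$left)$plausible_range
      rr <- schema_field(schema, rule$target_table, p$right)$plausible_range
      ok <- !is_null_value(lv) & !is_null_value(rv) &
        parses_numeric(lv) & parses_numeric(rv)
      if (!is.null(lr)) ok <- ok & !is.na(lx) & lx >= lr[1] & lx <= lr[2]
      if (!is.null(rr)) ok <- ok & !is.na(rx) & rx >= rr[1] & rx <= rr[2]
      cmpfun <- switch(p$comparator, ">" = `>`, ">=" = `>=`, "<" = `<`,
                       "<=" = `<=`,
                       dq_abort(sprintf("%s: unknown comparator '%s'",
                                        rule$rule_id, p$comparator),
                                "dq_engine_error"))
      observed_field <- p$left
      ok & !cmpfun(lx, rx)
    },
    date_format = {
      v <- df[[fld]]
      !is_null_value(v) &
        !parses_date8(v, p$min_year %||% 1900, p$max_year %||% 2100)
    },
    code_membership = {
      v <- df[[fld]]
      present <- !is_null_value(v)
      if (!is.null(p$pattern)) {
        present & !grepl(p$pattern, v)
      } else {
        present & !v %in% p$codes
      }
    },
    date_order = {
      ev <- df[[p$earlier]]
      e <- date8_value(ev)
      if (!is.null(p[["later"]])) {
        lv <- df[[p[["later"]]]]
        l <- date8_value(lv)
      } else {
        l <- rep(date8_value(p$later_constant), n)
      }
      observed_field <- p$earlier
      !is.na(e) & !is.na(l) & e > l
    },
    conditional_presence = {
      ant <- antecedent_holds(df, p$antecedent)
      observed_field <- p$consequent_field
      ant & is_null_value(df[[p$consequent_field]])
    },
    conditional_valid = {
      ant <- antecedent_holds(df, p$antecedent)
      cq <- p$consequent
      v <- df[[cq$field]]
      isnull <- is_null_value(v)
      in_set <- !isnull & v %in% cq$values
      ok <- if (identical(cq$op, "not_in")) !isnull & !in_set else in_set
      if (isTRUE(cq$allow_null)) ok <- ok | isnull
      observed_field <- cq$field
      ant & !ok
    },
    unique_key = {
      v <- df[[fld]]
      !is_null_value(v) & duplicated(v, incomparables = NA)
    },
    dq_abort(sprintf("%s: unsupported predicate kind '%s'", rule$rule_id,
                     p$kind), "dq_engine_error"))

  bad <- bad & applicable
  idx <- which(bad)
  if (!length(idx)) return(empty)

  keyf <- schema[[rule$target_table]]$key_fields
  key <- if (length(keyf)) df[[keyf[1]]][idx] else rep(NA_character_, length(idx))
  key <- ifelse(is.na(key) | key == "", paste0("row:", idx), key)
  obs <- df[[observed_field]][idx]

  tibble::tibble(rule_id = rule$rule_id,
                 institution_id = dataset$institution_id,
                 table = rule$target_table,
                 record_key = key,
                 field = observed_field,
                 observed_value = as.character(obs),
                 dimension = rule$dimension,
                 severity = rule$severity)
}

antecedent_holds <- function(df, ant) {
  v <- df[[ant$field]]
  present <- !is_null_value(v)
  switch(ant$op,
    eq = present & v == ant$value,
    ne = present & v != ant$value,
    "in" = present & v %in% ant$value,
    not_in = present & !v %in% ant$value,
    dq_abort(sprintf("unknown antecedent op '%s'", ant$op),
             "dq_engine_error"))
}

violation_tbl <- function() {
  tibble::tibble(rule_id = character(), institution_id = character(),
                 table = character(), record_key = character(),
                 field = character(), observed_value = character(),
                 dimension = character(), severity = character())
}

#' Duplicate-key check
#'
#' Within each group of records sharing a non-null key, every record after
#' the first counts as one violation (a group of k identical keys yields
#' k - 1 violations); null keys never form groups.
#'
#' @param keys Character vector of key values (`NA`/`""` = null).
#' @return Integer indices of the duplicate records.
#' @export
check_unique <- function(keys) {
  which(!is_null_value(keys) & duplicated(keys, incomparables = NA))
}

#' Evaluate a catalog over one or more institutions
#'
#' Union of [evaluate_rule()] over all rules and datasets. Violations are
#' sorted by (institution, rule, record key) for reproducible output.
#'
#' @param catalog A `dq_catalog`.
#' @param datasets A single `dq_dataset` or a list of them (all sharing
#'   `schema`).
#' @param schema The common schema; defaults to [default_schema()].
#' @return A `dq_violations` object: the violation tibble plus consistent
#'   per-rule and per-institution count views (see [per_rule_counts()] and
#'   [per_institution_counts()]).
#' @export
evaluate_catalog <- function(catalog, datasets, schema = default_schema()) {
  if (inherits(datasets, "dq_dataset")) datasets <- list(datasets)
  parts <- list()
  for (ds in datasets) {
    for (r in catalog) {
      v <- tryCatch(evaluate_rule(r, ds, schema), dq_engine_error = function(e) {
        dq_abort(sprintf("while evaluating %s on institution %s: %s",
                         r$rule_id, ds$institution_id, conditionMessage(e)),
                 "dq_engine_error")
      })
      if (nrow(v)) parts[[length(parts) + 1L]] <- v
    }
  }
  viol <- if (length(parts)) do.call(rbind, parts) else violation_tbl()
  viol <- viol[order(viol$institution_id, viol$rule_id, viol$record_key), ]
  structure(list(
    violations = tibble::as_tibble(viol),
    institutions = vapply(datasets, function(d) d$institution_id,
                          character(1)),
    rule_ids = names(catalog),
    severities = vapply(catalog, function(r) r$severity, character(1)),
    dimensions = vapply(catalog, function(r) r$dimension, character(1))),
    class = "dq_violations")
}

#' @export
print.dq_violations <- function(x, ...) {
  cat(sprintf("<dq_violations> %d violations, %d institutions, %d rules\n",
              nrow(x$violations), length(x$institutions), length(x$rule_ids)))
  invisible(x)
}

#' Count views over a violation set
#'
#' `per_rule_counts()` and `per_institution_counts()` tabulate the same
#' violation list two ways; both include zero rows for rules/institutions
#' that produced no violations, and both sum to `nrow(x$violations)`.
#'
#' @param x A `dq_violations` object.
#' @return A tibble of counts.
#' @export
per_rule_counts <- function(x) {
  tab <- table(factor(x$violations$rule_id, levels = x$rule_ids))
  tibble::tibble(rule_id = names(tab), n = as.integer(tab))
}

#' @rdname per_rule_counts
#' @export
per_institution_counts <- function(x) {
  tab <- table(factor(x$violations$institution_id, levels = x$institutions))
  tibble::tibble(institution_id = names(tab), n = as.integer(tab))
}

#' Write violations to CSV
#'
#' @param x A `dq_violations` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_violations <- function(x, path) {
  utils::write.csv(x$violations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a rule as an SQL query
#'
#' Emits a `SELECT` returning exactly the records [evaluate_rule()] flags
#' (modulo the engine's plausibility precedence for cross-field
#' comparisons, which SQL reproduces via explicit range guards). Intended
#' for sites that run their quality checks inside a relational database.
#'
#' @param rule A [rule_spec()] object.
#' @param schema Schema, for plausible-range guards.
#' @return A length-1 character SQL string.
#' @export
export_rule_sql <- function(rule, schema = default_schema()) {
  p <- rule$predicate
  tb <- rule$target_table
  fld <- rule$target_fields[1]
  notnull <- function(f) sprintf("%s IS NOT NULL", f)
  where <- switch(p$kind,
    not_null = sprintf("%s IS NULL", fld),
    numeric_parse = sprintf("%s AND NOT (%s GLOB '[0-9]*')", notnull(fld), fld),
    range_check = {
      parts <- character()
      if (!is.null(p$min)) parts <- c(parts, sprintf("CAST(%s AS REAL) < %s",
                                                     fld, p$min))
      if (!is.null(p$max)) parts <- c(parts, sprintf("CAST(%s AS REAL) > %s",
                                                     fld, p$max))
      sprintf("%s AND (%s)", notnull(fld), paste(parts, collapse = " OR "))
    },
    cross_field_compare = {
      guard <- function(f) {
        rng <- schema_field(schema, tb, f)$plausible_range
        if (is.null(rng)) notnull(f) else
          sprintf("%s AND CAST(%s AS REAL) BETWEEN %s AND %s", notnull(f), f,
                  rng[1], rng[2])
      }
      sprintf("%s AND %s AND NOT (CAST(%s AS REAL) %s CAST(%s AS REAL))",
              guard(p$left), guard(p$right), p$left, p$comparator, p$right)
    },
    date_format = sprintf(
      "%s AND (LENGTH(%s) <> 8 OR DATE(SUBSTR(%s,1,4)||'-'||SUBSTR(%s,5,2)||'-'||SUBSTR(%s,7,2)) IS NULL)",
      notnull(fld), fld, fld, fld, fld),
    code_membership = {
      if (!is.null(p$pattern)) {
        sprintf("%s AND %s NOT REGEXP '%s'", notnull(fld), fld, p$pattern)
      } else {
        sprintf("%s AND %s NOT IN (%s)", notnull(fld), fld,
                paste(sprintf("'%s'", p$codes), collapse = ", "))
      }
    },
    date_order = {
      later <- p[["later"]] %||% sprintf("'%s'", p$later_constant)
      sprintf("%s AND %s AND %s > %s", notnull(p$earlier),
              if (!is.null(p[["later"]])) notnull(p[["later"]]) else "1=1",
              p$earlier, later)
    },
    conditional_presence = sprintf("%s AND %s IS NULL",
      antecedent_sql(p$antecedent), p$consequent_field),
    conditional_valid = {
      cq <- p$consequent
      set <- paste(sprintf("'%s'", cq$values), collapse = ", ")
      test <- if (identical(cq$op, "not_in"))
        sprintf("(%s IS NOT NULL AND %s NOT IN (%s))", cq$field, cq$field, set)
      else sprintf("%s IN (%s)", cq$field, set)
      if (isTRUE(cq$allow_null)) test <- sprintf("(%s OR %s IS NULL)", test,
                                                 cq$field)
      sprintf("%s AND NOT %s", antecedent_sql(p$antecedent), test)
    },
    unique_key = NULL,
    dq_abort(sprintf("%s: cannot export predicate kind '%s' to SQL",
                     rule$rule_id, p$kind), "dq_export_error"))
  if (p$kind == "unique_key") {
    return(sprintf(
      "SELECT %s FROM %s WHERE %s GROUP BY %s HAVING COUNT(*) > 1;",
      fld, tb, notnull(fld), fld))
  }
  if (!is.null(rule$applicability)) {
    a <- rule$applicability
    app <- sprintf("%s AND %s %s '%s'", notnull(a$field), a$field,
                   if (a$comparator == "eq") "=" else "<>", a$value)
    where <- sprintf("(%s) AND (%s)", app, where)
  }
  sprintf("SELECT * FROM %s WHERE %s;", tb, where)
}

antecedent_sql <- function(ant) {
  set <- paste(sprintf("'%s'", ant$value), collapse = ", ")
  op <- switch(ant$op, eq = "=", ne = "<>", "in" = "IN", not_in = "NOT IN")
  if (op %in% c("IN", "NOT IN")) {
    sprintf("%s IS NOT NULL AND %s %s (%s)", ant$field, ant$field, op, set)
  } else {
    sprintf("%s IS NOT NULL AND %s %s '%s'", ant$field, ant$field, op,
            ant$value)
  }
}
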
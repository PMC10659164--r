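#' Validation rule specification
#'
#' One declarative data-quality rule. Dimensions follow the four-dimension
#' quality model: completeness (missing values), validity (range and
#' format/code conformance), accuracy (temporal ordering and cross-field
#' business logic) and uniqueness (duplicate keys). Severity `"E"` (error:
#' must be corrected before loading) or `"W"` (warning: may be loaded).
#'
#' @param rule_id Unique identifier.
#' @param dimension `"completeness"`, `"validity"`, `"accuracy"` or
#'   `"uniqueness"`.
#' @param sub_dimension `"none"`, `"range"`, `"format"`, `"timeline"` or
#'   `"business_rule"`; constrained by the dimension.
#' @param severity `"E"` or `"W"`.
#' @param target_table,target_fields Where the rule applies.
#' @param predicate A predicate descriptor: `list(kind = ..., ...)`; see
#'   [evaluate_rule()] for the supported kinds.
#' @param applicability Optional `list(field, comparator, value)` restricting
#'   which records are evaluated (comparator `"eq"` or `"ne"`); records
#'   failing it are skipped, not passed.
#' @param provenance `"paper-exampled"` for rules quoted in the published
#'   quality model, `"reconstructed"` for rules filled in over the default
#'   schema.
#' @return An object of class `dq_rule`.
#' @export
rule_spec <- function(rule_id, dimension, sub_dimension, severity,
                      target_table, target_fields, predicate,
                      applicability = NULL, provenance = "reconstructed") {
  dims <- c("completeness", "validity", "accuracy", "uniqueness")
  if (!dimension %in% dims) {
    dq_abort(sprintf("unknown dimension '%s' (%s)", dimension, rule_id),
             "dq_rule_error")
  }
  ok_sub <- switch(dimension,
    completeness = "none", uniqueness = "none",
    validity = c("range", "format"),
    accuracy = c("timeline", "business_rule"))
  if (!sub_dimension %in% ok_sub) {
    dq_abort(sprintf("sub_dimension '%s' invalid for dimension '%s' (%s)",
                     sub_dimension, dimension, rule_id), "dq_rule_error")
  }
  if (!severity %in% c("E", "W")) {
    dq_abort(sprintf("severity must be E or W (%s)", rule_id), "dq_rule_error")
  }
  structure(list(rule_id = rule_id, dimension = dimension,
                 sub_dimension = sub_dimension, severity = severity,
                 target_table = target_table,
                 target_fields = as.character(target_fields),
                 predicate = predicate, applicability = applicability,
                 provenance = provenance),
            class = "dq_rule")
}

new_catalog <- function(rules) {
  ids <- vapply(rules, function(r) r$rule_id, character(1))
  if (anyDuplicated(ids)) {
    dq_abort(sprintf("duplicate rule ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "dq_rule_error")
  }
  structure(stats::setNames(rules, ids), class = "dq_catalog")
}

#' @export
print.dq_catalog <- function(x, ...) {
  cat(sprintf("<dq_catalog> %d rules\n", length(x)))
  print(catalog_summary(x))
  invisible(x)
}

# Fields whose completeness is checked with warning (not error) severity in
# the pre-review catalog: the self-reported lifestyle questionnaire items.
LIFESTYLE_ITEMS <- c("DR_A", "DR_B", "DR_C", "DR_D", "SM_A", "SM_B", "SM_C",
                     "EX_A")

# ICD-10-like pattern for primary diagnosis codes: letter + 2 digits +
# optional .n or .nn. Malformations seen in practice ("?C21.49", "N80.0-1")
# fail it.
DIAG_CODE_PATTERN <- "^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$"

#' Build the pre-review validation-rule catalog
#'
#' Constructs the full 128-rule catalog over [default_schema()] as developed
#' before expert review: one not-null completeness rule per field (errors,
#' except the lifestyle questionnaire items which are warnings), range and
#' cross-field plausibility rules on the anthropometric/blood-pressure
#' measurements, format rules (date format, code membership, numeric parse)
#' for every non-key coded, date and numeric field, two timeline rules on the
#' birth and receipt dates, 23 cross-field business rules on the disease
#' history and lifestyle items, and one duplicate-key uniqueness rule on the
#' donor identifier. Rules directly quoted in the published quality model
#' carry `provenance = "paper-exampled"`; the remainder are
#' `"reconstructed"`.
#'
#' @param schema Schema to build over; defaults to [default_schema()]. The
#'   exact published marginal counts are only guaranteed for the default.
#' @param evaluation_date Cutoff `YYYYMMDD` used by the future-date timeline
#'   rule and the date-format year cap (data collection closed in 2020).
#' @return A `dq_catalog` of 128 `dq_rule` objects.
#' @export
build_prereview_catalog <- function(schema = default_schema(),
                                    evaluation_date = "20201231") {
  eval_year <- as.integer(substr(evaluation_date, 1, 4))
  rules <- list()
  add <- function(r) rules[[length(rules) + 1L]] <<- r

  exampled_complete <- c("KBN_Donor", "DR_A", "DR_B")

  ## Completeness: one not-null rule per field (54).
  for (tab in schema) {
    for (f in tab$fields) {
      sev <- if (tab$name == "lifestyle" && f$name %in% LIFESTYLE_ITEMS)
        "W" else "E"
      prov <- if ((tab$name == "basic_info" && f$name == "KBN_Donor") ||
                  (tab$name == "lifestyle" && f$name %in% c("DR_A", "DR_B")))
        "paper-exampled" else "reconstructed"
      add(rule_spec(sprintf("CMP-%s-%s", tab$name, f$name),
                    "completeness", "none", sev, tab$name, f$name,
                    list(kind = "not_null"), provenance = prov))
    }
  }

  ## Validity / range: plausible ranges on the four measurements (E) and two
  ## cross-field plausibility comparisons (W).
  for (f in c("height", "weight", "SBP", "DBP")) {
    rng <- schema$measurements$fields[[f]]$plausible_range
    add(rule_spec(sprintf("VLD-RNG-measurements-%s", f),
                  "validity", "range", "E", "measurements", f,
                  list(kind = "range_check", min = rng[1], max = rng[2]),
                  provenance = "paper-exampled"))
  }
  add(rule_spec("VLD-RNG-measurements-height_gt_weight",
                "validity", "range", "W", "measurements",
                c("height", "weight"),
                list(kind = "cross_field_compare", left = "height",
                     comparator = ">", right = "weight"),
                provenance = "paper-exampled"))
  add(rule_spec("VLD-RNG-measurements-sbp_gt_dbp",
                "validity", "range", "W", "measurements", c("SBP", "DBP"),
                list(kind = "cross_field_compare", left = "SBP",
                     comparator = ">", right = "DBP")))

  ## Validity / format (42): dates, code sets, numeric parses.
  for (spec in list(c("basic_info", "birthdate"),
                    c("basic_info", "receipt_date"),
                    c("measurements", "measure_date"))) {
    prov <- if (spec[2] == "birthdate") "paper-exampled" else "reconstructed"
    add(rule_spec(sprintf("VLD-FMT-%s-%s", spec[1], spec[2]),
                  "validity", "format", "E", spec[1], spec[2],
                  list(kind = "date_format", min_year = 1900,
                       max_year = eval_year), provenance = prov))
  }
  add(rule_spec("VLD-FMT-basic_info-diagnosis_code",
                "validity", "format", "E", "basic_info", "diagnosis_code",
                list(kind = "code_membership", pattern = DIAG_CODE_PATTERN),
                provenance = "paper-exampled"))
  for (tab in schema) {
    for (f in tab$fields) {
      if (f$name == "diagnosis_code") next
      if (length(f$allowed_codes)) {
        prov <- if (f$name == "sex") "paper-exampled" else "reconstructed"
        add(rule_spec(sprintf("VLD-FMT-%s-%s", tab$name, f$name),
                      "validity", "format", "E", tab$name, f$name,
                      list(kind = "code_membership", codes = f$allowed_codes),
                      provenance = prov))
      } else if (f$value_class == "numeric") {
        prov <- if (f$name == "total_protein") "paper-exampled" else
          "reconstructed"
        add(rule_spec(sprintf("VLD-FMT-%s-%s", tab$name, f$name),
                      "validity", "format", "E", tab$name, f$name,
                      list(kind = "numeric_parse"), provenance = prov))
      }
    }
  }

  ## Accuracy / timeline (2): birthdate before receipt, and no future
  ## birthdate relative to the evaluation cutoff.
  add(rule_spec("ACC-TL-basic_info-birth_before_receipt",
                "accuracy", "timeline", "E", "basic_info",
                c("birthdate", "receipt_date"),
                list(kind = "date_order", earlier = "birthdate",
                     later = "receipt_date"), provenance = "paper-exampled"))
  add(rule_spec("ACC-TL-basic_info-birth_not_future",
                "accuracy", "timeline", "E", "basic_info", "birthdate",
                list(kind = "date_order", earlier = "birthdate",
                     later_constant = evaluation_date),
                provenance = "paper-exampled"))

  ## Accuracy / business rules (23 = 10 E + 13 W). Conditional-presence
  ## rules require a consequent value when the antecedent holds;
  ## conditional-valid rules constrain the consequent's value. The
  ## applicability condition skips records flagged 9 = not investigated.
  not9 <- function(field) list(field = field, comparator = "ne", value = "9")
  br <- function(id, sev, table, fields, pred, app = NULL, prov =
                   "reconstructed") {
    add(rule_spec(paste0("ACC-BR-", id), "accuracy", "business_rule", sev,
                  table, fields, pred, applicability = app, provenance = prov))
  }
  cp <- function(a_field, a_value, c_field) {
    list(kind = "conditional_presence",
         antecedent = list(field = a_field, op = "eq", value = a_value),
         consequent_field = c_field)
  }
  cv <- function(a_field, a_op, a_value, c_field, c_op, c_values,
                 allow_null = FALSE) {
    list(kind = "conditional_valid",
         antecedent = list(field = a_field, op = a_op, value = a_value),
         consequent = list(field = c_field, op = c_op, values = c_values,
                           allow_null = allow_null))
  }
  br("01-cancer_type_present", "E", "disease_history", c("DHCa", "DHCa1"),
     cp("DHCa", "1", "DHCa1"), app = not9("DHCa"), prov = "paper-exampled")
  br("02-cancer_type_implies_history", "E", "disease_history",
     c("DHCa1", "DHCa"),
     cv("DHCa1", "not_in", c("0"), "DHCa", "in", "1"))
  br("03-second_cancer_implies_first", "E", "disease_history",
     c("DHCa2", "DHCa1"),
     cv("DHCa2", "not_in", c("0"), "DHCa1", "not_in", "0"))
  br("04-drink_status_implies_history", "E", "lifestyle", c("DR_B", "DR_A"),
     cv("DR_B", "not_in", c("0"), "DR_A", "in", "1"))
  br("05-smoke_status_implies_history", "E", "lifestyle", c("SM_B", "SM_A"),
     cv("SM_B", "not_in", c("0"), "SM_A", "in", "1"))
  br("06-drinker_has_status", "E", "lifestyle", c("DR_A", "DR_B"),
     cp("DR_A", "1", "DR_B"), app = not9("DR_A"))
  br("07-smoker_has_status", "E", "lifestyle", c("SM_A", "SM_B"),
     cp("SM_A", "1", "SM_B"), app = not9("SM_A"))
  br("08-other_disease_named", "E", "disease_history",
     c("DHEtc", "DHEtc_name"), cp("DHEtc", "1", "DHEtc_name"),
     app = not9("DHEtc"))
  br("09-family_cancer_detailed", "E", "disease_history",
     c("FHCa", "FHCa_other"), cp("FHCa", "1", "FHCa_other"),
     app = not9("FHCa"))
  br("10-diabetic_medication_present", "E", "disease_history",
     c("DHDm", "DHDm_medication"), cp("DHDm", "1", "DHDm_medication"),
     app = not9("DHDm"))
  br("11-other_cancer_named", "W", "disease_history",
     c("DHCa1", "DHCa_other"), cp("DHCa1", "C99", "DHCa_other"),
     app = list(field = "DHCa", comparator = "eq", value = "1"),
     prov = "paper-exampled")
  br("12-drinker_has_amount", "W", "lifestyle", c("DR_A", "DR_C"),
     cp("DR_A", "1", "DR_C"), app = not9("DR_A"))
  br("13-drinker_has_years", "W", "lifestyle", c("DR_A", "DR_D"),
     cp("DR_A", "1", "DR_D"), app = not9("DR_A"))
  br("14-smoker_has_packyears", "W", "lifestyle", c("SM_A", "SM_C"),
     cp("SM_A", "1", "SM_C"), app = not9("SM_A"))
  br("15-hypertensive_medication_present", "W", "disease_history",
     c("DHHtn", "DHHtn_medication"), cp("DHHtn", "1", "DHHtn_medication"),
     app = not9("DHHtn"))
  br("16-cancer_second_type_recorded", "W", "disease_history",
     c("DHCa", "DHCa2"), cp("DHCa", "1", "DHCa2"), app = not9("DHCa"))
  br("17-nondrinker_no_status", "W", "lifestyle", c("DR_A", "DR_B"),
     cv("DR_A", "eq", "0", "DR_B", "in", "0", allow_null = TRUE))
  br("18-nonsmoker_no_status", "W", "lifestyle", c("SM_A", "SM_B"),
     cv("SM_A", "eq", "0", "SM_B", "in", "0", allow_null = TRUE))
  br("19-no_cancer_no_type", "W", "disease_history", c("DHCa", "DHCa1"),
     cv("DHCa", "eq", "0", "DHCa1", "in", "0", allow_null = TRUE))
  br("20-no_cancer_no_second_type", "W", "disease_history",
     c("DHCa", "DHCa2"),
     cv("DHCa", "eq", "0", "DHCa2", "in", "0", allow_null = TRUE))
  br("21-no_other_disease_no_name", "W", "disease_history",
     c("DHEtc", "DHEtc_name"),
     cv("DHEtc", "eq", "0", "DHEtc_name", "in", "-", allow_null = TRUE))
  br("22-no_family_cancer_no_detail", "W", "disease_history",
     c("FHCa", "FHCa_other"),
     cv("FHCa", "eq", "0", "FHCa_other", "in", "-", allow_null = TRUE))
  br("23-nondiabetic_no_medication", "W", "disease_history",
     c("DHDm", "DHDm_medication"),
     cv("DHDm", "eq", "0", "DHDm_medication", "in", "-", allow_null = TRUE))

  ## Uniqueness (1): duplicate donor identifiers in the basic table.
  add(rule_spec("UNQ-basic_info-KBN_Donor", "uniqueness", "none", "W",
                "basic_info", "KBN_Donor", list(kind = "unique_key"),
                provenance = "paper-exampled"))

  new_catalog(rules)
}

#' Expert-review decisions
#'
#' A review decision either drops a rule or reassigns its severity.
#'
#' @param rule_id Rule to act on.
#' @param action `"keep"`, `"drop"` or `"set_severity"`.
#' @param new_severity Required (E/W) when `action = "set_severity"`.
#' @return A `dq_review_decision`.
#' @export
review_decision <- function(rule_id, action, new_severity = NULL) {
  if (!action %in% c("keep", "drop", "set_severity")) {
    dq_abort(sprintf("unknown review action '%s'", action), "dq_review_error")
  }
  if (action == "set_severity" && !identical(new_severity %in% c("E", "W"),
                                             TRUE)) {
    dq_abort("set_severity requires new_severity E or W", "dq_review_error")
  }
  if (action != "set_severity" && !is.null(new_severity)) {
    dq_abort("new_severity only allowed with action = set_severity",
             "dq_review_error")
  }
  structure(list(rule_id = rule_id, action = action,
                 new_severity = new_severity), class = "dq_review_decision")
}

#' Default expert-review decision list
#'
#' The shipped decision list reproducing the published expert review: 24
#' rules dropped (conditional questionnaire and history items whose
#' completeness or null-consistency could not be enforced given "not
#' investigated" responses), 32 completeness rules and 5 laboratory format
#' rules relaxed from error to warning, and the duplicate-donor uniqueness
#' rule raised from warning to error. Applying it to the pre-review catalog
#' yields the final 104-rule model.
#'
#' @param path YAML file of decisions; defaults to the copy shipped with the
#'   package.
#' @return List of [review_decision()] objects.
#' @export
default_review_decisions <- function(path = system.file(
  "extdata", "review_decisions.yaml", package = "biobankDQ")) {
  read_review_decisions(path)
}

#' @rdname default_review_decisions
#' @export
read_review_decisions <- function(path) {
  if (!file.exists(path)) {
    dq_abort(sprintf("review-decision file not found: %s", path),
             "dq_review_error")
  }
  lapply(yaml::read_yaml(path), function(d) {
    review_decision(d$rule_id, d$action, d$new_severity)
  })
}

#' @rdname default_review_decisions
#' @param decisions List of [review_decision()] objects to serialize.
#' @export
write_review_decisions <- function(decisions, path) {
  yaml::write_yaml(lapply(decisions, function(d) {
    x <- list(rule_id = d$rule_id, action = d$action)
    if (!is.null(d$new_severity)) x$new_severity <- d$new_severity
    x
  }), path)
  invisible(path)
}

#' Apply expert-review decisions to a catalog
#'
#' Dropped rules are removed, severity reassignments applied; catalog order
#' is otherwise preserved. Applying the same decision list twice is a no-op
#' beyond the first application.
#'
#' @param catalog A `dq_catalog`.
#' @param decisions List of [review_decision()] objects; defaults to the
#'   shipped list.
#' @return The reviewed `dq_catalog`.
#' @export
apply_expert_review <- function(catalog, decisions = default_review_decisions()) {
  ids <- names(catalog)
  for (d in decisions) {
    if (!d$rule_id %in% ids) {
      dq_abort(sprintf("review decision references unknown rule '%s'",
                       d$rule_id), "dq_review_error")
    }
  }
  drop <- vapply(decisions, function(d) if (d$action == "drop") d$rule_id
                 else NA_character_, character(1))
  kept <- catalog[!ids %in% drop]
  for (d in decisions) {
    if (d$action == "set_severity" && d$rule_id %in% names(kept)) {
      kept[[d$rule_id]]$severity <- d$new_severity
    }
  }
  new_catalog(unname(kept))
}

#' Final reviewed catalog
#'
#' Convenience wrapper: [build_prereview_catalog()] followed by
#' [apply_expert_review()] with the shipped decision list; 104 rules.
#'
#' @inheritParams build_prereview_catalog
#' @return A `dq_catalog` of 104 rules.
#' @export
build_final_catalog <- function(schema = default_schema(),
                                evaluation_date = "20201231") {
  apply_expert_review(build_prereview_catalog(schema, evaluation_date))
}

#' Summarise a catalog by dimension, sub-dimension and severity
#'
#' @param catalog A `dq_catalog`.
#' @return A tibble with columns `dimension`, `sub_dimension`, `severity`,
#'   `n`; `sum(n)` always equals `length(catalog)`.
#' @export
catalog_summary <- function(catalog) {
  if (!length(catalog)) {
    return(tibble::tibble(dimension = character(), sub_dimension = character(),
                          severity = character(), n = integer()))
  }
  df <- data.frame(
    dimension = vapply(catalog, function(r) r$dimension, character(1)),
    sub_dimension = vapply(catalog, function(r) r$sub_dimension, character(1)),
    severity = vapply(catalog, function(r) r$severity, character(1)),
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          df[c("dimension", "sub_dimension", "severity")],
                          FUN = sum)
  dim_order <- c("completeness", "validity", "accuracy", "uniqueness")
  agg <- agg[order(match(agg$dimension, dim_order), agg$sub_dimension,
                   agg$severity), ]
  tibble::as_tibble(agg)
}

#' Validate every rule of a catalog against a schema
#'
#' Checks that each rule's target table and fields exist and that predicate
#' parameters are complete for their kind.
#'
#' @param catalog A `dq_catalog`.
#' @param schema A `dq_schema`.
#' @return `TRUE` invisibly; aborts with a rule-error otherwise.
#' @export
validate_catalog <- function(catalog, schema = default_schema()) {
  for (r in catalog) {
    tab <- schema[[r$target_table]]
    if (is.null(tab)) {
      dq_abort(sprintf("%s targets unknown table '%s'", r$rule_id,
                       r$target_table), "dq_rule_error")
    }
    bad <- setdiff(r$target_fields, names(tab$fields))
    if (length(bad)) {
      dq_abort(sprintf("%s targets unknown field(s) %s", r$rule_id,
                       paste(bad, collapse = ", ")), "dq_rule_error")
    }
    p <- r$predicate
    need <- switch(p$kind,
      not_null = TRUE, numeric_parse = TRUE, unique_key = TRUE,
      range_check = !is.null(p$min) || !is.null(p$max),
      cross_field_compare = !is.null(p$left) && !is.null(p$right) &&
        !is.null(p$comparator),
      date_format = TRUE,
      date_order = !is.null(p$earlier) &&
        (!is.null(p[["later"]]) || !is.null(p$later_constant)),
      code_membership = length(p$codes %||% character()) > 0 ||
        !is.null(p$pattern),
      conditional_presence = !is.null(p$antecedent) &&
        !is.null(p$consequent_field),
      conditional_valid = !is.null(p$antecedent) && !is.null(p$consequent),
      NULL)
    if (is.null(need) || !isTRUE(need)) {
      dq_abort(sprintf("%s has incomplete or unknown predicate '%s'",
                       r$rule_id, p$kind %||% "?"), "dq_rule_error")
    }
  }
  invisible(TRUE)
}

#' Read / write a rule catalog as YAML
#'
#' One document entry per rule, mirroring the [rule_spec()] fields.
#'
#' @param catalog A `dq_catalog`.
#' @param path File path.
#' @return `write_catalog`: `path` invisibly; `read_catalog`: a `dq_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  yaml::write_yaml(lapply(unname(catalog), function(r) {
    x <- list(rule_id = r$rule_id, dimension = r$dimension,
              sub_dimension = r$sub_dimension, severity = r$severity,
              target_table = r$target_table,
              target_fields = as.list(r$target_fields),
              predicate = r$predicate, provenance = r$provenance)
    if (!is.null(r$applicability)) x$applicability <- r$applicability
    x
  }), path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  new_catalog(lapply(yaml::read_yaml(path), function(x) {
    rule_spec(x$rule_id, x$dimension, x$sub_dimension, x$severity,
              x$target_table, unlist(x$target_fields), x$predicate,
              applicability = x$applicability, provenance = x$provenance)
  }))
}
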
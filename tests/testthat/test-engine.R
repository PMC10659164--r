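# Independent per-record oracle: scalar re-implementation of the predicate
# semantics (null precedence, parse/plausibility precedence, applicability),
# used to cross-check the vectorized engine on small tables.
oracle_flags <- function(rule, ds, schema = default_schema()) {
  df <- ds$tables[[rule$target_table]]
  p <- rule$predicate
  nul <- function(v) is.na(v) || identical(v, "")
  num_ok <- function(v) !nul(v) && grepl("^-?[0-9]+(\\.[0-9]+)?$", v)
  date_ok <- function(v, lo = 1900, hi = 2100) {
    if (nul(v) || !grepl("^[0-9]{8}$", v)) return(FALSE)
    d <- as.Date(v, "%Y%m%d")
    !is.na(d) && as.integer(substr(v, 1, 4)) >= lo &&
      as.integer(substr(v, 1, 4)) <= hi
  }
  in_range <- function(v, rng) {
    if (is.null(rng)) return(!nul(v) && num_ok(v))
    num_ok(v) && as.numeric(v) >= rng[1] && as.numeric(v) <= rng[2]
  }
  ant_ok <- function(rec, ant) {
    v <- rec[[ant$field]]
    if (nul(v)) return(FALSE)
    switch(ant$op, eq = v == ant$value, ne = v != ant$value,
           "in" = v %in% ant$value, not_in = !v %in% ant$value)
  }
  seen <- character()
  out <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    rec <- as.list(df[i, , drop = FALSE])
    if (!is.null(rule$applicability)) {
      a <- rule$applicability
      av <- rec[[a$field]]
      keep <- !nul(av) && if (a$comparator == "eq") av == a$value else
        av != a$value
      if (!keep) next
    }
    v <- rec[[rule$target_fields[1]]]
    out[i] <- switch(p$kind,
      not_null = nul(v),
      numeric_parse = !nul(v) && !num_ok(v),
      range_check = num_ok(v) && ((!is.null(p$min) && as.numeric(v) < p$min) ||
        (!is.null(p$max) && as.numeric(v) > p$max)),
      date_format = !nul(v) && !date_ok(v, p$min_year, p$max_year),
      code_membership = !nul(v) && if (!is.null(p$pattern))
        !grepl(p$pattern, v) else !v %in% p$codes,
      cross_field_compare = {
        l <- rec[[p$left]]; r <- rec[[p$right]]
        lr <- schema[[rule$target_table]]$fields[[p$left]]$plausible_range
        rr <- schema[[rule$target_table]]$fields[[p$right]]$plausible_range
        if (in_range(l, lr) && in_range(r, rr)) {
          !do.call(p$comparator, list(as.numeric(l), as.numeric(r)))
        } else FALSE
      },
      date_order = {
        e <- rec[[p$earlier]]
        l <- if (!is.null(p[["later"]])) rec[[p[["later"]]]] else
          p$later_constant
        if (date_ok(e) && date_ok(l)) {
          as.Date(e, "%Y%m%d") > as.Date(l, "%Y%m%d")
        } else FALSE
      },
      conditional_presence = ant_ok(rec, p$antecedent) &&
        nul(rec[[p$consequent_field]]),
      conditional_valid = {
        if (!ant_ok(rec, p$antecedent)) FALSE else {
          cq <- p$consequent
          cv <- rec[[cq$field]]
          ok <- if (nul(cv)) isTRUE(cq$allow_null) else
            if (identical(cq$op, "not_in")) !cv %in% cq$values else
              cv %in% cq$values
          !ok
        }
      },
      unique_key = {
        dup <- !nul(v) && v %in% seen
        if (!nul(v)) seen <- c(seen, v)
        dup
      })
  }
  which(out)
}

final_rule <- function(id) build_final_catalog()[[id]]

test_that("predicates flag the canonical single-record defects", {
  fin <- build_final_catalog()

  ds <- edited_dataset("basic_info", "KBN_Donor", 3, NA_character_)
  v <- evaluate_rule(fin[["CMP-basic_info-KBN_Donor"]], ds)
  expect_equal(nrow(v), 1)
  expect_true(is.na(v$observed_value))
  expect_identical(v$record_key, "row:3")

  for (bad_date in c("1962318", "660307", "19621340", "19620230")) {
    ds <- edited_dataset("basic_info", "birthdate", 1, bad_date)
    v <- evaluate_rule(fin[["VLD-FMT-basic_info-birthdate"]], ds)
    expect_equal(nrow(v), 1, label = bad_date)
    expect_identical(v$observed_value, bad_date)
  }
  ds <- edited_dataset("basic_info", "birthdate", 1, "19620318")
  expect_equal(nrow(evaluate_rule(fin[["VLD-FMT-basic_info-birthdate"]], ds)),
               0)
  # leap-day handling
  ds <- edited_dataset("basic_info", "birthdate", 1, "20000229")
  expect_equal(nrow(evaluate_rule(fin[["VLD-FMT-basic_info-birthdate"]], ds)),
               0)
  ds <- edited_dataset("basic_info", "birthdate", 1, "19000229")
  expect_equal(nrow(evaluate_rule(fin[["VLD-FMT-basic_info-birthdate"]], ds)),
               1)

  for (bad_code in c("?C21.49", "N80.0-1")) {
    ds <- edited_dataset("basic_info", "diagnosis_code", 2, bad_code)
    v <- evaluate_rule(fin[["VLD-FMT-basic_info-diagnosis_code"]], ds)
    expect_equal(nrow(v), 1, label = bad_code)
  }

  # satisfied comparison yields nothing
  ds <- small_cohort(1, 20)[[1]]
  ds$tables$measurements$height[1] <- "170"
  ds$tables$measurements$weight[1] <- "65"
  expect_equal(nrow(evaluate_rule(
    final_rule("VLD-RNG-measurements-height_gt_weight"), ds)), 0)

  # birthdate after receipt
  ds <- edited_dataset("basic_info", "birthdate", 5, "20201230")
  ds$tables$basic_info$receipt_date[5] <- "20200101"
  v <- evaluate_rule(fin[["ACC-TL-basic_info-birth_before_receipt"]], ds)
  expect_equal(nrow(v), 1)

  # cancer history without recorded type
  ds <- small_cohort(1, 20)[[1]]
  ds$tables$disease_history$DHCa[7] <- "1"
  ds$tables$disease_history$DHCa1[7] <- NA_character_
  v <- evaluate_rule(fin[["ACC-BR-01-cancer_type_present"]], ds)
  expect_gte(nrow(v), 1)
  expect_true(any(v$record_key == ds$tables$disease_history$KBN_Donor[7]))
})

test_that("null precedence: a missing value is only a completeness defect", {
  fin <- build_final_catalog()
  ds <- small_cohort(1, 15)[[1]]
  ds$tables$basic_info$birthdate[4] <- NA_character_
  ds$tables$measurements$weight[6] <- NA_character_
  vs <- evaluate_catalog(fin, ds)
  v4 <- vs$violations[vs$violations$field == "birthdate", ]
  expect_identical(unique(v4$dimension), "completeness")
  v6 <- vs$violations[vs$violations$field == "weight", ]
  expect_identical(unique(v6$dimension), "completeness")
})

test_that("parse and plausibility precedence keep one defect in one dimension", {
  fin <- build_final_catalog()
  # unparseable weight: format defect only, not range, not comparison
  ds <- edited_dataset("measurements", "weight", 2, "6s.2")
  vs <- evaluate_catalog(fin, ds)
  w <- vs$violations[vs$violations$field == "weight", ]
  expect_identical(w$rule_id, "VLD-FMT-measurements-weight")
  # gram-entered weight: range defect only, comparison stays silent
  ds <- edited_dataset("measurements", "weight", 2, "65200")
  vs <- evaluate_catalog(fin, ds)
  w <- vs$violations[vs$violations$field == "weight", ]
  expect_identical(w$rule_id, "VLD-RNG-measurements-weight")
})

test_that("applicability skips records instead of passing them", {
  fin <- build_final_catalog()
  ds <- small_cohort(1, 12)[[1]]
  # flag 9 = not investigated: the presence rule must not evaluate
  ds$tables$disease_history$DHCa[3] <- "9"
  ds$tables$disease_history$DHCa1[3] <- "0"
  expect_equal(nrow(evaluate_rule(fin[["ACC-BR-01-cancer_type_present"]], ds)),
               0)
})

test_that("duplicate counting follows the group-minus-one convention", {
  expect_length(check_unique(c("x", "y", "x")), 1)
  expect_length(check_unique(c("x", "x", "x")), 2)
  expect_length(check_unique(c("a", "b", "c")), 0)
  expect_length(check_unique(c(NA, NA, "", "a")), 0)
})

test_that("catalog evaluation is additive and order-invariant", {
  fin <- build_final_catalog()
  expect_equal(nrow(evaluate_catalog(
    structure(list(), class = "dq_catalog"),
    small_cohort(1, 5))$violations), 0)

  d1 <- edited_dataset("basic_info", "sex", 1, NA_character_, n = 20, seed = 1)
  d2 <- edited_dataset("basic_info", "sex", 2, NA_character_, n = 20, seed = 2)
  d2$institution_id <- "Y"
  d1$tables$basic_info$sex[5:6] <- NA_character_
  d2$tables$basic_info$sex[5:6] <- NA_character_
  rule <- fin["CMP-basic_info-sex"]
  class(rule) <- "dq_catalog"
  vs <- evaluate_catalog(rule, list(d1, d2))
  pc <- per_institution_counts(vs)
  expect_equal(pc$n, c(3L, 3L))
  expect_equal(nrow(vs$violations), 6)
  expect_equal(sum(per_rule_counts(vs)$n), 6)

  # shuffling records changes labels at most, never counts
  perm <- sample(20)
  d1s <- d1
  d1s$tables$basic_info <- d1$tables$basic_info[perm, ]
  vs1 <- evaluate_catalog(fin, d1)
  vs2 <- evaluate_catalog(fin, d1s)
  expect_equal(per_rule_counts(vs2), per_rule_counts(vs1))
})

test_that("the vectorized engine matches the per-record oracle", {
  fin <- build_final_catalog()
  ds <- small_cohort(1, 60, seed = 5)[[1]]
  m <- error_model(null_rate = 0.05, date_malform_rate = 0.08,
                   code_malform_rate = 0.05, unit_error_rate = 0.04,
                   logic_error_rate = 0.04, duplicate_rate = 0.03)
  ds <- inject_errors(list(ds), m, seed = 6)$datasets[[1]]
  # extra hand defects the injector never makes
  ds$tables$measurements$height[1] <- "-5"
  ds$tables$lifestyle$DR_B[2] <- "7"
  ds$tables$disease_history$DHCa[3] <- "1"
  ds$tables$disease_history$DHCa1[3] <- NA_character_
  for (r in fin) {
    got <- evaluate_rule(r, ds)
    want <- oracle_flags(r, ds)
    expect_equal(nrow(got), length(want), label = r$rule_id)
  }
})

test_that("unsupported predicates and tables raise engine errors", {
  ds <- small_cohort(1, 5)[[1]]
  bad <- rule_spec("x", "validity", "format", "E", "basic_info", "sex",
                   list(kind = "code_membership", codes = "1"))
  bad$predicate$kind <- "teleport"
  expect_error(evaluate_rule(bad, ds), class = "dq_engine_error")
  r <- rule_spec("y", "completeness", "none", "E", "ghost", "f",
                 list(kind = "not_null"))
  expect_error(evaluate_rule(r, ds), class = "dq_engine_error")
})

test_that("SQL export mirrors the engine's predicates", {
  fin <- build_final_catalog()
  expect_match(export_rule_sql(fin[["CMP-basic_info-KBN_Donor"]]),
               "KBN_Donor IS NULL")
  expect_match(export_rule_sql(fin[["VLD-RNG-measurements-weight"]]),
               "CAST\\(weight AS REAL\\) < 0.1")
  expect_match(export_rule_sql(fin[["UNQ-basic_info-KBN_Donor"]]),
               "HAVING COUNT\\(\\*\\) > 1")
  expect_match(export_rule_sql(fin[["ACC-BR-01-cancer_type_present"]]),
               "DHCa1 IS NULL")
})

test_that("the exported duplicate-key query agrees with check_unique", {
  # executed against SQLite (via the system python) on a 5-row fixture
  sql <- export_rule_sql(build_final_catalog()[["UNQ-basic_info-KBN_Donor"]])
  keys <- c("d1", "d2", "d1", "d1", "d3")
  values <- paste(sprintf("('%s',)", keys), collapse = ", ")
  py <- c(
    "import sqlite3",
    "con = sqlite3.connect(':memory:')",
    "con.execute('CREATE TABLE basic_info (KBN_Donor TEXT)')",
    sprintf("con.executemany('INSERT INTO basic_info VALUES (?)', [%s])",
            values),
    sprintf('rows = con.execute("""%s""").fetchall()', sql),
    "total = 0",
    "for (k,) in rows:",
    "    c = con.execute('SELECT COUNT(*) FROM basic_info WHERE KBN_Donor = ?', (k,)).fetchone()[0]",
    "    total += c - 1",
    "print(total)")
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(py, script)
  out <- system2("python", script, stdout = TRUE)
  expect_equal(as.integer(out[length(out)]), length(check_unique(keys)))
})
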
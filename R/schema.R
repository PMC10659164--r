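#' Field specification
#'
#' Describes one column of a registry table: its value class, unit,
#' nullability and, where applicable, the enumerated code set or plausible
#' numeric range. All values in a dataset are raw strings; the value class
#' tells the rule engine how a value *should* parse, it never coerces.
#'
#' @param name Field identifier.
#' @param value_class One of `"coded-integer"`, `"numeric"`,
#'   `"date-YYYYMMDD"`, `"code-string"`, `"free-text"`.
#' @param unit Measurement unit (e.g. `"cm"`, `"kg"`, `"mmHg"`), or `""`.
#' @param nullable May the field be empty without a completeness defect?
#' @param allowed_codes Optional character vector of permitted codes; only
#'   meaningful for coded-integer and code-string fields.
#' @param plausible_range Optional `c(min, max)` inclusive bounds; only
#'   meaningful for numeric fields.
#' @return An object of class `dq_field`.
#' @export
field_spec <- function(name, value_class, unit = "", nullable = FALSE,
                       allowed_codes = NULL, plausible_range = NULL) {
  classes <- c("coded-integer", "numeric", "date-YYYYMMDD", "code-string",
               "free-text")
  if (!value_class %in% classes) {
    dq_abort(sprintf("unknown value_class '%s' for field '%s'",
                     value_class, name), "dq_schema_error")
  }
  if (!is.null(allowed_codes) &&
      !value_class %in% c("coded-integer", "code-string")) {
    dq_abort(sprintf("allowed_codes given for non-coded field '%s'", name),
             "dq_schema_error")
  }
  if (!is.null(plausible_range)) {
    if (value_class != "numeric") {
      dq_abort(sprintf("plausible_range given for non-numeric field '%s'",
                       name), "dq_schema_error")
    }
    if (length(plausible_range) != 2 ||
        plausible_range[1] > plausible_range[2]) {
      dq_abort(sprintf("plausible_range of '%s' must be c(min, max), min <= max",
                       name), "dq_schema_error")
    }
  }
  structure(list(name = name, value_class = value_class, unit = unit,
                 nullable = nullable,
                 allowed_codes = as.character(allowed_codes %||% character()),
                 plausible_range = plausible_range),
            class = "dq_field")
}

#' Table specification
#'
#' @param name Table identifier.
#' @param fields List of [field_spec()] objects, in column order.
#' @param key_fields Character vector of key field names (may be empty for
#'   non-keyed tables).
#' @return An object of class `dq_table`.
#' @export
table_spec <- function(name, fields, key_fields = character()) {
  nms <- vapply(fields, function(f) f$name, character(1))
  if (anyDuplicated(nms)) {
    dq_abort(sprintf("duplicate field name in table '%s': %s", name,
                     paste(unique(nms[duplicated(nms)]), collapse = ", ")),
             "dq_schema_error")
  }
  if (!all(key_fields %in% nms)) {
    dq_abort(sprintf("key fields of '%s' not among its fields", name),
             "dq_schema_error")
  }
  structure(list(name = name, fields = stats::setNames(fields, nms),
                 key_fields = key_fields),
            class = "dq_table")
}

schema_field <- function(schema, table, field) {
  tab <- schema[[table]]
  if (is.null(tab)) dq_abort(sprintf("no table '%s' in schema", table),
                             "dq_schema_error")
  fld <- tab$fields[[field]]
  if (is.null(fld)) dq_abort(sprintf("no field '%s' in table '%s'",
                                     field, table), "dq_schema_error")
  fld
}

# Code sets used by the default schema. Flags follow the registry
# convention 0 = no, 1 = yes, 9 = not investigated; cancer-type codes are a
# compact ICD-10-like set with 0 = not applicable and C99 = other cancer.
FLAG_CODES <- c("0", "1", "9")
CANCER_CODES <- c("0", "C16", "C18", "C22", "C34", "C50", "C61", "C73", "C99")
FREQ_CODES <- c("0", "1", "2", "3")

#' Default biobank-network schema
#'
#' The built-in relational schema of a donor-centric clinical-epidemiological
#' registry: a basic-information table keyed by the donor identifier
#' (`KBN_Donor`), physical measurements, laboratory results, disease and
#' family history with yes/no/not-investigated flags and type codes, and a
#' lifestyle (drinking/smoking/exercise) questionnaire. 54 fields over five
#' tables; all non-key coded fields carry explicit code sets and all numeric
#' fields carry plausible ranges.
#'
#' @return Named list of [table_spec()] objects (class `dq_schema`).
#' @export
default_schema <- function() {
  basic <- table_spec("basic_info", list(
    field_spec("KBN_Donor", "code-string"),
    field_spec("sex", "coded-integer", allowed_codes = c("1", "2")),
    field_spec("birthdate", "date-YYYYMMDD"),
    field_spec("receipt_date", "date-YYYYMMDD"),
    field_spec("diagnosis_code", "code-string"),
    field_spec("disease_group", "coded-integer",
               allowed_codes = as.character(1:26)),
    field_spec("diagnosis_name", "free-text"),
    field_spec("occupation", "free-text", nullable = TRUE)
  ), key_fields = "KBN_Donor")

  meas <- table_spec("measurements", list(
    field_spec("KBN_Donor", "code-string"),
    field_spec("measure_date", "date-YYYYMMDD"),
    field_spec("height", "numeric", unit = "cm", plausible_range = c(50, 250)),
    field_spec("weight", "numeric", unit = "kg", plausible_range = c(0.1, 300)),
    field_spec("SBP", "numeric", unit = "mmHg", plausible_range = c(40, 300)),
    field_spec("DBP", "numeric", unit = "mmHg", plausible_range = c(20, 200))
  ), key_fields = "KBN_Donor")

  lab_fields <- list(
    field_spec("KBN_Donor", "code-string"),
    field_spec("total_protein", "numeric", unit = "g/dL",
               plausible_range = c(2, 15)),
    field_spec("albumin", "numeric", unit = "g/dL", plausible_range = c(1, 7)),
    field_spec("glucose", "numeric", unit = "mg/dL",
               plausible_range = c(20, 800)),
    field_spec("hba1c", "numeric", unit = "%", plausible_range = c(3, 20)),
    field_spec("creatinine", "numeric", unit = "mg/dL",
               plausible_range = c(0.1, 25)),
    field_spec("bun", "numeric", unit = "mg/dL", plausible_range = c(1, 200)),
    field_spec("ast", "numeric", unit = "IU/L", plausible_range = c(1, 3000)),
    field_spec("alt", "numeric", unit = "IU/L", plausible_range = c(1, 3000)),
    field_spec("total_cholesterol", "numeric", unit = "mg/dL",
               plausible_range = c(50, 600)),
    field_spec("triglyceride", "numeric", unit = "mg/dL",
               plausible_range = c(10, 4000)),
    field_spec("hdl_cholesterol", "numeric", unit = "mg/dL",
               plausible_range = c(5, 200)),
    field_spec("hemoglobin", "numeric", unit = "g/dL",
               plausible_range = c(3, 25))
  )
  lab <- table_spec("lab", lab_fields, key_fields = "KBN_Donor")

  dh <- table_spec("disease_history", list(
    field_spec("KBN_Donor", "code-string"),
    field_spec("DHCa", "coded-integer", allowed_codes = FLAG_CODES),
    field_spec("DHCa1", "code-string", allowed_codes = CANCER_CODES,
               nullable = TRUE),
    field_spec("DHCa2", "code-string", allowed_codes = CANCER_CODES,
               nullable = TRUE),
    field_spec("DHCa_other", "free-text", nullable = TRUE),
    field_spec("DHHtn", "coded-integer", allowed_codes = FLAG_CODES),
    field_spec("DHHtn_medication", "free-text", nullable = TRUE),
    field_spec("DHDm", "coded-integer", allowed_codes = FLAG_CODES),
    field_spec("DHDm_medication", "free-text", nullable = TRUE),
    field_spec("DHTb", "coded-integer", allowed_codes = FLAG_CODES),
    field_spec("DHHep", "coded-integer", allowed_codes = FLAG_CODES),
    field_spec("DHCvd", "coded-integer", allowed_codes = FLAG_CODES),
    field_spec("DHThy", "coded-integer", allowed_codes = FLAG_CODES),
    field_spec("DHRen", "coded-integer", allowed_codes = FLAG_CODES),
    field_spec("DHEtc", "coded-integer", allowed_codes = FLAG_CODES),
    field_spec("DHEtc_name", "free-text", nullable = TRUE),
    field_spec("FHCa", "coded-integer", allowed_codes = FLAG_CODES),
    field_spec("FHCa_other", "free-text", nullable = TRUE)
  ), key_fields = "KBN_Donor")

  life <- table_spec("lifestyle", list(
    field_spec("KBN_Donor", "code-string"),
    field_spec("DR_A", "coded-integer", allowed_codes = FLAG_CODES,
               nullable = TRUE),
    field_spec("DR_B", "coded-integer", allowed_codes = FREQ_CODES,
               nullable = TRUE),
    field_spec("DR_C", "numeric", unit = "drinks/week",
               plausible_range = c(0, 150), nullable = TRUE),
    field_spec("DR_D", "numeric", unit = "years", plausible_range = c(0, 90),
               nullable = TRUE),
    field_spec("SM_A", "coded-integer", allowed_codes = FLAG_CODES,
               nullable = TRUE),
    field_spec("SM_B", "coded-integer", allowed_codes = FREQ_CODES,
               nullable = TRUE),
    field_spec("SM_C", "numeric", unit = "pack-years",
               plausible_range = c(0, 200), nullable = TRUE),
    field_spec("EX_A", "coded-integer", allowed_codes = FLAG_CODES,
               nullable = TRUE)
  ), key_fields = "KBN_Donor")

  structure(list(basic_info = basic, measurements = meas, lab = lab,
                 disease_history = dh, lifestyle = life),
            class = "dq_schema")
}

#' Load a schema from a YAML configuration file
#'
#' The YAML layout mirrors [default_schema()]: a top-level `tables` list,
#' each entry holding `name`, optional `key_fields`, and a `fields` list of
#' field descriptors (`name`, `value_class`, optional `unit`, `nullable`,
#' `allowed_codes`, `plausible_range`). An empty `tables` list yields an
#' empty schema.
#'
#' @param config_path Path to the YAML file.
#' @return Named list of [table_spec()] objects (class `dq_schema`).
#' @export
load_schema <- function(config_path) {
  if (!file.exists(config_path)) {
    dq_abort(sprintf("schema config not found: %s", config_path),
             "dq_schema_error")
  }
  cfg <- tryCatch(yaml::read_yaml(config_path), error = function(e) {
    dq_abort(sprintf("malformed schema config %s: %s", config_path,
                     conditionMessage(e)), "dq_schema_error")
  })
  tabs <- cfg$tables %||% list()
  out <- lapply(tabs, function(t) {
    flds <- lapply(t$fields %||% list(), function(f) {
      field_spec(f$name, f$value_class, unit = f$unit %||% "",
                 nullable = isTRUE(f$nullable),
                 allowed_codes = f$allowed_codes,
                 plausible_range = if (!is.null(f$plausible_range))
                   as.numeric(f$plausible_range))
    })
    table_spec(t$name, flds, key_fields = as.character(t$key_fields %||%
                                                         character()))
  })
  names(out) <- vapply(tabs, function(t) t$name, character(1))
  structure(out, class = "dq_schema")
}

#' Write a schema to YAML
#'
#' Inverse of [load_schema()].
#'
#' @param schema A `dq_schema`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  tabs <- lapply(unname(schema), function(t) {
    list(name = t$name,
         key_fields = as.list(t$key_fields),
         fields = lapply(unname(t$fields), function(f) {
           x <- list(name = f$name, value_class = f$value_class)
           if (nzchar(f$unit)) x$unit <- f$unit
           if (f$nullable) x$nullable <- TRUE
           if (length(f$allowed_codes)) x$allowed_codes <-
               as.list(f$allowed_codes)
           if (!is.null(f$plausible_range)) x$plausible_range <-
               as.list(f$plausible_range)
           x
         }))
  })
  yaml::write_yaml(list(tables = tabs), path)
  invisible(path)
}

#' Read one institution's dataset from a directory of CSV files
#'
#' Expects one UTF-8 comma-separated file per schema table, named
#' `<table>.csv`, with a header row matching the schema's field names
#' exactly. Every cell is kept as a raw string -- no type coercion happens at
#' read time, so malformed dates, undefined codes and unit errors arrive in
#' the dataset verbatim and are surfaced by validation rules, never by I/O.
#' Empty cells become nulls (`NA`).
#'
#' @param directory Directory holding the per-table CSV files.
#' @param schema A `dq_schema`.
#' @param institution_id Institution label; defaults to the directory name.
#' @return An object of class `dq_dataset`: `institution_id` plus a named
#'   list `tables` of character data frames.
#' @export
read_dataset <- function(directory, schema, institution_id = basename(directory)) {
  tables <- lapply(schema, function(tab) {
    path <- file.path(directory, paste0(tab$name, ".csv"))
    if (!file.exists(path)) {
      dq_abort(sprintf("missing file for table '%s': %s", tab$name, path),
               "dq_io_error")
    }
    df <- utils::read.csv(path, colClasses = "character", na.strings = "",
                          check.names = FALSE, fileEncoding = "UTF-8")
    want <- names(tab$fields)
    if (!identical(names(df), want)) {
      missing <- setdiff(want, names(df))
      extra <- setdiff(names(df), want)
      dq_abort(sprintf(
        "header mismatch in %s (missing: %s; extra: %s)", path,
        paste(missing, collapse = ",") , paste(extra, collapse = ",")),
        "dq_structure_error")
    }
    df
  })
  names(tables) <- names(schema)
  new_dataset(institution_id, tables)
}

#' @rdname read_dataset
#' @param dataset A `dq_dataset` to write.
#' @export
write_dataset <- function(dataset, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(dataset$tables)) {
    utils::write.csv(dataset$tables[[nm]],
                     file.path(directory, paste0(nm, ".csv")),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  invisible(directory)
}

new_dataset <- function(institution_id, tables) {
  structure(list(institution_id = institution_id, tables = tables),
            class = "dq_dataset")
}

#' @export
print.dq_dataset <- function(x, ...) {
  cat(sprintf("<dq_dataset> institution %s\n", x$institution_id))
  for (nm in names(x$tables)) {
    cat(sprintf("  %-16s %d records\n", nm, nrow(x$tables[[nm]])))
  }
  invisible(x)
}

#' @export
print.dq_schema <- function(x, ...) {
  cat(sprintf("<dq_schema> %d tables, %d fields\n", length(x),
              sum(vapply(x, function(t) length(t$fields), integer(1)))))
  invisible(x)
}
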
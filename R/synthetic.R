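#' Synthetic-generator configuration
#'
#' Describes the clean (error-free) multi-institution registry the generator
#' emulates: 16 unit biobanks (labels A-P) by default, roughly a thousand
#' donor records each, with anthropometric and blood-pressure values drawn
#' from normal distributions well inside the schema's plausible ranges,
#' birth years 1930-2002, receipt dates in the 2020 collection year,
#' disease-history prevalences of a mixed adult clinical population and
#' drinking/smoking questionnaire items with realistic yes/no/not-investigated
#' splits.
#'
#' @param n_institutions Number of institutions (default 16).
#' @param n_records Per-institution record count; scalar or vector of length
#'   `n_institutions`.
#' @param seed Integer seed; the generator is bit-reproducible given
#'   (config, seed).
#' @param institution_ids Labels; default `LETTERS[1:n_institutions]`.
#' @return A `dq_generator_config`.
#' @export
generator_config <- function(n_institutions = 16, n_records = 1000,
                             seed = 1L,
                             institution_ids = LETTERS[seq_len(n_institutions)]) {
  if (n_institutions < 1) dq_abort("need at least one institution",
                                   "dq_config_error")
  n_records <- rep_len(as.integer(n_records), n_institutions)
  if (any(n_records < 0)) dq_abort("record counts must be >= 0",
                                   "dq_config_error")
  if (length(institution_ids) != n_institutions ||
      anyDuplicated(institution_ids)) {
    dq_abort("institution_ids must be unique and match n_institutions",
             "dq_config_error")
  }
  structure(list(n_institutions = as.integer(n_institutions),
                 n_records = n_records, seed = as.integer(seed),
                 institution_ids = institution_ids),
            class = "dq_generator_config")
}

DIAG_CODES <- c("C16.9", "C18.7", "C22.0", "C34.1", "C50.9", "C61", "C73",
                "I10", "E11.9", "K29.6", "N18.3", "J44.9")
DIAG_NAMES <- c("gastric carcinoma", "colon carcinoma", "liver carcinoma",
                "lung carcinoma", "breast carcinoma", "prostate carcinoma",
                "thyroid carcinoma", "essential hypertension",
                "type 2 diabetes", "chronic gastritis",
                "chronic kidney disease", "COPD")
OCCUPATIONS <- c("farmer", "office worker", "teacher", "retired",
                 "self-employed", "homemaker", "none")
HTN_MEDS <- c("amlodipine", "losartan", "telmisartan", "hydrochlorothiazide")
DM_MEDS <- c("metformin", "glimepiride", "sitagliptin", "insulin")
OTHER_DISEASES <- c("asthma", "gout", "osteoporosis", "depression",
                    "rheumatoid arthritis")
CANCER_NAMES <- c("pancreatic cancer", "bladder cancer", "ovarian cancer",
                  "laryngeal cancer")
FH_DETAILS <- c("father - gastric cancer", "mother - breast cancer",
                "sibling - colon cancer", "parent - liver cancer")

date8 <- function(year, month, day) sprintf("%04d%02d%02d", year, month, day)

clipped_normal <- function(n, mean, sd, lo, hi, digits = 1) {
  x <- pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
  formatC(round(x, digits), format = "f", digits = digits)
}

flag_sample <- function(n, p_yes, p_ni = 0.05) {
  sample(c("0", "1", "9"), n, replace = TRUE,
         prob = c(1 - p_yes - p_ni, p_yes, p_ni))
}

# One clean institution table set. Values are constructed to satisfy every
# rule of both the pre-review and the reviewed catalog: all fields filled
# (free-text uses "-" when not applicable), codes from the schema's code
# sets, numbers inside plausible ranges, height > weight, SBP > DBP,
# birthdate <= receipt date <= evaluation cutoff, and flag/type/detail
# triples logically consistent.
generate_institution <- function(inst, n) {
  donor <- sprintf("KBN-%s-%06d", inst, seq_len(n))
  birth <- date8(sample(1930:2002, n, TRUE), sample(1:12, n, TRUE),
                 sample(1:28, n, TRUE))
  receipt <- date8(2020L, sample(1:12, n, TRUE), sample(1:28, n, TRUE))
  mdate <- date8(2020L, sample(1:12, n, TRUE), sample(1:28, n, TRUE))
  code_i <- sample(seq_along(DIAG_CODES), n, TRUE)

  basic <- data.frame(
    KBN_Donor = donor,
    sex = sample(c("1", "2"), n, TRUE, prob = c(0.48, 0.52)),
    birthdate = birth,
    receipt_date = receipt,
    diagnosis_code = DIAG_CODES[code_i],
    disease_group = as.character(sample(1:26, n, TRUE)),
    diagnosis_name = DIAG_NAMES[code_i],
    occupation = sample(OCCUPATIONS, n, TRUE),
    stringsAsFactors = FALSE)

  dbp <- pmin(pmax(stats::rnorm(n, 76, 8), 55), 95)
  sbp <- dbp + pmin(pmax(stats::rnorm(n, 45, 10), 15), 90)
  meas <- data.frame(
    KBN_Donor = donor,
    measure_date = mdate,
    height = clipped_normal(n, 162, 9, 130, 200),
    weight = clipped_normal(n, 63, 11, 35, 125),
    SBP = as.character(round(sbp)),
    DBP = as.character(round(dbp)),
    stringsAsFactors = FALSE)

  lab <- data.frame(
    KBN_Donor = donor,
    total_protein = clipped_normal(n, 7.1, 0.5, 5, 9),
    albumin = clipped_normal(n, 4.3, 0.4, 3, 5.5),
    glucose = clipped_normal(n, 102, 22, 60, 350, 0),
    hba1c = clipped_normal(n, 5.8, 0.8, 4, 12),
    creatinine = clipped_normal(n, 0.9, 0.25, 0.3, 4, 2),
    bun = clipped_normal(n, 15, 5, 4, 60, 0),
    ast = clipped_normal(n, 26, 10, 8, 200, 0),
    alt = clipped_normal(n, 24, 12, 5, 250, 0),
    total_cholesterol = clipped_normal(n, 190, 35, 90, 400, 0),
    triglyceride = clipped_normal(n, 130, 60, 30, 900, 0),
    hdl_cholesterol = clipped_normal(n, 54, 13, 20, 120, 0),
    hemoglobin = clipped_normal(n, 13.8, 1.5, 8, 19),
    stringsAsFactors = FALSE)

  dhca <- flag_sample(n, 0.15)
  has_ca <- dhca == "1"
  dhca1 <- rep("0", n)
  dhca1[has_ca] <- sample(setdiff(CANCER_CODES, "0"), sum(has_ca), TRUE,
                          prob = c(rep(0.85 / 7, 7), 0.15))
  dhca2 <- rep("0", n)
  second <- has_ca & stats::runif(n) < 0.1
  dhca2[second] <- sample(setdiff(CANCER_CODES, c("0", "C99")), sum(second),
                          TRUE)
  dhca_other <- rep("-", n)
  dhca_other[dhca1 == "C99"] <- sample(CANCER_NAMES, sum(dhca1 == "C99"), TRUE)

  dhhtn <- flag_sample(n, 0.25); dhdm <- flag_sample(n, 0.12)
  dhetc <- flag_sample(n, 0.10); fhca <- flag_sample(n, 0.12)
  htn_med <- rep("-", n)
  htn_med[dhhtn == "1"] <- sample(HTN_MEDS, sum(dhhtn == "1"), TRUE)
  dm_med <- rep("-", n)
  dm_med[dhdm == "1"] <- sample(DM_MEDS, sum(dhdm == "1"), TRUE)
  etc_name <- rep("-", n)
  etc_name[dhetc == "1"] <- sample(OTHER_DISEASES, sum(dhetc == "1"), TRUE)
  fh_other <- rep("-", n)
  fh_other[fhca == "1"] <- sample(FH_DETAILS, sum(fhca == "1"), TRUE)

  dh <- data.frame(
    KBN_Donor = donor, DHCa = dhca, DHCa1 = dhca1, DHCa2 = dhca2,
    DHCa_other = dhca_other, DHHtn = dhhtn, DHHtn_medication = htn_med,
    DHDm = dhdm, DHDm_medication = dm_med,
    DHTb = flag_sample(n, 0.03), DHHep = flag_sample(n, 0.04),
    DHCvd = flag_sample(n, 0.08), DHThy = flag_sample(n, 0.05),
    DHRen = flag_sample(n, 0.03), DHEtc = dhetc, DHEtc_name = etc_name,
    FHCa = fhca, FHCa_other = fh_other,
    stringsAsFactors = FALSE)

  dra <- flag_sample(n, 0.50); sma <- flag_sample(n, 0.30)
  drinker <- dra == "1"; smoker <- sma == "1"
  drb <- rep("0", n); drb[drinker] <- sample(c("1", "2", "3"), sum(drinker),
                                             TRUE)
  drc <- rep("0", n)
  drc[drinker] <- formatC(round(stats::runif(sum(drinker), 0.5, 30), 1),
                          format = "f", digits = 1)
  drd <- rep("0", n); drd[drinker] <- as.character(sample(1:50, sum(drinker),
                                                          TRUE))
  smb <- rep("0", n); smb[smoker] <- sample(c("1", "2", "3"), sum(smoker),
                                            TRUE)
  smc <- rep("0", n)
  smc[smoker] <- formatC(round(stats::runif(sum(smoker), 0.5, 60), 1),
                         format = "f", digits = 1)

  life <- data.frame(
    KBN_Donor = donor, DR_A = dra, DR_B = drb, DR_C = drc, DR_D = drd,
    SM_A = sma, SM_B = smb, SM_C = smc, EX_A = flag_sample(n, 0.40),
    stringsAsFactors = FALSE)

  new_dataset(inst, list(basic_info = basic, measurements = meas, lab = lab,
                         disease_history = dh, lifestyle = life))
}

#' Generate clean multi-institution datasets
#'
#' Produces one error-free dataset per institution: the output yields zero
#' violations under both the pre-review (128-rule) and the reviewed
#' (104-rule) catalog, and is bit-reproducible from the config seed.
#'
#' @param config A [generator_config()].
#' @return List of `dq_dataset` objects, one per institution.
#' @export
generate_clean <- function(config = generator_config()) {
  if (!inherits(config, "dq_generator_config")) {
    dq_abort("config must come from generator_config()", "dq_config_error")
  }
  set.seed(config$seed)
  out <- vector("list", config$n_institutions)
  for (j in seq_len(config$n_institutions)) {
    out[[j]] <- generate_institution(config$institution_ids[j],
                                     config$n_records[j])
  }
  names(out) <- config$institution_ids
  out
}

#' Error-injection model
#'
#' Per-error-type injection rates (fraction of an institution's records
#' corrupted), each a scalar or a per-institution vector. The six types
#' mirror the defect classes observed in multicenter registry submissions:
#'
#' * `null_rate` -- nulls in essential fields (`null_fields`, default the
#'   donor identifier, sex, the cancer-history flag and the drinking flag);
#' * `date_malform_rate` -- birthdates truncated to 6 digits (`YYMMDD`) or 7
#'   digits, with equal probability;
#' * `code_malform_rate` -- diagnosis codes prefixed with `"?"` or suffixed
#'   with `"-1"`;
#' * `unit_error_rate` -- weights multiplied by 1000 (kg entered as g);
#' * `logic_error_rate` -- a cancer-type code recorded while the history
#'   flag says no cancer;
#' * `duplicate_rate` -- a donor identifier copied onto another record.
#'
#' Injection sites are chosen without overlap (at most one corruption per
#' record and field) and so that, on clean data, each injection trips
#' exactly one rule of the reviewed catalog.
#'
#' @param null_rate,date_malform_rate,code_malform_rate,unit_error_rate,logic_error_rate,duplicate_rate
#'   Rates in `[0, 1]`.
#' @param null_fields Named list `table -> field names` targeted by
#'   `null_rate` (each listed field receives `round(rate * n)` nulls).
#' @return A `dq_error_model`.
#' @export
error_model <- function(null_rate = 0, date_malform_rate = 0,
                        code_malform_rate = 0, unit_error_rate = 0,
                        logic_error_rate = 0, duplicate_rate = 0,
                        null_fields = list(
                          basic_info = c("KBN_Donor", "sex"),
                          disease_history = "DHCa",
                          lifestyle = "DR_A")) {
  rates <- list(null_rate = null_rate, date_malform_rate = date_malform_rate,
                code_malform_rate = code_malform_rate,
                unit_error_rate = unit_error_rate,
                logic_error_rate = logic_error_rate,
                duplicate_rate = duplicate_rate)
  for (nm in names(rates)) {
    if (any(rates[[nm]] < 0 | rates[[nm]] > 1)) {
      dq_abort(sprintf("%s must lie in [0, 1]", nm), "dq_config_error")
    }
  }
  structure(c(rates, list(null_fields = null_fields)),
            class = "dq_error_model")
}

rate_for <- function(rate, j) rate[[min(j, length(rate))]]

# Rules credited in the ground-truth ledger for each injection channel.
NULL_RULE_OF <- c(
  "basic_info.KBN_Donor" = "CMP-basic_info-KBN_Donor",
  "basic_info.sex" = "CMP-basic_info-sex",
  "disease_history.DHCa" = "CMP-disease_history-DHCa",
  "lifestyle.DR_A" = "CMP-lifestyle-DR_A")
DATE_RULE <- "VLD-FMT-basic_info-birthdate"
CODE_RULE <- "VLD-FMT-basic_info-diagnosis_code"
UNIT_RULE <- "VLD-RNG-measurements-weight"
LOGIC_RULE <- "ACC-BR-02-cancer_type_implies_history"
DUP_RULE <- "UNQ-basic_info-KBN_Donor"

#' Inject controlled errors into clean datasets
#'
#' Corrupts clean datasets according to an [error_model()] and returns both
#' the corrupted datasets and a ground-truth ledger recording, per
#' institution and per rule, how many violations were injected. Because
#' sites are disjoint and each corruption trips exactly one reviewed-catalog
#' rule, [evaluate_catalog()] with [build_final_catalog()] on the corrupted
#' data recovers the ledger exactly.
#'
#' Nullable-flag sites are restricted to records where the corruption is
#' free of side effects (e.g. the cancer-history flag is only nulled on
#' records without a recorded cancer type), and requesting more injections
#' than there are eligible sites is an error.
#'
#' @param datasets Clean datasets from [generate_clean()].
#' @param model An [error_model()].
#' @param seed Integer seed for site selection.
#' @return A list with `datasets` (corrupted) and `ledger` (tibble
#'   `institution_id`, `rule_id`, `injected`).
#' @export
inject_errors <- function(datasets, model, seed = 1L) {
  if (!inherits(model, "dq_error_model")) {
    dq_abort("model must come from error_model()", "dq_config_error")
  }
  set.seed(seed)
  ledger <- list()
  credit <- function(inst, rule, k) {
    if (k > 0) ledger[[length(ledger) + 1L]] <<- tibble::tibble(
      institution_id = inst, rule_id = rule, injected = as.integer(k))
  }
  pick <- function(pool, k, what, inst) {
    if (k > length(pool)) {
      dq_abort(sprintf(
        "institution %s: %d %s injections requested but only %d eligible sites",
        inst, k, what, length(pool)), "dq_injection_error")
    }
    if (k == 0) integer() else sample(pool, k)
  }

  for (j in seq_along(datasets)) {
    ds <- datasets[[j]]
    inst <- ds$institution_id
    n <- nrow(ds$tables$basic_info)
    if (n == 0) next

    ## Logic errors first: they constrain the flag-null eligibility below.
    k_logic <- round(rate_for(model$logic_error_rate, j) * n)
    dh <- ds$tables$disease_history
    logic_pool <- which(dh$DHCa == "0" & dh$DHCa1 == "0")
    logic_idx <- pick(logic_pool, k_logic, "logic", inst)
    if (length(logic_idx)) {
      dh$DHCa1[logic_idx] <- sample(setdiff(CANCER_CODES, c("0", "C99")),
                                    length(logic_idx), TRUE)
      credit(inst, LOGIC_RULE, length(logic_idx))
    }

    ## Essential-field nulls.
    null_rate <- rate_for(model$null_rate, j)
    for (tab in names(model$null_fields)) {
      for (f in model$null_fields[[tab]]) {
        k <- round(null_rate * n)
        pool <- switch(paste(tab, f, sep = "."),
          "disease_history.DHCa" = setdiff(
            which(dh$DHCa %in% c("0", "9") & dh$DHCa1 == "0"), logic_idx),
          "lifestyle.DR_A" = which(ds$tables$lifestyle$DR_A %in% c("0", "9")),
          seq_len(nrow(ds$tables[[tab]])))
        idx <- pick(pool, k, paste0("null(", f, ")"), inst)
        if (length(idx)) {
          if (tab == "disease_history") dh[[f]][idx] <- NA_character_
          else ds$tables[[tab]][[f]][idx] <- NA_character_
          rule <- NULL_RULE_OF[[paste(tab, f, sep = ".")]]
          if (is.null(rule)) rule <- sprintf("CMP-%s-%s", tab, f)
          credit(inst, rule, length(idx))
        }
      }
    }
    ds$tables$disease_history <- dh

    ## Malformed birthdates: 6-digit (YYMMDD) or 7-digit forms.
    k_date <- round(rate_for(model$date_malform_rate, j) * n)
    idx <- pick(seq_len(n), k_date, "date-malform", inst)
    if (length(idx)) {
      b <- ds$tables$basic_info$birthdate[idx]
      six <- stats::runif(length(idx)) < 0.5
      b[six] <- substr(b[six], 3, 8)
      b[!six] <- substr(b[!six], 1, 7)
      ds$tables$basic_info$birthdate[idx] <- b
      credit(inst, DATE_RULE, length(idx))
    }

    ## Undefined diagnosis codes: "?" prefix or "-1" suffix.
    k_code <- round(rate_for(model$code_malform_rate, j) * n)
    idx <- pick(seq_len(n), k_code, "code-malform", inst)
    if (length(idx)) {
      cc <- ds$tables$basic_info$diagnosis_code[idx]
      pre <- stats::runif(length(idx)) < 0.5
      cc[pre] <- paste0("?", cc[pre])
      cc[!pre] <- paste0(cc[!pre], "-1")
      ds$tables$basic_info$diagnosis_code[idx] <- cc
      credit(inst, CODE_RULE, length(idx))
    }

    ## kg -> g unit errors on weight.
    k_unit <- round(rate_for(model$unit_error_rate, j) * n)
    idx <- pick(seq_len(n), k_unit, "unit", inst)
    if (length(idx)) {
      w <- as_num(ds$tables$measurements$weight[idx])
      ds$tables$measurements$weight[idx] <- as.character(round(w * 1000))
      credit(inst, UNIT_RULE, length(idx))
    }

    ## Duplicate donor identifiers: copy one record's ID onto another.
    k_dup <- round(rate_for(model$duplicate_rate, j) * n)
    donor_null_idx <- which(is.na(ds$tables$basic_info$KBN_Donor))
    dup_pool <- setdiff(seq_len(n), donor_null_idx)
    both <- pick(dup_pool, 2L * k_dup, "duplicate", inst)
    if (k_dup > 0) {
      src <- both[seq_len(k_dup)]
      dst <- both[k_dup + seq_len(k_dup)]
      ds$tables$basic_info$KBN_Donor[dst] <-
        ds$tables$basic_info$KBN_Donor[src]
      credit(inst, DUP_RULE, k_dup)
    }

    datasets[[j]] <- ds
  }

  led <- if (length(ledger)) do.call(rbind, ledger) else
    tibble::tibble(institution_id = character(), rule_id = character(),
                   injected = integer())
  led <- led[order(led$institution_id, led$rule_id), ]
  list(datasets = datasets, ledger = tibble::as_tibble(led))
}

#' Build an error model whose totals follow a linear law in biobank size
#'
#' Sets each institution's injected-error total to
#' `round(slope * n_i + rnorm(1, 0, sigma))` (floored at 0), where `n_i` is
#' its record count, and splits that total evenly across three side-effect
#' free channels (sex nulls, malformed birthdates, malformed diagnosis
#' codes). Because error recovery is exact, the correlation between
#' biospecimen counts and detected error totals has the computable
#' theoretical value `slope * sd(n) / sqrt(slope^2 * var(n) + sigma^2)`,
#' recorded as attribute `theoretical_r`.
#'
#' @param record_counts Per-institution record counts.
#' @param slope Expected extra errors per additional record.
#' @param sigma Standard deviation of the institution-level noise (errors).
#' @param seed Integer seed for the noise draw.
#' @return A `dq_error_model` with attributes `theoretical_r` and `targets`.
#' @export
error_model_from_biospecimens <- function(record_counts, slope, sigma,
                                          seed = 1L) {
  set.seed(seed)
  n <- as.numeric(record_counts)
  targets <- pmax(0, round(slope * n + stats::rnorm(length(n), 0, sigma)))
  targets <- pmin(targets, 3 * n)  # each channel holds at most n sites
  k_sex <- targets %/% 3
  k_date <- targets %/% 3
  k_code <- targets - 2 * (targets %/% 3)
  m <- error_model(
    null_rate = ifelse(n > 0, k_sex / n, 0),
    date_malform_rate = ifelse(n > 0, k_date / n, 0),
    code_malform_rate = ifelse(n > 0, k_code / n, 0),
    null_fields = list(basic_info = "sex"))
  r_th <- if (stats::sd(n) == 0 || (slope == 0 && sigma == 0)) NA_real_ else
    slope * stats::sd(n) / sqrt(slope^2 * stats::var(n) + sigma^2)
  attr(m, "theoretical_r") <- r_th
  attr(m, "targets") <- targets
  m
}

#' Generate an institutional-factors table for synthetic institutions
#'
#' `biospecimen_count` is set to each institution's basic-table record
#' count; the remaining eight survey factors (hospital level, staffing, IT
#' infrastructure, network tenure, beds, collection sites) are drawn from
#' plausible discrete distributions, independent of the error process.
#'
#' @param datasets Synthetic datasets (clean or corrupted).
#' @param seed Integer seed.
#' @return A tibble with `institution_id` and nine numeric factor columns.
#' @export
generate_factors <- function(datasets, seed = 1L) {
  set.seed(seed)
  k <- length(datasets)
  if (k < 3) dq_abort("need at least 3 institutions for factor analysis",
                      "dq_config_error")
  tibble::tibble(
    institution_id = unname(vapply(datasets, function(d) d$institution_id,
                                   character(1))),
    biospecimen_count = unname(vapply(datasets, function(d)
      nrow(d$tables$basic_info), integer(1))),
    hospital_level = sample(1:3, k, TRUE),
    dedicated_staff = sample(0:5, k, TRUE),
    non_specialist_staff = sample(0:10, k, TRUE),
    it_infrastructure_level = sample(1:5, k, TRUE),
    data_manager_count = sample(0:4, k, TRUE),
    years_in_network = sample(1:15, k, TRUE),
    bed_count = sample(seq(100, 2500, by = 50), k, TRUE),
    collection_sites = sample(1:6, k, TRUE))
}

#' Write synthetic datasets and ledger to disk
#'
#' Writes the per-institution CSV layout [read_dataset()] reads (one
#' sub-directory per institution) and, when a ledger is given,
#' `ledger.csv`.
#'
#' @param datasets List of `dq_dataset` objects.
#' @param out_dir Output directory.
#' @param ledger Optional ground-truth ledger tibble.
#' @return `out_dir`, invisibly.
#' @export
write_datasets <- function(datasets, out_dir, ledger = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in datasets) {
    write_dataset(ds, file.path(out_dir, ds$institution_id))
  }
  if (!is.null(ledger)) {
    utils::write.csv(ledger, file.path(out_dir, "ledger.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
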
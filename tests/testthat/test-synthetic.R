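test_that("clean generation is sound under both catalogs and reproducible", {
  cfg <- generator_config(n_institutions = 4, n_records = c(120, 80, 50, 3),
                          seed = 21)
  ds <- generate_clean(cfg)
  expect_length(ds, 4)
  expect_equal(vapply(ds, function(d) nrow(d$tables$basic_info), integer(1)),
               c(A = 120L, B = 80L, C = 50L, D = 3L))
  expect_equal(nrow(evaluate_catalog(build_prereview_catalog(), ds)$violations),
               0)
  expect_equal(nrow(evaluate_catalog(build_final_catalog(), ds)$violations),
               0)
  expect_identical(generate_clean(cfg), ds)
  # zero-record institutions are legal
  ds0 <- generate_clean(generator_config(2, c(3, 0), seed = 1))
  expect_equal(nrow(ds0[[2]]$tables$basic_info), 0)
})

test_that("generator and model configs validate their parameters", {
  expect_error(generator_config(0), class = "dq_config_error")
  expect_error(generator_config(2, c(-1, 5)), class = "dq_config_error")
  expect_error(generator_config(2, 5, institution_ids = c("A", "A")),
               class = "dq_config_error")
  expect_error(error_model(null_rate = 1.2), class = "dq_config_error")
  expect_error(error_model(duplicate_rate = -0.1), class = "dq_config_error")
})

test_that("a zero-rate model changes nothing and an excessive one refuses", {
  ds <- small_cohort(2, c(20, 10), seed = 31)
  inj <- inject_errors(ds, error_model(), seed = 1)
  expect_identical(inj$datasets, ds)
  expect_equal(nrow(inj$ledger), 0)
  # more cancer-flag nulls than eligible sites must fail loudly
  m <- error_model(null_rate = 0.9,
                   null_fields = list(disease_history = "DHCa"))
  expect_error(inject_errors(ds, m, seed = 1), class = "dq_injection_error")
})

test_that("each injection channel produces its characteristic defect", {
  ds <- small_cohort(1, 40, seed = 12)

  # five donor-identifier nulls: ledger says five, the engine finds five
  m <- error_model(null_rate = 5 / 40,
                   null_fields = list(basic_info = "KBN_Donor"))
  inj <- inject_errors(ds, m, seed = 2)
  expect_equal(inj$ledger$rule_id, "CMP-basic_info-KBN_Donor")
  expect_equal(inj$ledger$injected, 5L)
  vs <- evaluate_catalog(build_final_catalog(), inj$datasets)
  expect_equal(nrow(vs$violations), 5)
  expect_true(ledger_matches(vs, inj$ledger))

  # gram-entered weights exceed 2400 and trip the weight range rule
  m <- error_model(unit_error_rate = 4 / 40)
  inj <- inject_errors(ds, m, seed = 3)
  w <- as.numeric(inj$datasets[[1]]$tables$measurements$weight)
  expect_equal(sum(w > 2400, na.rm = TRUE), 4)
  vs <- evaluate_catalog(build_final_catalog(), inj$datasets)
  expect_identical(unique(vs$violations$rule_id),
                   "VLD-RNG-measurements-weight")
  expect_true(ledger_matches(vs, inj$ledger))

  # malformed birthdates shrink to 6 or 7 digits
  m <- error_model(date_malform_rate = 6 / 40)
  inj <- inject_errors(ds, m, seed = 4)
  b <- inj$datasets[[1]]$tables$basic_info$birthdate
  expect_equal(sum(nchar(b) %in% c(6, 7)), 6)

  # logic errors record a cancer type on a no-cancer-history record
  m <- error_model(logic_error_rate = 3 / 40)
  inj <- inject_errors(ds, m, seed = 5)
  dh <- inj$datasets[[1]]$tables$disease_history
  expect_equal(sum(dh$DHCa == "0" & dh$DHCa1 != "0", na.rm = TRUE), 3)
  vs <- evaluate_catalog(build_final_catalog(), inj$datasets)
  expect_identical(unique(vs$violations$rule_id),
                   "ACC-BR-02-cancer_type_implies_history")

  # duplicates copy an existing donor identifier
  m <- error_model(duplicate_rate = 2 / 40)
  inj <- inject_errors(ds, m, seed = 6)
  ids <- inj$datasets[[1]]$tables$basic_info$KBN_Donor
  expect_equal(sum(duplicated(ids)), 2)
  vs <- evaluate_catalog(build_final_catalog(), inj$datasets)
  expect_true(ledger_matches(vs, inj$ledger))
})

test_that("mixed-rate injection is recovered exactly from the ledger", {
  ds <- small_cohort(3, c(150, 90, 60), seed = 101)
  m <- error_model(null_rate = 0.02, date_malform_rate = 0.04,
                   code_malform_rate = 0.03, unit_error_rate = 0.02,
                   logic_error_rate = 0.02, duplicate_rate = 0.015)
  inj <- inject_errors(ds, m, seed = 102)
  vs <- evaluate_catalog(build_final_catalog(), inj$datasets)
  expect_true(ledger_matches(vs, inj$ledger))
  expect_equal(nrow(vs$violations), sum(inj$ledger$injected))
  # injection is reproducible from its seed
  inj2 <- inject_errors(ds, m, seed = 102)
  expect_identical(inj2$ledger, inj$ledger)
  expect_identical(inj2$datasets, inj$datasets)
})

test_that("per-institution rate vectors target individual institutions", {
  ds <- small_cohort(3, c(50, 50, 50), seed = 44)
  m <- error_model(date_malform_rate = c(0.1, 0, 0.04))
  inj <- inject_errors(ds, m, seed = 45)
  led <- inj$ledger
  expect_equal(led$injected[led$institution_id == "A"], 5L)
  expect_false("B" %in% led$institution_id)
  expect_equal(led$injected[led$institution_id == "C"], 2L)
})

test_that("biospecimen-driven error models expose their theoretical correlation", {
  counts <- seq(100, 475, by = 25)
  m <- error_model_from_biospecimens(counts, slope = 0.08, sigma = 4,
                                     seed = 9)
  r_th <- attr(m, "theoretical_r")
  expect_equal(r_th,
               0.08 * sd(counts) / sqrt(0.08^2 * var(counts) + 16))
  targets <- attr(m, "targets")
  expect_true(all(targets >= 0))
  # channel split conserves the target totals
  n <- as.numeric(counts)
  realized <- round(m$null_rate * n) + round(m$date_malform_rate * n) +
    round(m$code_malform_rate * n)
  expect_equal(realized, as.numeric(targets))
})

test_that("factor tables anchor biospecimen counts to the generated data", {
  ds <- small_cohort(3, c(40, 30, 20), seed = 61)
  fac <- generate_factors(ds, seed = 62)
  expect_equal(fac$biospecimen_count, c(40L, 30L, 20L))
  expect_setequal(setdiff(names(fac), "institution_id"),
                  c("biospecimen_count", "hospital_level", "dedicated_staff",
                    "non_specialist_staff", "it_infrastructure_level",
                    "data_manager_count", "years_in_network", "bed_count",
                    "collection_sites"))
  expect_identical(generate_factors(ds, seed = 62), fac)
  expect_error(generate_factors(ds[1:2], seed = 1),
               class = "dq_config_error")
})

test_that("synthetic datasets round-trip through the CSV reader", {
  ds <- small_cohort(2, c(15, 10), seed = 71)
  m <- error_model(null_rate = 0.05, date_malform_rate = 0.1)
  inj <- inject_errors(ds, m, seed = 72)
  dir <- withr::local_tempdir()
  write_datasets(inj$datasets, dir, ledger = inj$ledger)
  back <- lapply(c("A", "B"), function(i)
    read_dataset(file.path(dir, i), default_schema(), institution_id = i))
  expect_identical(back[[1]]$tables, inj$datasets[[1]]$tables)
  expect_identical(back[[2]]$tables, inj$datasets[[2]]$tables)
  led <- utils::read.csv(file.path(dir, "ledger.csv"))
  expect_equal(sum(led$injected), sum(inj$ledger$injected))
})
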
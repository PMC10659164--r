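# biobankDQ

Rule-based data-quality assessment for multicenter biobank registries.

Biobank networks pool clinical-epidemiological records from many unit
biobanks, each exporting tables (basic donor information, physical
measurements, laboratory results, disease history, lifestyle questionnaire)
that were often compiled by hand. The result is a characteristic mix of
defects: missing values in essential fields, malformed dates (`660307`,
`1962318`), undefined diagnostic codes (`?C21.49`), weights entered in grams
instead of kilograms, cancer types recorded for donors whose history says
"no cancer", and duplicated donor identifiers. biobankDQ is for data
managers and informatics researchers who need to quantify these defects per
institution, compare sites, and relate error burdens to institutional
characteristics.

## What it implements

The package decomposes quality into four DQ4HEALTH-style dimensions, each
checked by declarative rules with severity **E** (error: must be corrected
before loading) or **W** (warning: may be loaded):

* **completeness** — required fields are non-null;
* **validity** — values conform to plausible ranges (`range`) and to
  formats/code sets (`format`);
* **accuracy** — temporal ordering (`timeline`, e.g. birthdate ≤ receipt
  date) and cross-field business logic (`business_rule`, e.g. cancer
  history ⇒ cancer type present);
* **uniqueness** — donor identifiers are not duplicated.

`build_prereview_catalog()` constructs the full 128-rule catalog over the
built-in 54-field registry schema; `apply_expert_review()` applies the
shipped expert-review decision list (drops and severity reassignments) to
obtain the final 104-rule model. `evaluate_catalog()` runs a catalog over
per-institution datasets and emits one violation per failing record, with
strict precedence so a single defective cell is counted in exactly one
dimension (nulls belong to completeness, unparseable values to format,
implausible values to range).

On top of the violation stream the package computes the reporting surfaces
of a multicenter assessment: the per-institution severity table
(total/E/W), the per-institution dimension table, the headline error rate

```
error rate = total violations / (records × rules)
```

institution profiles (omission-dominant vs mapping-dominant sites, from the
completeness/validity balance), chi-square tests of independence on the
count tables, and Pearson correlations between error counts and
institutional factors such as the number of biospecimens collected.

Because real registry data is access-restricted, the package ships a
first-class synthetic generator: `generate_clean()` emulates a
16-institution network whose output passes every rule, and
`inject_errors()` corrupts it with the defect classes above at controlled
rates while writing a ground-truth ledger. Injection sites are chosen so
each corruption trips exactly one rule of the final catalog, which makes
recovery testable: detected per-rule, per-institution counts must equal the
ledger *exactly*.

## Worked example

```r
library(biobankDQ)

cfg   <- generator_config(n_institutions = 4, n_records = 500, seed = 2024)
clean <- generate_clean(cfg)
model <- error_model(null_rate = 0.01, date_malform_rate = 0.02,
                     code_malform_rate = 0.01, unit_error_rate = 0.005,
                     logic_error_rate = 0.005, duplicate_rate = 0.005)
inj     <- inject_errors(clean, model, seed = 2025)
catalog <- build_final_catalog()
vs      <- evaluate_catalog(catalog, inj$datasets)

severity_table(vs)
#> # A tibble: 4 × 4
#>   institution_id total errors warnings
#> 1 A                 41     31       10
#> 2 B                 41     31       10
#> 3 C                 41     31       10
#> 4 D                 41     31       10

dimension_table(vs)
#> # A tibble: 4 × 5
#>   institution_id completeness validity accuracy uniqueness
#> 1 A                        20       17        2          2
#> ...

error_rate(nrow(vs$violations), 2000, length(catalog))$percent
#> [1] "0.08%"
```

Each institution received `round(rate × 500)` corruptions per channel, so
the four sites tie at 41 violations: 20 completeness (nulls in the donor
ID, sex, cancer-history and drinking flags), 17 validity (10 malformed
birthdates, 5 undefined diagnosis codes, 2 gram-scale weights caught by the
weight range rule), 2 accuracy (cancer type without history) and 2
duplicate donor IDs. The error rate divides the 164 violations by
2,000 records × 104 rules. Comparing detected counts with the injection
ledger:

```r
max(abs(merge(detected, inj$ledger)$n - merge(detected, inj$ledger)$injected))
#> [1] 0
```

and the flagged values are the injected ones verbatim:

```r
vs$violations[vs$violations$dimension == "validity", ][1:3, ]
#>                        rule_id   record_key observed_value
#> 1 VLD-FMT-basic_info-birthdate KBN-A-000016         790522
#> 2 VLD-FMT-basic_info-birthdate KBN-A-000059        1990030
#> 3 VLD-FMT-basic_info-birthdate KBN-A-000088         760704
```

A thin command-line front end over the same functions lives at
`inst/cli/biobank-dq.R` (subcommands `catalog`, `generate`, `inspect`,
`validate`, `report`, `stats`).

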
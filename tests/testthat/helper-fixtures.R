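# Shared fixtures: a small synthetic cohort and a toy schema for predicate
# unit tests. Everything is generated in code; nothing is read from disk.

small_cohort <- function(n_institutions = 3, n_records = c(120, 80, 50),
                         seed = 42) {
  generate_clean(generator_config(n_institutions = n_institutions,
                                  n_records = n_records, seed = seed))
}

# Single-institution dataset over the default schema with a chosen cell
# edited, for targeted predicate checks.
edited_dataset <- function(table, field, row, value, n = 30, seed = 99) {
  ds <- generate_clean(generator_config(n_institutions = 1, n_records = n,
                                        seed = seed,
                                        institution_ids = "Z"))[[1]]
  ds$tables[[table]][[field]][row] <- value
  ds
}

# Detected per-(institution, rule) counts of a violation set, as a data
# frame directly comparable with a ground-truth ledger.
detected_counts <- function(vs) {
  v <- vs$violations
  if (!nrow(v)) {
    return(data.frame(institution_id = character(), rule_id = character(),
                      n = integer()))
  }
  stats::aggregate(list(n = rep(1L, nrow(v))),
                   v[c("institution_id", "rule_id")], sum)
}

# TRUE iff detected counts equal the ledger exactly (zero elsewhere).
ledger_matches <- function(vs, ledger) {
  det <- detected_counts(vs)
  m <- merge(det, as.data.frame(ledger),
             by = c("institution_id", "rule_id"), all = TRUE)
  m$n[is.na(m$n)] <- 0L
  m$injected[is.na(m$injected)] <- 0L
  all(m$n == m$injected)
}

# Independent brute-force chi-square of independence: explicit margins,
# expected counts and sum, no library call.
brute_chisq <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  list(statistic = sum((m - e)^2 / e),
       dof = (nrow(m) - 1) * (ncol(m) - 1))
}
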
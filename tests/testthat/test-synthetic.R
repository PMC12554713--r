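test_that("generator configs validate probability maps and require a seed", {
  expect_error(synthetic_config(n_reports = 10), "seed")
  expect_error(synthetic_config(seed = 1, drug_marginals = c(A = 0.7, B = 0.6)),
               "drug_marginals")
  expect_error(synthetic_config(seed = 1, event_marginals = c(OSTEOPENIA = 1.2)),
               "event_marginals")
  expect_error(synthetic_config(seed = 1,
                                signal_multipliers = data.frame(
                                  drug = "X", pt = "OSTEOPENIA", multiplier = -1)),
               "multipliers")
  expect_error(synthetic_config(seed = 1,
                                event_marginals = c(NOT_A_REAL_PT = 0.001)),
               "hierarchy")
})

test_that("identical config and seed produce byte-identical files and leave the RNG untouched", {
  cfg <- synthetic_config(n_reports = 1000, seed = 7)
  d1 <- file.path(tempdir(), "sd1"); d2 <- file.path(tempdir(), "sd2")
  set.seed(999); before <- runif(1)
  generate_faers(cfg, d1)
  set.seed(999); expect_equal(runif(1), before)   # global RNG state restored
  generate_faers(cfg, d2)
  for (f in c("DEMO.txt", "DRUG.txt", "REAC.txt", "OUTC.txt", "ground_truth.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generated files ingest with zero malformed-line warnings and match the in-memory path", {
  cfg <- synthetic_config(n_reports = 1500, seed = 8, duplicate_rate = 0.08)
  dir <- file.path(tempdir(), "sdin")
  generate_faers(cfg, dir)
  for (kind in c("demo", "drug", "reac", "outc")) {
    tab <- read_faers_table(file.path(dir, paste0(toupper(kind), ".txt")), kind)
    expect_equal(attr(tab, "n_malformed"), 0L)
    expect_length(attr(tab, "warnings"), 0L)
  }
  from_files <- ingest_faers(dir)
  in_memory <- synthetic_cases(cfg)
  expect_setequal(from_files$demo$primaryid, in_memory$demo$primaryid)
  expect_equal(from_files$ingest$duplicates_removed,
               in_memory$ingest$duplicates_removed)
  unlink(dir, recursive = TRUE)
})

test_that("deduplication removes the injected duplicate versions at the configured rate", {
  cfg <- synthetic_config(n_reports = 10000, seed = 9, duplicate_rate = 0.1)
  cases <- synthetic_cases(cfg)
  n_removed <- cases$ingest$duplicates_removed
  # binomial 3 sigma around n * rate
  expect_lt(abs(n_removed - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_equal(nrow(cases$demo), 10000L)
  # every survivor is the latest version: no caseid appears twice
  expect_equal(anyDuplicated(cases$demo$caseid), 0L)
})

test_that("an injected multiplier reproduces its configured relative reporting rate", {
  mult <- data.frame(drug = "GABAPENTIN", pt = "OSTEOPENIA", multiplier = 3)
  cfg <- synthetic_config(n_reports = 50000, seed = 10,
                          signal_multipliers = mult)
  truth <- expected_table(cfg, "GABAPENTIN", "OSTEOPENIA")
  cases <- synthetic_cases(cfg)
  t <- build_contingency(cases, "GABAPENTIN", "OSTEOPENIA", "all_ingested")
  emp_prr <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
  # 3 sigma on the log relative rate (delta method on the 2x2)
  se_log <- sqrt(1 / t$a - 1 / (t$a + t$b) + 1 / t$c - 1 / (t$c + t$d))
  expect_lt(abs(log(emp_prr) - log(truth$prr)), 3 * se_log)
  # and the configured multiplier is close to the implied relative rate
  expect_equal(truth$prr, 3, tolerance = 0.05)
})

test_that("expected tables are exact for the null model and analytic limits", {
  cfg <- synthetic_config(n_reports = 1000, seed = 12)
  for (dg in c("GABAPENTIN", "PHENYTOIN", "OTHER DRUG 01")) {
    et <- expected_table(cfg, dg, "OSTEOPENIA")
    expect_equal(sum(et$props), 1, tolerance = 1e-12)
    expect_equal(et$ror, 1, tolerance = 1e-9)     # no multiplier: null ROR
    expect_equal(et$prr, 1, tolerance = 1e-9)
  }
  # rare pair: expected PRR approaches the multiplier as marginals vanish
  m <- 5
  cfg2 <- synthetic_config(
    n_reports = 1000, seed = 13,
    drug_marginals = c(ESLICARBAZEPINE = 1e-4),
    event_marginals = c(OSTEOPENIA = 1e-5),
    signal_multipliers = data.frame(drug = "ESLICARBAZEPINE",
                                    pt = "OSTEOPENIA", multiplier = m))
  et2 <- expected_table(cfg2, "ESLICARBAZEPINE", "OSTEOPENIA")
  expect_equal(et2$prr, m, tolerance = 0.01)
})

test_that("stratum-restricted multipliers shift only the targeted stratum", {
  mult <- data.frame(drug = "GABAPENTIN", pt = "OSTEOPENIA", multiplier = 5,
                     sex = "F")
  cfg <- synthetic_config(n_reports = 40000, seed = 14,
                          signal_multipliers = mult)
  cases <- synthetic_cases(cfg)
  d <- cases$demo
  fem <- subset_cases(cases, d$primaryid[d$sex == "F"])
  mal <- subset_cases(cases, d$primaryid[d$sex == "M"])
  tf <- build_contingency(fem, "GABAPENTIN", "OSTEOPENIA", "all_ingested")
  tm <- build_contingency(mal, "GABAPENTIN", "OSTEOPENIA", "all_ingested")
  prr_f <- (tf$a / (tf$a + tf$b)) / (tf$c / (tf$c + tf$d))
  prr_m <- (tm$a / (tm$a + tm$b)) / (tm$c / (tm$c + tm$d))
  # female stratum sees the multiplier (3 sigma around 5), male stays null
  se_f <- sqrt(1 / tf$a - 1 / (tf$a + tf$b) + 1 / tf$c - 1 / (tf$c + tf$d))
  se_m <- sqrt(1 / max(tm$a, 0.5) - 1 / (tm$a + tm$b) +
                 1 / tm$c - 1 / (tm$c + tm$d))
  expect_lt(abs(log(prr_f) - log(5)), 3 * se_f)
  expect_lt(abs(log(max(prr_m, 0.1))), 3 * se_m)
})

test_that("demographic marginals match their configured proportions", {
  cfg <- synthetic_config(n_reports = 20000, seed = 15)
  cases <- synthetic_cases(cfg)
  d <- cases$demo
  p_f <- mean(d$sex == "F")
  expect_lt(abs(p_f - cfg$sex_probs[["F"]]), 3 * sqrt(0.25 / 20000) + 0.01)
  p_missing_age <- mean(is.na(d$age_years))
  expect_lt(abs(p_missing_age - cfg$age_missing_rate), 0.02)
})
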
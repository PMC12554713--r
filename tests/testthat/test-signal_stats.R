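test_that("contingency tables are built from PS drugs and target PTs with set semantics", {
  cases <- six_case_fixture()
  t <- build_contingency(cases, "GABAPENTIN", "OSTEOPENIA", "all_ingested")
  expect_equal(c(t$a, t$b, t$c, t$d), c(2, 1, 1, 2))

  # a drug listed twice as PS still counts once
  demo <- demo_rows(1:2, c("C1", "C2"), 20200101)
  drugs <- drug_rows(c(1, 1, 2), c("GABAPENTIN", "NEURONTIN", "OTHERX"))
  cases2 <- fixture_cases(demo, drugs, reac_rows(1, "OSTEOPENIA"))
  t2 <- build_contingency(cases2, "GABAPENTIN", "OSTEOPENIA", "all_ingested")
  expect_equal(t2$a, 1)

  # absent drug: empty row, background intact
  t3 <- build_contingency(cases, "PHENYTOIN", "OSTEOPENIA", "all_ingested")
  expect_equal(c(t3$a, t3$b), c(0, 0))
  expect_equal(t3$c + t3$d, t3$n)

  # an SS role never assigns the case to the drug row
  cases4 <- fixture_cases(demo_rows(1, "C1", 20200101),
                          drug_rows(1, "PHENYTOIN", role_cod = "SS"),
                          reac_rows(1, "OSTEOPENIA"))
  t4 <- build_contingency(cases4, "PHENYTOIN", "OSTEOPENIA", "all_ingested")
  expect_equal(t4$a + t4$b, 0)
})

test_that("ROR and its Wald interval match the closed form, with 0.5 correction on zero cells", {
  r <- ror_stats(contingency_table(10, 90, 100, 9900))
  expect_equal(r$ror, 11)
  expect_equal(r$ror_lo, 11 * exp(-1.96 * sqrt(0.121212121212)), tolerance = 1e-9)
  expect_equal(r$ror_hi, 11 * exp(+1.96 * sqrt(0.121212121212)), tolerance = 1e-9)

  r5 <- ror_stats(contingency_table(5, 5, 5, 5))
  expect_equal(r5$ror, 1)
  expect_equal(r5$ror_lo * r5$ror_hi, 1, tolerance = 1e-12)  # symmetric about 1

  rz <- ror_stats(contingency_table(0, 10, 10, 100))
  expect_equal(rz$ror, (0.5 * 100.5) / (10.5 * 10.5))
})

test_that("PRR and Yates chi-square match the closed form; zero margins are flagged", {
  p <- prr_stats(contingency_table(10, 90, 100, 9900))
  expect_equal(p$prr, 10)
  expect_equal(p$chi2,
               10100 * (abs(10 * 9900 - 90 * 100) - 10100 / 2)^2 /
                 (100 * 10000 * 110 * 9990), tolerance = 1e-12)

  p5 <- prr_stats(contingency_table(5, 5, 5, 5))
  expect_equal(p5$prr, 1)
  expect_equal(p5$chi2, 0)   # floored under the continuity correction

  pz <- prr_stats(contingency_table(2, 0, 0, 0))
  expect_true(is.na(pz$prr) && is.na(pz$chi2))
  expect_true(attr(pz, "undefined"))
})

test_that("shrunken IC and its credibility bound match the closed form", {
  i <- ic_stats(contingency_table(10, 90, 100, 9900))
  expect_equal(i$expected, 110 * 100 / 10100)
  expect_equal(i$ic, log2(10.5 / (110 * 100 / 10100 + 0.5)), tolerance = 1e-12)
  expect_equal(i$ic025, i$ic - 3.3 / sqrt(10.5) - 2 / 10.5^1.5, tolerance = 1e-12)

  # degenerate empty-margin table shrinks to the null center
  expect_equal(ic_stats(contingency_table(0, 0, 0, 5))$ic, 0)
})

test_that("Fisher p-values are exact and symmetric", {
  expect_equal(fisher_p(contingency_table(5, 5, 5, 5)), 1)
  expect_equal(fisher_p(contingency_table(10, 0, 0, 10)), 2 / choose(20, 10),
               tolerance = 1e-12)
  t1 <- contingency_table(3, 7, 9, 21)
  t2 <- contingency_table(9, 21, 3, 7)   # row swap leaves Fisher unchanged
  expect_equal(fisher_p(t1), fisher_p(t2), tolerance = 1e-12)
})

test_that("Bonferroni adjustment scales, caps at 1 and never decreases p", {
  expect_equal(bonferroni(0.01, 12), 0.12)
  expect_equal(bonferroni(0.2, 12), 1)
  expect_equal(bonferroni(0.3, 1), 0.3)   # m = 1 is the identity
  set.seed(1)
  p <- runif(50)
  adj <- bonferroni(p, 50)
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_false(is.unsorted(adj[order(p)]))   # order-preserving (ties at the cap)
  expect_error(bonferroni(c(0.1, 0.2), 1))
})

test_that("ROR obeys its reciprocal and transpose symmetries", {
  set.seed(11)
  for (k in 1:50) {
    cl <- sample(1:40, 4, TRUE)
    r <- ror_stats(contingency_table(cl[1], cl[2], cl[3], cl[4]))
    rinv <- ror_stats(contingency_table(cl[2], cl[1], cl[4], cl[3]))
    rtr <- ror_stats(contingency_table(cl[4], cl[3], cl[2], cl[1]))
    expect_equal(r$ror, 1 / rinv$ror, tolerance = 1e-12)
    expect_equal(r$ror, rtr$ror, tolerance = 1e-12)
  }
})

test_that("PRR approaches ROR for rare events", {
  # as the event becomes rare in both rows the two measures agree
  rel <- vapply(c(1e3, 1e4, 1e5, 1e6), function(b) {
    t <- contingency_table(3, b, 7, 2 * b)
    abs(prr_stats(t)$prr - ror_stats(t)$ror) / ror_stats(t)$ror
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[length(rel)], 1e-3)
})

test_that("IC025 is strictly below IC and shrinkage weakens with doubled counts", {
  set.seed(12)
  for (k in 1:50) {
    cl <- sample(0:30, 4, TRUE)
    if (sum(cl) == 0) next
    i <- ic_stats(contingency_table(cl[1], cl[2], cl[3], cl[4]))
    expect_lt(i$ic025, i$ic)
  }
  # doubling all cells moves the shrunken ratio toward the raw O/E
  t1 <- ic_stats(contingency_table(4, 16, 20, 160))
  t2 <- ic_stats(contingency_table(8, 32, 40, 320))
  raw <- log2(4 / ic_stats(contingency_table(4, 16, 20, 160))$expected)
  expect_gt(abs(t1$ic - raw), abs(t2$ic - raw))
})

test_that("positivity classification applies the any-of-four rule behind a minimum-count gate", {
  th <- default_thresholds()
  # a lower CI bound just above 1 is enough (ROR route)
  v <- classify_signal(ror_lo = 1.18, prr = 2, chi2 = 6.95, ic025 = 0.16,
                       ebgm05 = 1.18, a = 14, thresholds = th)
  expect_true(v$ror_pos && v$overall)
  # the count gate blocks otherwise-positive pairs
  v2 <- classify_signal(ror_lo = 5, prr = 10, chi2 = 50, ic025 = 2,
                        ebgm05 = 4, a = 2, thresholds = th)
  expect_false(v2$min_case_ok || v2$overall)
  # nothing fires: negative
  v3 <- classify_signal(ror_lo = 0.8, prr = 1, chi2 = 1, ic025 = -0.5,
                        ebgm05 = 1, a = 10, thresholds = th)
  expect_false(v3$overall)
  # undefined statistics count as negative, not as errors
  v4 <- classify_signal(ror_lo = NA, prr = NA, chi2 = NA, ic025 = 0.2,
                        ebgm05 = NA, a = 10, thresholds = th)
  expect_true(v4$ic_pos && v4$overall)
  expect_false(v4$prr_pos)
  # "all" rule requires all four methods
  th_all <- th; th_all$rule <- "all"
  v5 <- classify_signal(ror_lo = 1.2, prr = 3, chi2 = 10, ic025 = 0.5,
                        ebgm05 = 1.5, a = 10, thresholds = th_all)
  expect_false(v5$overall)
})

test_that("classification is monotone in the case count", {
  th <- default_thresholds()
  overall <- vapply(1:10, function(a)
    classify_signal(1.5, 3, 10, 0.5, 3, a, th)$overall, logical(1))
  expect_true(all(diff(overall) >= 0))   # never flips true -> false as a grows
})
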
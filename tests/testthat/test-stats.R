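test_that("contingency tables are built from carrier counts and group sizes", {
  ds <- toy_dataset()
  t <- build_contingency(ds, snp_barcode(c(1, 2), c(3, 3)))
  expect_equal(unlist(t[c("a", "b", "c", "d")]),
               c(a = 2, b = 1, c = 1, d = 2))
  # margins equal the group sizes
  expect_equal(t$a + t$c, group_sizes(ds)[["n_high"]])
  expect_equal(t$b + t$d, group_sizes(ds)[["n_low"]])
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
})

test_that("odds ratio and its transformations behave", {
  expect_equal(odds_ratio(contingency_table(10, 10, 10, 10)), 1)
  set.seed(10)
  for (i in 1:25) {
    t <- random_contingency()
    or <- odds_ratio(t)
    # swapping rows and columns simultaneously leaves OR unchanged
    expect_equal(odds_ratio(contingency_table(t$d, t$c, t$b, t$a)), or)
    # swapping only rows inverts it and mirrors the CI
    inv <- contingency_table(t$c, t$d, t$a, t$b)
    expect_equal(odds_ratio(inv), 1 / or)
    ci <- woolf_ci(t)
    ci_inv <- woolf_ci(inv)
    expect_equal(unname(ci_inv), unname(rev(1 / ci)))
    # CI contains the point estimate
    expect_true(ci[["low"]] <= or && or <= ci[["high"]])
  }
  expect_error(odds_ratio(contingency_table(5, 0, 5, 5)), "haldane")
  expect_equal(odds_ratio(contingency_table(5, 0, 5, 5), haldane = TRUE),
               (5.5 * 5.5) / (0.5 * 5.5))
})

test_that("Woolf CI narrows as counts scale and collapses as level -> 0", {
  t1 <- contingency_table(30, 18, 59, 75)
  t4 <- contingency_table(120, 72, 236, 300)
  w <- function(ci) log(ci[["high"]]) - log(ci[["low"]])
  expect_lt(w(woolf_ci(t4)), w(woolf_ci(t1)))
  tiny <- woolf_ci(t1, level = 1e-12)
  expect_equal(unname(tiny), rep(odds_ratio(t1), 2), tolerance = 1e-5)
})

test_that("closed-form chi-square agrees with the generic O/E statistic", {
  set.seed(11)
  for (i in 1:25) {
    t <- random_contingency()
    ours <- pearson_chi2(t)
    ref <- suppressWarnings(stats::chisq.test(
      matrix(c(t$a, t$c, t$b, t$d), 2), correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
    yates <- suppressWarnings(stats::chisq.test(
      matrix(c(t$a, t$c, t$b, t$d), 2), correct = TRUE))
    expect_equal(pearson_chi2(t, yates = TRUE)$statistic,
                 unname(yates$statistic))
  }
  # perfectly proportional table
  flat <- pearson_chi2(contingency_table(10, 20, 5, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(pearson_chi2(contingency_table(0, 0, 5, 5)), "margin")
})

test_that("post-hoc power has its analytic limits and monotonicity", {
  flat <- contingency_table(10, 20, 5, 10)  # chi2 = 0
  expect_equal(posthoc_power(flat, alpha = 0.05), 0.05)
  expect_equal(posthoc_power(flat, alpha = 0.2), 0.2)
  # power grows with the observed statistic
  tabs <- list(contingency_table(12, 10, 77, 83),
               contingency_table(20, 10, 69, 83),
               contingency_table(30, 10, 59, 83),
               contingency_table(40, 10, 49, 83))
  pows <- vapply(tabs, posthoc_power, numeric(1))
  expect_true(all(diff(pows) > 0))
  # large effect: power near 1
  expect_gt(posthoc_power(contingency_table(80, 5, 9, 88)), 0.999)
  # independent check against direct noncentral integration
  t <- contingency_table(30, 18, 59, 75)
  lam <- pearson_chi2(t)$statistic
  crit <- qchisq(0.95, 1)
  num <- integrate(function(x) dchisq(x, 1, ncp = lam), crit, Inf)$value
  expect_equal(posthoc_power(t), num, tolerance = 1e-6)
})

test_that("evaluate_barcodes assembles the full per-barcode report row", {
  ds <- dichotomize_by_mean(generate_dataset(synthetic_spec(seed = 4)))
  res <- evaluate_barcodes(ds, list(snp_barcode(c(1, 4), c(3, 3)),
                                    snp_barcode(c(2, 5), c(1, 2))))
  expect_identical(nrow(res), 2L)
  expect_true(all(c("k", "snp_names", "genotype_codes", "n_high_match",
                    "n_low_match", "difference", "chi2", "p_value",
                    "odds_ratio", "ci_low", "ci_high", "power",
                    "p_bonferroni") %in% names(res)))
  expect_identical(res$snp_names[1], "rs1130233,rs41735")
  expect_equal(res$difference, res$n_high_match - res$n_low_match)
  expect_equal(res$p_bonferroni, pmin(res$p_value * 2, 1))
})
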
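test_that("END rule instances and validation", {
  t1 <- nihss_trajectory(4, 4, 5, 6, 4)
  expect_true(classify_end(t1))                       # baseline < 6, delta 2
  expect_false(classify_end(t1, "general-delta4"))
  t2 <- nihss_trajectory(10, 10, 11, 13, 9)
  expect_false(classify_end(t2))                      # baseline >= 6, delta 3
  t3 <- nihss_trajectory(5, 5, 5, 5, 5)
  expect_false(classify_end(t3))
  expect_false(classify_end(t3, "general-delta4"))
  t4 <- nihss_trajectory(10, 10, 12, 14, 10)
  expect_true(classify_end(t4))                       # delta 4 at baseline >= 6
  expect_true(classify_end(t4, "general-delta4"))
  expect_error(nihss_trajectory(43, 0, 0, 0, 0), class = "csmri_parameter_error")
  expect_error(nihss_trajectory(3.5, 0, 0, 0, 0), class = "csmri_parameter_error")
  expect_error(classify_end(list(baseline = -1, h24 = 3)),
               class = "csmri_parameter_error")
})

test_that("proportions reproduce the printed worked-example values", {
  expect_equal(proportion_pct(36, 196), 18.37)     # printed as 18.36
  expect_equal(proportion_pct(30, 36), 83.33)
  expect_equal(proportion_pct(28, 36), 77.78)
  expect_equal(proportion_pct(0, 57), 0)
  expect_error(proportion_pct(1, 0), class = "csmri_parameter_error")
  expect_error(proportion_pct(5, 4), class = "csmri_parameter_error")
})

test_that("odds ratio: null table, printed-count table, scale invariance, correction", {
  expect_equal(odds_ratio(contingency_2x2(7, 7, 7, 7))$or, 1)
  tab <- contingency_2x2(30, 6, 74, 77)
  o <- odds_ratio(tab)
  expect_equal(o$or, (30 * 77) / (6 * 74))
  expect_false(o$corrected)
  expect_true(o$ci_low < o$or && o$or < o$ci_high)
  o2 <- odds_ratio(contingency_2x2(60, 12, 148, 154))
  expect_equal(o2$or, o$or)
  expect_lt(o2$ci_high - o2$ci_low, o$ci_high - o$ci_low)   # doubling narrows CI
  oz <- odds_ratio(contingency_2x2(5, 0, 3, 9))
  expect_true(oz$corrected)
  expect_equal(oz$or, (5.5 * 9.5) / (0.5 * 3.5))
  expect_error(odds_ratio(contingency_2x2(0, 0, 3, 9)), class = "csmri_parameter_error")
  expect_error(odds_ratio(tab, ci_level = 1.2), class = "csmri_parameter_error")
})

test_that("chi-square matches the direct formula and stats::chisq.test", {
  prop <- contingency_2x2(10, 20, 5, 10)   # perfectly proportional
  cs0 <- chi_square_test(prop)
  expect_equal(cs0$statistic, 0)
  expect_equal(cs0$p, 1)

  tab <- contingency_2x2(30, 6, 74, 77)
  cs <- chi_square_test(tab)
  O <- matrix(c(30, 74, 6, 77), 2, 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(cs$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  ref <- suppressWarnings(stats::chisq.test(O, correct = FALSE))
  expect_equal(cs$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(cs$p, ref$p.value, tolerance = 1e-12)
  # row swap leaves the statistic unchanged
  swapped <- chi_square_test(contingency_2x2(74, 77, 30, 6))
  expect_equal(swapped$statistic, cs$statistic, tolerance = 1e-12)
  # Yates flag against R's corrected test
  refy <- suppressWarnings(stats::chisq.test(O, correct = TRUE))
  expect_equal(chi_square_test(tab, yates = TRUE)$statistic, unname(refy$statistic),
               tolerance = 1e-12)
  expect_true(chi_square_test(contingency_2x2(1, 1, 1, 30))$small_expected)
})

test_that("IRLS logistic fit agrees with glm and the closed-form single-covariate OR", {
  ch <- simulate_cohort(cohort_spec(n_deterioration = 100, n_control = 400, seed = 8),
                        mechanism = "logistic")
  fit <- fit_logistic(ch, c("nihss_baseline", "occlusion"))
  g <- stats::glm(end_label ~ nihss_baseline + occlusion, stats::binomial, data = ch)
  expect_equal(fit$beta, unname(stats::coef(g)), tolerance = 1e-7)
  expect_equal(fit$se, unname(sqrt(diag(stats::vcov(g)))), tolerance = 1e-4)
  expect_equal(fit$wald, (fit$beta / fit$se)^2)

  # saturated one-covariate model: exp(B) equals the 2x2 odds ratio
  x <- ch$occlusion == 1; y <- ch$end_label
  tab <- contingency_2x2(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
  f1 <- fit_logistic(ch, "occlusion")
  expect_equal(f1$or[f1$term == "occlusion"], odds_ratio(tab)$or, tolerance = 1e-6)

  expect_error(fit_logistic(ch[1:15, ], c("nihss_baseline", "occlusion")),
               class = "csmri_parameter_error")
})

test_that("separation is flagged, not raised", {
  df <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                   end_label = c(rep(FALSE, 20), rep(TRUE, 20)))
  fit <- fit_logistic(df, "x")
  expect_false(fit$estimable[fit$term == "x"])
})

test_that("null covariate has near-zero estimated effect at n = 2000", {
  betas <- vapply(1:10, function(s) {
    ch <- simulate_cohort(cohort_spec(385, 1615, seed = s), mechanism = "logistic")
    set.seed(s)
    ch$noise_cov <- rnorm(nrow(ch))
    fit <- fit_logistic(ch, c("nihss_baseline", "occlusion", "noise_cov"))
    fit$beta[fit$term == "noise_cov"]
  }, numeric(1))
  expect_lt(abs(mean(betas)), 0.15)
})

test_that("univariate screening keeps true effects and drops pure noise", {
  ch <- simulate_cohort(cohort_spec(385, 1615, seed = 3), mechanism = "logistic")
  set.seed(42)
  ch$noise_cov <- rnorm(nrow(ch))
  kept <- screen_covariates(ch, c("nihss_baseline", "occlusion", "noise_cov"))
  expect_true(all(c("nihss_baseline", "occlusion") %in% kept))
})

test_that("worked-example report reproduces every printed count-backed percentage", {
  rep <- worked_example_report()
  e <- rep$entries
  # every non-flagged entry matches its printed value at the printed precision
  expect_true(all(e$match[!nzchar(e$flag)]))
  # flagged mismatches stay within 0.05 of the printed value
  off <- e[!e$match, ]
  expect_true(all(abs(off$computed_pct - off$printed_pct) <= 0.05))
  expect_true(all(nzchar(off$flag)))
  # spot values
  expect_equal(e$computed_pct[e$id == "det_male"], 77.78)
  expect_equal(e$computed_pct[e$id == "ctrl_occlusion"], 49.01)
  expect_equal(e$computed_pct[e$id == "ctrl_ica"], 6.62)
  expect_equal(e$computed_pct[e$id == "det_standard_dose"], 58.33)
  # occlusion table statistics recomputed from counts
  expect_equal(rep$occlusion$or$or, (30 * 77) / (6 * 74))
  expect_gt(rep$occlusion$chi_square$statistic, 0)
  # the printed multivariate inconsistencies are carried with flags
  expect_true(nzchar(rep$logistic_printed$nihss$flag))
  # serialization
  jpath <- withr::local_tempfile(fileext = ".json")
  mpath <- withr::local_tempfile(fileext = ".md")
  write_worked_example(rep, jpath, "json")
  write_worked_example(rep, mpath, "markdown")
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(nrow(back$entries), nrow(e))
  expect_true(any(grepl("Occlusion table", readLines(mpath))))
})
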
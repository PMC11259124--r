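# Odds ratios, Woolf intervals, pooling, descriptives and the model object.

test_that("cross-product odds ratios match hand-computed values", {
  expect_equal(round(odds_ratio(c(36, 2330, 16, 22432)), 2), 21.66)
  expect_equal(round(odds_ratio(c(36, 2330, 39, 38710)), 2), 15.34)
  expect_equal(odds_ratio(c(1, 1, 1, 1)), 1)
  expect_warning(or0 <- odds_ratio(contingency_2x2(0, 10, 0, 10)), "zero cell")
  expect_true(is.nan(or0))
  expect_equal(odds_ratio(c(0, 10, 0, 10), correction = TRUE), 1)
})

test_that("Woolf intervals reproduce closed-form bounds and symmetry", {
  ci <- woolf_ci(c(36, 2330, 16, 22432))
  expect_equal(round(unname(ci), 2), c(12.00, 39.10))
  ci2 <- woolf_ci(c(36, 2330, 8, 5988))
  expect_equal(round(unname(ci2), 2), c(5.37, 24.92))
  # symmetric table: interval symmetric about 1 on the log scale
  cis <- woolf_ci(c(7, 7, 7, 7))
  expect_equal(log(cis[["low"]]), -log(cis[["high"]]))
  expect_error(woolf_ci(c(0, 5, 3, 4)), "positive")
  # closed form with the full-precision quantile
  z <- qnorm(0.975)
  ci3 <- woolf_ci(c(12, 88, 4, 96), z = z)
  se <- sqrt(1/12 + 1/88 + 1/4 + 1/96)
  expect_equal(unname(ci3),
               exp(log((12 * 96) / (88 * 4)) + c(-1, 1) * z * se))
})

test_that("carrier frequencies render at the printed precision", {
  expect_equal(carrier_frequency(36, 2366, digits = 1), 1.5)
  expect_equal(carrier_frequency(16, 22448, digits = 2), 0.07)
  expect_equal(carrier_frequency(0, 10), 0)
  expect_error(carrier_frequency(1, 0), "positive")
})

test_that("pooling control panels sums counts element-wise", {
  p <- pool_controls(list(c(22448, 16), c(10305, 15), c(5996, 8)))
  expect_equal(p$n, 38749)
  expect_equal(p$carriers, 39)
  expect_equal(carrier_frequency(p$carriers, p$n, digits = 2), 0.10)
  one <- pool_controls(list(c(100, 2)))
  expect_equal(c(one$n, one$carriers), c(100, 2))
  # manifest form
  m <- data.frame(sample_id = 1:4, carrier = c(TRUE, FALSE, FALSE, TRUE))
  p2 <- pool_controls(list(m, c(10, 1)))
  expect_equal(c(p2$n, p2$carriers), c(14, 3))
})

test_that("OR is invariant to control scaling, inverts under transposition, and is monotone in a", {
  t0 <- c(12, 488, 7, 993)
  expect_equal(odds_ratio(t0), odds_ratio(t0 * c(1, 1, 5, 5)))
  # transposition: swap case and control panels
  expect_equal(odds_ratio(c(t0[3], t0[4], t0[1], t0[2])), 1 / odds_ratio(t0))
  cit <- woolf_ci(c(t0[3], t0[4], t0[1], t0[2]))
  ci0 <- woolf_ci(t0)
  expect_equal(unname(cit), unname(rev(1 / ci0)))
  # monotonicity in a
  ors <- vapply(10:20, function(a) odds_ratio(c(a, 500 - a, 7, 993)),
                numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("the burden model object carries estimate, interval and methods", {
  tab <- contingency_2x2(36, 2366, 16, 22448,
                         labels = c("cases", "controls"))
  fit <- burden_test(tab)
  expect_s3_class(fit, "ptv_burden")
  expect_equal(round(fit$estimate, 2), 21.66)
  expect_true(fit$ci_low <= fit$estimate && fit$estimate <= fit$ci_high)
  expect_equal(unname(coef(fit)), log(fit$estimate))
  expect_equal(unname(confint(fit)), c(fit$ci_low, fit$ci_high))
  expect_equal(unname(sqrt(vcov(fit)[1, 1])), fit$se_log)
  s <- summary(fit)
  expect_lt(s$p_value, 1e-10)
  r <- residuals(fit)
  expect_equal(dim(r), c(2, 2))
  expect_gt(r[1, 1], 0)      # more case carriers than independence expects
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "contingency_2x2")
  expect_output(print(fit), "OR = 21.66")
})

test_that("the formula interface matches the count interface", {
  man <- data.frame(
    carrier = c(rep(TRUE, 12), rep(FALSE, 488), rep(TRUE, 7), rep(FALSE, 993)),
    panel = rep(c("case", "control"), c(500, 1000)))
  f1 <- burden_test(carrier ~ panel, data = man, case = "case")
  f2 <- burden_test(contingency_2x2(12, 500, 7, 1000))
  expect_equal(f1$estimate, f2$estimate)
  expect_equal(f1$ci_low, f2$ci_low)
})

test_that("build_2x2 derives non-carrier cells and rejects bad panels", {
  cm <- data.frame(sample_id = paste0("a", 1:100), carrier = rep(c(TRUE, FALSE), c(9, 91)))
  ctl <- data.frame(sample_id = paste0("b", 1:200), carrier = rep(c(TRUE, FALSE), c(4, 196)))
  tb <- build_2x2(cm, ctl)
  expect_equal(c(tb$a, tb$b, tb$c, tb$d), c(9, 91, 4, 196))
  expect_error(build_2x2(cm, cm), "duplicate sample ids")
  expect_error(build_2x2(cm[0, ], ctl), "empty panel")
})

test_that("subgroup re-analysis equals brute-force recomputation on filtered lists", {
  set.seed(12)
  cm <- data.frame(sample_id = paste0("a", 1:400),
                   carrier = runif(400) < 0.1, age = sample(5:90, 400, TRUE))
  ctl <- data.frame(sample_id = paste0("b", 1:900),
                    carrier = runif(900) < 0.03, age = sample(1:90, 900, TRUE))
  fit <- subgroup_reanalysis(cm, ctl, ~ age >= 17)
  cm2 <- cm[cm$age >= 17, ]; ctl2 <- ctl[ctl$age >= 17, ]
  expect_equal(fit$table$a, sum(cm2$carrier))
  expect_equal(fit$table$c, sum(ctl2$carrier))
  expect_equal(fit$estimate,
               (sum(cm2$carrier) * sum(!ctl2$carrier)) /
                 (sum(!cm2$carrier) * sum(ctl2$carrier)))
  # always-true predicate reproduces the unfiltered analysis
  all_fit <- subgroup_reanalysis(cm, ctl, function(df) rep(TRUE, nrow(df)))
  expect_equal(all_fit$estimate, burden_test(build_2x2(cm, ctl))$estimate)
  expect_error(subgroup_reanalysis(cm, ctl, ~ age > 1000), "empties")
})

test_that("cohort descriptives use even-n medians and n-1 standard deviations", {
  m <- data.frame(age = c(10, 20, 30, 40))
  d <- describe_cohort(m)$numeric
  expect_equal(d$median, 25)
  expect_equal(d$mean, 25)
  expect_equal(d$sd, sd(c(10, 20, 30, 40)))
  one <- describe_cohort(data.frame(age = 42))$numeric
  expect_equal(one$median, 42)
  expect_true(is.na(one$sd))
  # missing values excluded per-field with counts
  dm <- describe_cohort(data.frame(age = c(1, NA, 3)))$numeric
  expect_equal(dm$n, 2); expect_equal(dm$n_missing, 1)
  # categorical proportions
  p <- describe_cohort(data.frame(sex = c("m", "m", "f")))$categorical$sex
  expect_equal(unname(p[order(names(p))]), c(1/3, 2/3))
})

test_that("diagnostic yield counts multi-gene individuals once in the denominator", {
  m <- data.frame(reported_genes = c("A;B", "A", "B", "", "", NA))
  dy <- diagnostic_yield(m)
  expect_equal(dy$n_diagnosed, 3)
  expect_equal(dy$yield_pct, 50)
  expect_equal(dy$genes$count[dy$genes$gene == "A"], 2L)
  expect_equal(dy$genes$share_pct[dy$genes$gene == "A"], 200 / 3)
  empty <- diagnostic_yield(data.frame(reported_genes = c("", NA)))
  expect_equal(empty$yield_pct, 0)
  expect_equal(nrow(empty$genes), 0)
})

test_that("forest tables keep input order and respect their own intervals", {
  fits <- lapply(load_comparison_counts(), burden_test)
  ft <- forest_table(unname(fits))
  expect_equal(nrow(ft), 4)
  expect_true(all(ft$ci_low <= ft$or & ft$or <= ft$ci_high))
  expect_equal(attr(ft, "axis"), "log")
  single <- forest_table(list(fits[[1]]))
  expect_equal(nrow(single), 1)
  # plotting works headless
  png_file <- tempfile(fileext = ".png")
  grDevices::png(png_file); plot(ft); grDevices::dev.off()
  expect_true(file.exists(png_file))
})
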
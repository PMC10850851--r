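test_that("completion-rate tests match their oracles on random tables", {
  set.seed(10)
  for (i in 1:120) {
    tab <- matrix(rpois(4, sample(3:8, 1)) + (i %% 2), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    f <- completion_rate_test(tab, method = "fisher_exact")
    expect_equal(f$p_value, oracle_fisher_p(tab), tolerance = 1e-12)
    expect_equal(f$p_value, fisher.test(tab)$p.value, tolerance = 1e-9)
    y <- completion_rate_test(tab, method = "chi2_yates")
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(y$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(y$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("completion-rate test on the study's table and edge cases", {
  tab <- matrix(c(203, 13, 212, 4), 2, byrow = TRUE)
  res <- completion_rate_test(tab)             # auto -> fisher (cells < 10)
  expect_identical(res$method, "fisher_exact")
  expect_equal(res$p_value, fisher.test(tab)$p.value, tolerance = 1e-9)
  expect_lt(res$p_value, 0.05)
  # identical rows with an empty failure column: degenerate, p = 1
  expect_equal(completion_rate_test(matrix(c(10, 0, 10, 0), 2,
                                           byrow = TRUE))$p_value, 1)
  expect_error(completion_rate_test(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
  # large balanced table goes to the corrected chi-square
  expect_identical(completion_rate_test(matrix(c(100, 20, 90, 30), 2,
                                               byrow = TRUE))$method,
                   "chi2_yates")
})

test_that("paired Wilcoxon: exact small-sample p equals sign-flip oracle", {
  set.seed(20)
  for (i in 1:60) {
    n <- sample(3:10, 1)
    a <- round(runif(n, 1, 5) * 4) / 4    # coarse grid induces ties
    b <- round(runif(n, 1, 5) * 4) / 4
    if (all(a == b)) next
    res <- paired_wilcoxon(a, b)
    expect_equal(res$p_value, oracle_wilcoxon_perm_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("paired Wilcoxon: degenerate input, direction, asymptotic bound", {
  expect_warning(res <- paired_wilcoxon(1:5, 1:5), "zero")
  expect_equal(res$p_value, 1)

  # sign of Z follows a - b
  set.seed(21)
  a <- rnorm(72); b <- a + abs(rnorm(72)) + 0.1   # every difference negative
  res <- paired_wilcoxon(a, b)
  expect_lt(res$statistic, 0)
  # |Z| attains the closed-form maximum when all differences share a sign
  n <- 72
  zmax <- (n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  expect_equal(abs(res$statistic), zmax, tolerance = 1e-12)
  expect_lt(zmax, 7.374)
  expect_gt(zmax, 7.373)

  # against the reference implementation on tie-free data (no continuity
  # correction, asymptotic)
  set.seed(22)
  x <- rnorm(40); y <- rnorm(40)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  mine <- paired_wilcoxon(x, y, exact = FALSE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("order-effect ANOVA: exact null, t^2 identity, type-I error", {
  g <- rep(c("A", "B"), each = 10)
  x <- rep(rnorm(10), 2)                      # identical group data
  res <- order_effect_test(x, g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  set.seed(30)
  x <- rnorm(20); res <- order_effect_test(x, g)
  tt <- t.test(x[g == "A"], x[g == "B"], var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)

  expect_error(order_effect_test(1:3, c("A", "A", "B")), "at least 2")
  expect_error(order_effect_test(1:3, c("A", "A", "A")), "two groups")

  # type-I error at nominal alpha under the null (3 SE band)
  set.seed(31)
  reps <- 1500
  rej <- mean(replicate(reps, {
    order_effect_test(rnorm(24), rep(c("A", "B"), each = 12))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps))

  # Wilcoxon (asymptotic) and Fisher under their nulls
  set.seed(32)
  rejw <- mean(replicate(1000, {
    paired_wilcoxon(rnorm(72), rnorm(72))$p_value < 0.05
  }))
  expect_lt(abs(rejw - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.005)
  rejf <- mean(replicate(1000, {
    tab <- matrix(rbinom(2, 30, 0.5), 2)
    tab <- cbind(tab, 30 - tab)
    completion_rate_test(tab, "fisher_exact")$p_value < 0.05
  }))
  expect_lte(rejf, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))  # exact test: conservative
})

test_that("summary tables print the study's rounding conventions", {
  mk <- function(successes, N, modality) {
    data.frame(nurse_id = sprintf("N%02d", rep(1:36, length.out = N)),
               patient_id = sprintf("P%03d", seq_len(N)),
               modality = modality,
               truth_delirium = FALSE, outcome_delirium = FALSE,
               outcome_label = "x",
               success = seq_len(N) <= successes,
               human_errors = 0L, duration = 2.3,
               items_administered = 21L, items_skipped = 0L,
               group = rep(c("A", "B"), each = N / 2),
               order = 1L, slot = 1L,
               pair_id = sprintf("N%02d-%d", rep(1:36, length.out = N),
                                 seq_len(N)),
               stringsAsFactors = FALSE)
  }
  trial <- structure(list(assessments = rbind(mk(203, 216, "paper"),
                                              mk(212, 216, "dst"))),
                     class = "ddst_trial")
  s <- summarize_trial(trial)
  expect_identical(s$success$pct[s$success$modality == "paper"], "94")
  expect_identical(s$success$pct[s$success$modality == "dst"], "98.1")
  expect_identical(s$time$median_iqr[1], "2.3 (2.3-2.3)")

  all_ok <- structure(list(assessments = rbind(mk(216, 216, "paper"),
                                               mk(216, 216, "dst"))),
                      class = "ddst_trial")
  s2 <- summarize_trial(all_ok)
  expect_setequal(s2$success$pct, "100")

  expect_error(summarize_trial(structure(list(assessments = NULL),
                                         class = "ddst_trial")), "empty")
  # prevalence formatting follows the count (%) style: 38/148 -> 26
  expect_identical(ddst:::format_pct(38, 148, digits = 0), "26")
  expect_identical(ddst:::format_pct(203, 216), "94")
  expect_identical(ddst:::format_pct(212, 216), "98.1")
})

test_that("sample size formula and attrition inflation", {
  expect_identical(required_sample_size(n_analysable = 54,
                                        attrition = 0.25)$n_enrol, 72L)
  res <- required_sample_size(delta = 1, sd = 1, alpha = 0.05, power = 0.90)
  expect_identical(res$n_analysable, 22L)
  expect_identical(res$n_enrol, 22L)              # attrition = 0
  expect_error(required_sample_size(n_analysable = 10, attrition = 1),
               "attrition")
  # closed form: 2 (z_{.975} + z_{.90})^2 (sd/delta)^2, rounded up
  for (par in list(c(0.5, 1), c(1, 2), c(0.8, 1.2))) {
    res <- required_sample_size(delta = par[1], sd = par[2])
    expect_identical(res$n_analysable,
                     as.integer(ceiling(2 * ((qnorm(0.975) + qnorm(0.90)) *
                                               par[2] / par[1])^2)))
  }
})

test_that("summarize_trial on a simulated trial includes usability tests", {
  tr <- simulate_trial(trial_design(n_nurses = 12, n_patients = 20),
                       sim_config(), seed = 5)
  s <- summarize_trial(tr)
  expect_identical(s$n_pairs, 36L)
  expect_identical(nrow(s$usability), 7L)       # 6 domains + total
  expect_true(all(vapply(s$usability_tests, function(t)
    t$p_value >= 0 && t$p_value <= 1, logical(1))))
  expect_identical(s$order_effect$method, "anova")
  expect_true(s$prevalence$n > 0L && s$prevalence$n <= 20L)
  expect_output(print(s), "Trial summary")
})
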
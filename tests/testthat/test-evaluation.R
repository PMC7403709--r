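# Splitting, ROC/AUC, bootstrap, threshold metrics, calibration,
# Hosmer-Lemeshow, decision curves and Table-1-style statistics.

test_that("cohort split sizes and reproducibility match the 80:20 design", {
  pats <- data.frame(patient_id = sprintf("P%03d", 1:151),
                     label = rep(c("non-PR", "PR"), c(72, 79)))
  sp <- split_cohort(pats, ratio = 0.8, seed = 4)
  expect_equal(nrow(sp$primary), 120)
  expect_equal(nrow(sp$validation), 31)
  expect_length(intersect(sp$primary$patient_id, sp$validation$patient_id), 0)
  expect_setequal(c(sp$primary$patient_id, sp$validation$patient_id),
                  pats$patient_id)
  # stratification keeps class fractions within one patient
  expect_lt(abs(mean(sp$primary$label == "PR") - 79 / 151), 1 / 120)

  sp2 <- split_cohort(pats, ratio = 0.8, seed = 4)
  expect_identical(sp, sp2)

  small <- split_cohort(pats[1:10, ], ratio = 0.8, seed = 1)
  expect_equal(nrow(small$primary), 8)
  expect_equal(nrow(small$validation), 2)
  expect_error(split_cohort(pats, ratio = 1.2), "ratio")
})

test_that("rank AUC equals the brute-force pairwise oracle", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.7), c(1, 1, 0))$auc, 1)
  expect_equal(compute_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)

  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5)) # both classes guaranteed
    s <- round(runif(n), sample(1:3, 1)) # rounding induces ties
    expect_equal(compute_auc(s, y)$auc, brute_auc(s, y))
    # invariance under strictly increasing transforms
    expect_equal(compute_auc(plogis(5 * s), y)$auc, compute_auc(s, y)$auc)
  }
  expect_error(compute_auc(1:3, c(1, 1, 1)), "two classes")
})

test_that("ROC curve is monotone and agrees with pROC", {
  set.seed(7)
  y <- rbinom(60, 1, 0.5); s <- runif(60) + 0.4 * y
  r <- compute_auc(s, y)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  ext <- pROC::roc(response = y, predictor = s, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ext)))
  d <- compute_auc(s, y, ci = "delong")
  expect_true(d$ci[1] <= d$auc && d$auc <= d$ci[2])
})

test_that("stratified bootstrap CI behaves and covers", {
  y <- rep(c(0, 1), each = 20); s <- runif(40)
  const <- bootstrap_ci(function(...) 0.7, s, y, B = 200, seed = 1)
  expect_equal(as.numeric(const), c(0.7, 0.7))
  ci1 <- bootstrap_ci(function(a, b) compute_auc(a, b)$auc, s, y, B = 200, seed = 5)
  ci2 <- bootstrap_ci(function(a, b) compute_auc(a, b)$auc, s, y, B = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(ci1[1] >= 0 && ci1[2] <= 1)
  expect_error(bootstrap_ci(function(...) 1, s, y, B = 50), "B must be")

  # coverage at true AUC 0.8: binormal scores, n = 100 per dataset
  mu <- sqrt(2) * qnorm(0.8)
  covered <- 0; nsim <- 120
  for (i in seq_len(nsim)) {
    withr::with_seed(1000 + i, {
      yy <- rep(c(0, 1), each = 50)
      ss <- rnorm(100) + mu * yy
    })
    ci <- bootstrap_ci(function(a, b) compute_auc(a, b)$auc, ss, yy,
                       B = 400, seed = i)
    if (ci[1] <= 0.8 && 0.8 <= ci[2]) covered <- covered + 1
  }
  expect_gt(covered / nsim, 0.86)
  expect_lt(covered / nsim, 1)
})

test_that("threshold metrics reproduce a hand-computed confusion matrix", {
  # TP=7, FN=3, TN=8, FP=2 at threshold 0.5
  scores <- c(rep(0.9, 7), rep(0.1, 3), rep(0.2, 8), rep(0.8, 2))
  labels <- rep(c(1, 0), c(10, 10))
  tm <- threshold_metrics(scores, labels, 0.5)
  expect_equal(tm$tp, 7); expect_equal(tm$fn, 3)
  expect_equal(tm$tn, 8); expect_equal(tm$fp, 2)
  expect_equal(tm$sensitivity, 0.7)
  expect_equal(tm$specificity, 0.8)
  expect_equal(tm$accuracy, 0.75)
  expect_equal(tm$f1, 2 * (7 / 9) * 0.7 / (7 / 9 + 0.7), tolerance = 1e-12)
  expect_equal(round(tm$f1, 3), 0.737)

  perfect <- threshold_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  allpos <- threshold_metrics(rep(0.9, 4), c(1, 1, 0, 0), 0.5)
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)

  withci <- threshold_metrics(scores, labels, 0.5, ci = TRUE, B = 200)
  expect_true(withci$ci$sensitivity[1] <= 0.7 & withci$ci$sensitivity[2] >= 0.7)

  # Youden threshold on a separable set sits at the positive block
  expect_equal(youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.8)
})

test_that("calibration curve bins by deciles and sums to n", {
  withr::with_seed(2, {
    s <- runif(500)
    y <- rbinom(500, 1, s)
  })
  cal <- calibration_curve(s, y, g = 10)
  expect_equal(sum(cal$n), 500)
  expect_equal(nrow(cal), 10)
  expect_lt(max(abs(cal$mean_predicted - cal$observed_fraction)), 0.15)

  expect_warning(c1 <- calibration_curve(rep(0.4, 50), rbinom(50, 1, 0.4)),
                 "collapsed")
  expect_equal(nrow(c1), 1)
})

test_that("Hosmer-Lemeshow matches hand arithmetic and its null behaviour", {
  # observed = expected in every bin -> H = 0, p = 1
  s0 <- rep(c(0.2, 0.5, 0.8), each = 10)
  y0 <- c(rep(c(1, 0), c(2, 8)), rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(8, 2)))
  h0 <- hosmer_lemeshow(s0, y0, g = 3)
  expect_equal(h0$statistic, 0)
  expect_equal(h0$p_value, 1)

  # hand-computed 3-bin toy: bins (E=2,O=3), (E=10,O=8), (E=16,O=17), n=20 each
  s1 <- rep(c(0.1, 0.5, 0.8), each = 20)
  y1 <- c(rep(c(1, 0), c(3, 17)), rep(c(1, 0), c(8, 12)), rep(c(1, 0), c(17, 3)))
  h1 <- hosmer_lemeshow(s1, y1, g = 3)
  H_hand <- 1 / (2 * 0.9) + 4 / (10 * 0.5) + 1 / (16 * 0.2)
  expect_equal(h1$statistic, H_hand)
  expect_equal(h1$df, 1)
  expect_equal(h1$p_value, pchisq(H_hand, 1, lower.tail = FALSE))
})

test_that("decision curve reproduces its closed forms", {
  # predict-all-positive at prevalence 0.5, threshold 0.5 -> net benefit 0
  y <- rep(c(0, 1), each = 10)
  dc <- decision_curve(rep(0.99, 20), y, thresholds = c(0.25, 0.5, 0.75))
  expect_equal(dc$net_benefit[dc$threshold == 0.5], 0)
  expect_equal(dc$net_benefit, dc$treat_all) # all-positive model == treat-all
  expect_equal(dc$treat_all, 0.5 - 0.5 * dc$threshold / (1 - dc$threshold))
  expect_true(all(dc$treat_none == 0))

  # perfect classifier: NB == prevalence wherever the threshold separates
  sp <- c(rep(0.9, 6), rep(0.1, 14))
  yp <- rep(c(1, 0), c(6, 14))
  dcp <- decision_curve(sp, yp, thresholds = seq(0.2, 0.8, 0.1))
  expect_true(all(abs(dcp$net_benefit - 0.3) < 1e-12))
  # net benefit never exceeds prevalence
  withr::with_seed(9, {
    sr <- runif(50)
    yr <- rbinom(50, 1, 0.4)
  })
  dcr <- decision_curve(sr, yr)
  expect_true(all(dcr$net_benefit <= mean(yr) + 1e-12))
  expect_true(all(dcr$treat_all <= mean(yr) + 1e-12))
})

test_that("univariable tests reproduce the published cohort statistics", {
  tab1 <- reference_table1("primary")
  res <- univariable_tests(tab1)
  nst <- res[res$variable == "n_stage", ]
  expect_equal(nst$test, "chisq")
  expect_equal(round(nst$statistic, 2), 8.35)
  expect_equal(nst$df, 2)
  expect_equal(round(nst$p_value, 3), 0.015)
  gen <- res[res$variable == "gender", ]
  expect_equal(round(gen$p_value, 3), 0.401)
  cea <- res[res$variable == "cea", ]
  expect_equal(round(cea$p_value, 3), 0.134)
  # sparse T2 row triggers Fisher by default; plain chi-square by option
  tst <- res[res$variable == "t_stage", ]
  expect_equal(tst$test, "fisher")
  res2 <- univariable_tests(tab1, vars = "t_stage", fisher_when_sparse = FALSE)
  expect_equal(round(res2$p_value, 3), 0.698)

  same <- data.frame(label = rep(c("a", "b"), each = 20),
                     v = rep(c("x", "y"), 20))
  expect_equal(univariable_tests(same)$p_value, 1)
  one <- data.frame(label = rep(c("a", "b"), each = 20), v = "x")
  expect_warning(r1 <- univariable_tests(one), "single-category")
  expect_null(r1)
})

test_that("cohort summary reproduces the published percentages", {
  sm <- summarize_cohort(reference_table1("primary"))
  cat_tab <- sm$categorical
  pick <- function(var, lev, grp) {
    cat_tab$pct[cat_tab$variable == var & cat_tab$level == lev &
                  cat_tab$group == grp]
  }
  expect_equal(round(pick("gender", "male", "non-PR"), 1), 62.3)
  expect_equal(round(pick("n_stage", "N1", "non-PR"), 1), 75.4)
  expect_equal(round(pick("t_stage", "T4", "PR"), 1), 54.2)
  expect_equal(round(pick("cea", "normal", "PR"), 1), 64.4)
  smv <- summarize_cohort(reference_table1("validation"))
  cv <- smv$categorical
  expect_equal(round(cv$pct[cv$variable == "gender" & cv$level == "male" &
                              cv$group == "PR"], 1), 70.0)
  # continuous summary block
  d <- data.frame(label = rep(c("A", "B"), each = 10), age = c(1:10, 11:20))
  sc <- summarize_cohort(d)$continuous
  expect_equal(sc$mean, c(5.5, 15.5))
  expect_equal(sc$median, c(5.5, 15.5))
})
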
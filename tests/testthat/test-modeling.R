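# Standardization, LASSO selection, SVM tile classifier, aggregation,
# pathology signature and the multivariable model.

test_that("standardization centres primary data and reuses its parameters", {
  set.seed(1)
  x <- matrix(rnorm(50 * 4, mean = 5, sd = 2), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  sp <- standardize_fit(x)
  z <- standardize_apply(sp, x)
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-10))

  xc <- cbind(x, constant = 1)
  expect_warning(spc <- standardize_fit(xc), "zero-variance")
  expect_false("constant" %in% spc$features)

  # validation transformed with primary parameters differs from its own z-scores
  xv <- matrix(rnorm(30 * 4, mean = 9, sd = 1), 30, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  zv <- standardize_apply(sp, xv)
  own <- scale(xv)
  expect_gt(max(abs(zv - own)), 1)
  expect_gt(abs(mean(zv[, 1])), 0.5) # shifted cohort stays shifted
})

test_that("LASSO recovers planted informative features and shrinks under nulls", {
  n <- 300; p <- 104
  hits <- 0; noise_ok <- 0
  for (s in 1:5) {
    withr::with_seed(s, {
      y <- rbinom(n, 1, 0.5)
      x <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, sprintf("f%03d", 1:p)))
      x[, 1] <- x[, 1] + 1.5 * (2 * y - 1) # 3-SD class separation
      x[, 2] <- x[, 2] - 1.5 * (2 * y - 1)
    })
    res <- lasso_select(scale(x), y, seed = s)
    if (all(c("f001", "f002") %in% res$selected)) hits <- hits + 1
    # the sparser 1-SE solution keeps the signal and sheds most noise
    res1 <- lasso_select(scale(x), y, seed = s, rule = "1se")
    if (all(c("f001", "f002") %in% res1$selected) &&
        length(setdiff(res1$selected, c("f001", "f002"))) <= 15) {
      noise_ok <- noise_ok + 1
    }
  }
  expect_gte(hits, 4)
  expect_gte(noise_ok, 4)

  # permuted labels: selection collapses in the majority of seeds
  small <- 0
  for (s in 1:5) {
    withr::with_seed(100 + s, {
      y <- rbinom(n, 1, 0.5)
      x <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, sprintf("f%03d", 1:p)))
    })
    res <- lasso_select(scale(x), y, seed = s, rule = "1se")
    if (length(res$selected) <= 5) small <- small + 1
  }
  expect_gte(small, 3)

  expect_error(lasso_select(matrix(rnorm(40), 10, 4), rep(1, 10)),
               "two classes")
})

test_that("full shrinkage at large penalties selects nothing", {
  withr::with_seed(3, {
    y <- rbinom(80, 1, 0.5)
    x <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("f", 1:6)))
  })
  res <- lasso_select(x, y, lambda = c(50, 40, 30), seed = 1)
  expect_length(res$coefficients[res$coefficients != 0][-1], 0)
})

test_that("patient-grouped folds never split a patient", {
  y <- rep(c(0, 1), each = 30)
  groups <- rep(sprintf("P%02d", 1:20), each = 3)
  ids <- pathsig:::make_fold_ids(y, 5, groups, seed = 2)
  expect_true(all(tapply(ids, groups, function(v) length(unique(v))) == 1))
  expect_equal(sort(unique(ids)), 1:5)
})

test_that("SVM tile classifier separates a separable toy set and calibrates", {
  withr::with_seed(5, {
    n <- 120
    y <- rep(c(0, 1), each = n / 2)
    # disjoint supports: genuinely separable
    x <- cbind(a = runif(n) + 2.5 * y, b = runif(n) - 2.5 * y)
  })
  clf <- train_tile_classifier(x, y, cv_folds = 3, cost_grid = c(1, 10),
                               gamma_grid = c(0.1, 1), seed = 1)
  p <- predict_tile_prob(clf, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(compute_auc(p, y)$auc, 1)
  expect_equal(compute_auc(1 - p, y)$auc, 1 - compute_auc(p, y)$auc)
  expect_gte(clf$cv_auc, 0.95)

  expect_error(train_tile_classifier(x, y, cost_grid = numeric(0)),
               "non-empty")
})

test_that("label-permuted SVM hovers at chance in cross-validation", {
  aucs <- vapply(1:4, function(s) {
    withr::with_seed(s, {
      y <- rbinom(100, 1, 0.5)
      x <- matrix(rnorm(100 * 3), 100, 3)
    })
    clf <- train_tile_classifier(x, y, cv_folds = 3, cost_grid = c(0.5, 2),
                                 gamma_grid = c(0.1, 0.5), seed = s)
    clf$cv_auc
  }, numeric(1))
  expect_true(mean(aucs) > 0.35 && mean(aucs) < 0.65)
})

test_that("patient aggregation is the order-invariant arithmetic mean", {
  agg <- aggregate_patients(c(0.2, 0.4, 0.6), rep("P1", 3))
  expect_equal(agg$mean_prob, 0.4)
  a1 <- aggregate_patients(c(0.1, 0.9, 0.5, 0.5), c("A", "B", "A", "B"))
  a2 <- aggregate_patients(c(0.5, 0.5, 0.9, 0.1), c("B", "A", "B", "A"))
  expect_equal(a1, a2)
  # duplicating every tile leaves the mean unchanged
  a3 <- aggregate_patients(rep(c(0.1, 0.5), 2), rep(c("A", "A"), 2))
  expect_equal(a3$mean_prob, 0.3)
  expect_equal(a3$n_tiles, 4)
})

test_that("pathology signature recovers parameters and preserves ranking", {
  sig0 <- structure(list(beta0 = 0, beta1 = 0, separation = FALSE,
                         positive = "PR"), class = "pathology_signature")
  expect_equal(pathology_score(sig0, c(0, 0.5, 1)), rep(0.5, 3))

  withr::with_seed(9, {
    m <- runif(2000)
    y <- rbinom(2000, 1, plogis(-2 + 4 * m))
  })
  sig <- fit_signature(m, y)
  expect_lt(abs(sig$beta0 - (-2)), 0.5)
  expect_lt(abs(sig$beta1 - 4), 0.5)
  s <- pathology_score(sig, m)
  expect_equal(compute_auc(s, y)$auc, compute_auc(m, y)$auc)
  expect_true(all(diff(pathology_score(sig, seq(0, 1, 0.1))) > 0))

  # perfect separation falls back to the ridge-penalized fit
  ms <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  ys <- c(0, 0, 0, 1, 1, 1)
  expect_warning(sigs <- fit_signature(ms, ys), "separation")
  expect_true(sigs$beta1 > 0)
  expect_true(all(pathology_score(sigs, ms) > 0 & pathology_score(sigs, ms) < 1))

  expect_error(fit_signature(c(0.1, 0.9), c(0, 1)), "2 patients per class")
})

test_that("multivariable model flags the score and rejects collinearity", {
  gen <- function(seed, n = 150) {
    withr::with_seed(seed, {
      score <- runif(n)
      y <- rbinom(n, 1, plogis(-2 + 4 * score))
      data.frame(label = ifelse(y == 1, "PR", "non-PR"),
                 age = rnorm(n, 55, 11),
                 gender = sample(c("male", "female"), n, TRUE),
                 t_stage = sample(c("T2", "T3", "T4"), n, TRUE, c(.05, .4, .55)),
                 n_stage = sample(c("N0", "N1", "N2"), n, TRUE, c(.2, .6, .2)),
                 cea = sample(c("normal", "abnormal"), n, TRUE),
                 pathology_score = score)
    })
  }
  covars <- c("age", "genderfemale", "ceaabnormal")
  score_sig <- 0; covar_null <- 0
  for (s in 1:3) {
    mv <- fit_multivariable(gen(s))
    tab <- mv$table
    expect_true(all(tab$odds_ratio > 0))
    expect_equal(tab$odds_ratio, exp(tab$estimate))
    if (tab$p_value[tab$term == "pathology_score"] < 0.05) score_sig <- score_sig + 1
    covar_null <- covar_null +
      all(tab$p_value[tab$term %in% covars] > 0.01)
  }
  expect_equal(score_sig, 3) # the score is the only designed predictor
  expect_gte(covar_null, 2)

  d2 <- gen(1); d2$age <- 5 # constant covariate is collinear with intercept
  expect_error(fit_multivariable(d2), "collinear")
  expect_error(fit_multivariable(gen(1)[, -2]), "missing columns")
})
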
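# Evaluation layer: cohort splitting, ROC/AUC with bootstrap or DeLong
# intervals, threshold metrics, calibration and the Hosmer-Lemeshow test,
# decision-curve analysis, and Table-1-style univariable statistics.

#' Split a cohort into primary and validation sets
#'
#' The primary set holds `floor(n * ratio)` patients (151 patients at the
#' default 80% ratio give 120/31). When stratified, per-class primary counts
#' are `floor(n_class * ratio)` with the remainder distributed by largest
#' fractional part so the total is exact.
#'
#' @param patients data.frame with a `label` column.
#' @param ratio primary fraction in (0, 1).
#' @param seed RNG seed.
#' @param stratify stratify by outcome (default TRUE).
#' @return list with `primary` and `validation` data.frames (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(patients, ratio = 0.8, seed = 1, stratify = TRUE) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)", call. = FALSE)
  n <- nrow(patients)
  if (n < 5) stop("need at least 5 patients to split", call. = FALSE)
  n_primary <- floor(n * ratio)
  withr::with_seed(as.integer(seed), {
    if (stratify) {
      classes <- unique(patients$label)
      raw <- vapply(classes, function(cl) sum(patients$label == cl) * ratio,
                    numeric(1))
      take <- floor(raw)
      rem <- n_primary - sum(take)
      if (rem > 0) {
        ord <- order(raw - take, decreasing = TRUE)
        take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
      }
      idx <- unlist(lapply(seq_along(classes), function(k) {
        pool <- which(patients$label == classes[k])
        sample(pool, take[k])
      }))
    } else {
      idx <- sample(n, n_primary)
    }
  })
  list(primary = patients[sort(idx), , drop = FALSE],
       validation = patients[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' ROC curve and AUC
#'
#' AUC by the rank-sum (Mann-Whitney) estimator with ties contributing 1/2;
#' identical to the area under the empirical ROC curve traced over all
#' thresholds. Optional 95% interval by stratified percentile bootstrap or
#' DeLong (via \pkg{pROC}).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels.
#' @param ci `"none"`, `"bootstrap"` or `"delong"`.
#' @param B bootstrap replicates (default 2000).
#' @param level confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `roc_result`: `auc`, `points` (data.frame fpr,
#'   tpr, threshold), `ci`, `ci_method`, `n_pos`, `n_neg`.
#' @export
compute_auc <- function(scores, labels, ci = c("none", "bootstrap", "delong"),
                        B = 2000, level = 0.95, seed = 1) {
  ci <- match.arg(ci)
  y <- as_binary_label(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, cumsum(tapply(y == 1, factor(-scores, levels = -thr), sum)) / n_pos)
  fpr <- c(0, cumsum(tapply(y == 0, factor(-scores, levels = -thr), sum)) / n_neg)
  pts <- data.frame(threshold = c(Inf, thr), fpr = as.vector(fpr),
                    tpr = as.vector(tpr))
  interval <- NULL
  if (ci == "bootstrap") {
    interval <- bootstrap_ci(function(s, l) compute_auc(s, l)$auc,
                             scores, y, B = B, level = level, seed = seed)
  } else if (ci == "delong") {
    suppressMessages({
      rr <- pROC::roc(response = y, predictor = scores,
                      levels = c(0, 1), direction = "<", quiet = TRUE)
      v <- as.numeric(pROC::ci.auc(rr, method = "delong", conf.level = level))
    })
    interval <- c(lower = v[1], upper = v[3])
  }
  structure(list(auc = auc, points = pts, ci = interval, ci_method = ci,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (n+ = %d, n- = %d)", x$auc, x$n_pos, x$n_neg))
  if (!is.null(x$ci)) cat(sprintf(" [%.3f, %.3f] (%s)", x$ci[1], x$ci[2], x$ci_method))
  cat("\n")
  invisible(x)
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples positives and negatives separately (so every replicate keeps
#' both classes), evaluates `metric_fn(scores, labels)` on each, and returns
#' the percentile interval. Deterministic for a fixed seed.
#'
#' @param metric_fn function of (scores, labels) returning a scalar.
#' @param scores,labels data to resample.
#' @param B replicates (>= 100).
#' @param level confidence level.
#' @param seed RNG seed.
#' @return named numeric `c(lower, upper)`; the replicate vector is attached
#'   as attribute `"replicates"`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, B = 2000, level = 0.95,
                         seed = 1) {
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  y <- as_binary_label(labels)
  pos <- which(y == 1); neg <- which(y == 0)
  stats <- numeric(B)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      idx <- c(pos[sample.int(length(pos), replace = TRUE)],
               neg[sample.int(length(neg), replace = TRUE)])
      stats[b] <- metric_fn(scores[idx], y[idx])
    }
  })
  a <- (1 - level) / 2
  out <- quantile(stats, c(a, 1 - a), names = FALSE)
  out <- c(lower = out[1], upper = out[2])
  attr(out, "replicates") <- stats
  out
}

#' Operating threshold by Youden's J
#'
#' Maximises sensitivity + specificity - 1 over the observed scores
#' (classification rule: score >= threshold); ties resolve to the lowest
#' such threshold. Chosen on the primary cohort and reused on validation.
#'
#' @param scores,labels primary-cohort scores and labels.
#' @return the threshold (one of the observed score values).
#' @export
youden_threshold <- function(scores, labels) {
  y <- as_binary_label(labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Threshold classification metrics
#'
#' Confusion counts at `score >= threshold`, with accuracy, sensitivity,
#' specificity, precision and F1; optional stratified bootstrap CIs.
#'
#' @param scores,labels scores and binary labels.
#' @param threshold decision threshold.
#' @param ci add bootstrap CIs (default FALSE).
#' @param B,level,seed bootstrap parameters.
#' @return object of class `threshold_metrics`.
#' @export
threshold_metrics <- function(scores, labels, threshold, ci = FALSE,
                              B = 2000, level = 0.95, seed = 1) {
  y <- as_binary_label(labels)
  point <- threshold_metrics_point(scores, y, threshold)
  cis <- NULL
  if (ci) {
    cis <- lapply(c("accuracy", "sensitivity", "specificity", "f1"),
                  function(metric) {
      bootstrap_ci(function(s, l) threshold_metrics_point(s, l, threshold)[[metric]],
                   scores, y, B = B, level = level, seed = seed)
    })
    names(cis) <- c("accuracy", "sensitivity", "specificity", "f1")
  }
  structure(c(point, list(threshold = threshold, ci = cis)),
            class = "threshold_metrics")
}

threshold_metrics_point <- function(scores, y, threshold) {
  pred <- scores >= threshold
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  tn <- sum(!pred & y == 0); fp <- sum(pred & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (!is.na(sens) && prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y), sensitivity = sens,
       specificity = spec, precision = prec, f1 = f1)
}

# Equal-frequency score bins shared by the calibration curve and H-L test;
# heavy ties collapse bins with a warning.
score_bins <- function(scores, g) {
  br <- unique(quantile(scores, probs = seq(0, 1, length.out = g + 1)))
  if (length(br) < g + 1) {
    warning("ties collapsed ", g + 1 - length(br), " calibration bin(s)",
            call. = FALSE)
  }
  if (length(br) < 2) return(rep(1L, length(scores)))
  cut(scores, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Calibration curve
#'
#' Equal-frequency (decile by default) bins on the score, with per-bin mean
#' predicted probability and observed event fraction.
#'
#' @param scores predicted probabilities.
#' @param labels binary labels.
#' @param g number of bins (default 10).
#' @return data.frame: bin, n, mean_predicted, observed_fraction.
#' @export
calibration_curve <- function(scores, labels, g = 10) {
  y <- as_binary_label(labels)
  if (length(y) < g) stop("need at least g observations", call. = FALSE)
  b <- score_bins(scores, g)
  data.frame(bin = sort(unique(b)),
             n = as.vector(table(b)),
             mean_predicted = as.vector(tapply(scores, b, mean)),
             observed_fraction = as.vector(tapply(y, b, mean)),
             row.names = NULL)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' `H = sum_g (O_g - E_g)^2 / (E_g (1 - E_g / n_g))` over `g`
#' equal-frequency score bins, referred to chi-square with `g - 2` degrees
#' of freedom. Bins whose variance term vanishes are merged with a warning.
#'
#' @param scores predicted probabilities.
#' @param labels binary labels.
#' @param g number of bins (default 10).
#' @return object of class `hl_result`: `statistic`, `df`, `p_value`,
#'   `bins` (per-bin n, observed, expected).
#' @export
hosmer_lemeshow <- function(scores, labels, g = 10) {
  y <- as_binary_label(labels)
  if (length(y) < 2 * g) stop("need at least 2g observations", call. = FALSE)
  b <- score_bins(scores, g)
  tab <- data.frame(bin = sort(unique(b)),
                    n = as.vector(table(b)),
                    observed = as.vector(tapply(y, b, sum)),
                    expected = as.vector(tapply(scores, b, sum)))
  denom <- tab$expected * (1 - tab$expected / tab$n)
  while (any(denom <= 0) && nrow(tab) > 1) {
    warning("merging a degenerate Hosmer-Lemeshow bin", call. = FALSE)
    i <- which(denom <= 0)[1]
    j <- if (i == nrow(tab)) i - 1 else i + 1
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab <- tab[-i, , drop = FALSE]
    denom <- tab$expected * (1 - tab$expected / tab$n)
  }
  H <- sum((tab$observed - tab$expected)^2 / denom)
  df <- max(1L, nrow(tab) - 2L)
  structure(list(statistic = H, df = df,
                 p_value = pchisq(H, df, lower.tail = FALSE),
                 bins = tab),
            class = "hl_result")
}

#' @export
print.hl_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: H = %.3f, df = %d, p = %.3f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Decision-curve analysis
#'
#' Net benefit `NB(t) = TP(t)/N - FP(t)/N * t/(1-t)` of classifying at each
#' threshold probability `t`, alongside the treat-all policy
#' `pi - (1 - pi) t/(1-t)` (prevalence `pi`) and treat-none (identically 0).
#'
#' @param scores predicted probabilities.
#' @param labels binary labels.
#' @param thresholds threshold grid in (0, 1); values >= 1 are dropped.
#' @return data.frame: threshold, net_benefit, treat_all, treat_none.
#' @export
decision_curve <- function(scores, labels, thresholds = seq(0.01, 0.99, 0.01)) {
  y <- as_binary_label(labels)
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present", call. = FALSE)
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(y); prev <- mean(y)
  nb <- vapply(thresholds, function(t) {
    pred <- scores >= t
    sum(pred & y == 1) / n - sum(pred & y == 0) / n * t / (1 - t)
  }, numeric(1))
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
             treat_none = 0)
}

#' Univariable association tests (Table-1 style)
#'
#' Categorical variables: Pearson chi-square (with the conventional
#' continuity correction on 2x2 tables), switching to Fisher's exact test
#' when any expected cell count is below 5 (configurable). Continuous
#' variables: Mann-Whitney by default, Welch t-test by option. Variables
#' with a single observed category are skipped with a warning.
#'
#' @param data data.frame of covariates plus a binary group column.
#' @param group_col grouping column name (default `"label"`).
#' @param vars variables to test (default: all others).
#' @param continuous_test `"wilcox"` or `"t"`.
#' @param fisher_when_sparse use Fisher when expected counts < 5.
#' @return data.frame: variable, test, statistic, df, p_value.
#' @export
univariable_tests <- function(data, group_col = "label", vars = NULL,
                              continuous_test = c("wilcox", "t"),
                              fisher_when_sparse = TRUE) {
  continuous_test <- match.arg(continuous_test)
  grp <- factor(data[[group_col]])
  if (nlevels(grp) != 2) stop("group column must have two levels", call. = FALSE)
  vars <- vars %||% setdiff(names(data), group_col)
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      if (length(unique(x)) < 2) {
        warning("skipping constant variable: ", v, call. = FALSE)
        return(NULL)
      }
      if (continuous_test == "wilcox") {
        ht <- suppressWarnings(wilcox.test(x ~ grp))
        data.frame(variable = v, test = "mann-whitney",
                   statistic = unname(ht$statistic), df = NA_real_,
                   p_value = ht$p.value, stringsAsFactors = FALSE)
      } else {
        ht <- t.test(x ~ grp)
        data.frame(variable = v, test = "t",
                   statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p_value = ht$p.value,
                   stringsAsFactors = FALSE)
      }
    } else {
      tab <- table(factor(x), grp)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) < 2) {
        warning("skipping single-category variable: ", v, call. = FALSE)
        return(NULL)
      }
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (fisher_when_sparse && any(expected < 5)) {
        ht <- fisher.test(tab)
        data.frame(variable = v, test = "fisher", statistic = NA_real_,
                   df = NA_real_, p_value = ht$p.value,
                   stringsAsFactors = FALSE)
      } else {
        ht <- suppressWarnings(chisq.test(tab))
        data.frame(variable = v,
                   test = if (grepl("Yates", ht$method)) "chisq-yates" else "chisq",
                   statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p_value = ht$p.value,
                   stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Table-1 style cohort summary
#'
#' Counts with within-group percentages for categorical variables;
#' mean, SD, median and IQR for continuous ones.
#'
#' @param data data.frame of covariates plus a binary group column.
#' @param group_col grouping column name (default `"label"`).
#' @param vars variables to summarise (default: all others).
#' @return list with `categorical` (variable, level, group, n, pct) and
#'   `continuous` (variable, group, mean, sd, median, q1, q3) data.frames.
#' @export
summarize_cohort <- function(data, group_col = "label", vars = NULL) {
  grp <- factor(data[[group_col]])
  vars <- vars %||% setdiff(names(data), group_col)
  cat_rows <- list(); num_rows <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x)) {
      for (g in levels(grp)) {
        xi <- x[grp == g]
        num_rows[[length(num_rows) + 1]] <- data.frame(
          variable = v, group = g, mean = mean(xi), sd = sd(xi),
          median = median(xi), q1 = unname(quantile(xi, 0.25)),
          q3 = unname(quantile(xi, 0.75)), stringsAsFactors = FALSE)
      }
    } else {
      tab <- table(factor(x), grp)
      for (g in colnames(tab)) {
        tot <- sum(tab[, g])
        for (lv in rownames(tab)) {
          cat_rows[[length(cat_rows) + 1]] <- data.frame(
            variable = v, level = lv, group = g, n = tab[lv, g],
            pct = 100 * tab[lv, g] / tot, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(categorical = do.call(rbind, cat_rows) %||% data.frame(),
       continuous = do.call(rbind, num_rows) %||% data.frame())
}
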
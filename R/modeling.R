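# Modeling layer: z-score standardization fit on the primary cohort, LASSO
# feature selection with patient-grouped 10-fold CV, an RBF-SVM tile
# classifier with calibrated probabilities, tile-to-patient mean
# aggregation, the logistic pathology score, and the multivariable
# adjustment model.

#' Fit per-feature standardization parameters
#'
#' Means and SDs are estimated on primary-cohort tiles only; validation data
#' are transformed with these parameters, never their own. Zero-variance
#' features are dropped with a warning.
#'
#' @param x numeric matrix or data.frame of features (rows = tiles).
#' @return object of class `standardization_params` (`mean`, `sd`, `features`).
#' @export
standardize_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to standardize", call. = FALSE)
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  keep <- sdev > 1e-12
  if (any(!keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "), call. = FALSE)
  }
  structure(list(mean = mu[keep], sd = sdev[keep],
                 features = colnames(x)[keep]),
            class = "standardization_params")
}

#' Apply standardization parameters
#'
#' @param params a [standardize_fit()] result.
#' @param x matrix or data.frame containing at least `params$features`.
#' @return standardized matrix restricted to the retained features.
#' @export
standardize_apply <- function(params, x) {
  stopifnot(inherits(params, "standardization_params"))
  x <- as.matrix(x)[, params$features, drop = FALSE]
  scale(x, center = params$mean, scale = params$sd)[, , drop = FALSE]
}

# Stratified fold assignment; when `groups` is given, whole groups (patients)
# are assigned to folds, stratified by the group's label.
make_fold_ids <- function(y, n_folds, groups = NULL, seed = 1) {
  withr::with_seed(as.integer(seed), {
    if (is.null(groups)) groups <- seq_along(y)
    gl <- tapply(y, groups, function(v) v[1])
    fold_of_group <- setNames(integer(length(gl)), names(gl))
    for (cls in unique(gl)) {
      g <- sample(names(gl)[gl == cls])
      fold_of_group[g] <- rep_len(seq_len(n_folds), length(g))
    }
    unname(fold_of_group[as.character(groups)])
  })
}

#' LASSO feature selection with grouped, stratified cross-validation
#'
#' L1-penalized logistic regression over a log-spaced penalty grid
#' (via \pkg{glmnet}); the penalty minimising mean CV binomial deviance is
#' chosen by default (`rule = "1se"` gives the sparser one-standard-error
#' solution). Tiles inherit their patient's outcome, so CV folds are grouped
#' by patient to prevent leakage between folds.
#'
#' @param x standardized feature matrix (rows = tiles).
#' @param y binary tile labels (factor, character, logical or 0/1).
#' @param groups patient id per tile (NULL = ungrouped).
#' @param n_folds number of CV folds (default 10).
#' @param lambda optional penalty grid (decreasing); glmnet's own by default.
#' @param rule `"min"` or `"1se"`.
#' @param seed RNG seed for fold assignment.
#' @return object of class `lasso_result`: `selected` (feature names with
#'   nonzero coefficients at the chosen penalty), `lambda`, `cvm`,
#'   `lambda_min`, `lambda_1se`, `chosen_lambda`, `coefficients`, `fit`.
#' @export
lasso_select <- function(x, y, groups = NULL, n_folds = 10, lambda = NULL,
                         rule = c("min", "1se"), seed = 1) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  yb <- as_binary_label(y)
  foldid <- make_fold_ids(yb, n_folds, groups, seed)
  cv <- glmnet::cv.glmnet(x, yb, family = "binomial", alpha = 1,
                          lambda = lambda, foldid = foldid,
                          standardize = FALSE, type.measure = "deviance")
  chosen <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- coef(cv, s = chosen)
  nz <- rownames(beta)[as.vector(beta != 0)]
  nz <- setdiff(nz, "(Intercept)")
  structure(list(selected = nz,
                 lambda = cv$lambda, cvm = cv$cvm,
                 lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
                 chosen_lambda = chosen, rule = rule,
                 coefficients = setNames(as.vector(beta), rownames(beta)),
                 fit = cv),
            class = "lasso_result")
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf("lasso_result: %d feature(s) selected at lambda = %.4g (%s rule)\n",
              length(x$selected), x$chosen_lambda, x$rule))
  invisible(x)
}

#' Train the RBF-SVM tile classifier
#'
#' Grid search over (cost, gamma) by stratified k-fold cross-validation
#' maximising out-of-fold AUC, then a final radial-kernel SVM fit (libsvm via
#' \pkg{e1071}) with Platt-scaled probability output.
#'
#' @param x standardized matrix of the selected features (rows = tiles).
#' @param y binary tile labels.
#' @param cv_folds folds for the grid search (default 5).
#' @param cost_grid,gamma_grid hyperparameter grids; defaults
#'   `2^seq(-3, 7, 2)` and `2^seq(-9, 1, 2)`.
#' @param seed RNG seed (folds and libsvm's internal Platt CV).
#' @return object of class `tile_classifier`: `model`, `cost`, `gamma`,
#'   `cv_auc`, `grid` (per-combination CV AUC), `features`, `positive`.
#' @export
train_tile_classifier <- function(x, y, cv_folds = 5,
                                  cost_grid = 2^seq(-3, 7, 2),
                                  gamma_grid = 2^seq(-9, 1, 2),
                                  seed = 1) {
  x <- as.matrix(x)
  yb <- as_binary_label(y)
  positive <- attr(yb, "positive")
  if (!length(cost_grid) || !length(gamma_grid) ||
      any(cost_grid <= 0) || any(gamma_grid <= 0)) {
    stop("cost_grid and gamma_grid must be non-empty and positive", call. = FALSE)
  }
  yf <- factor(yb, levels = c(0, 1))
  foldid <- make_fold_ids(yb, cv_folds, seed = seed)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  grid$cv_auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    oof <- rep(NA_real_, length(yb))
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      if (length(unique(yb[tr])) < 2) next
      fit <- withr::with_seed(derive_seed(seed, g * 100 + f),
        e1071::svm(x[tr, , drop = FALSE], yf[tr], kernel = "radial",
                   cost = grid$cost[g], gamma = grid$gamma[g],
                   probability = TRUE, scale = FALSE))
      pr <- attr(predict(fit, x[!tr, , drop = FALSE], probability = TRUE),
                 "probabilities")[, "1"]
      oof[!tr] <- pr
    }
    ok <- !is.na(oof)
    grid$cv_auc[g] <- compute_auc(oof[ok], yb[ok])$auc
  }
  best <- which.max(grid$cv_auc)
  model <- withr::with_seed(derive_seed(seed, 0),
    e1071::svm(x, yf, kernel = "radial", cost = grid$cost[best],
               gamma = grid$gamma[best], probability = TRUE, scale = FALSE))
  structure(list(model = model, cost = grid$cost[best],
                 gamma = grid$gamma[best], cv_auc = grid$cv_auc[best],
                 grid = grid, features = colnames(x), positive = positive),
            class = "tile_classifier")
}

#' Predict tile-level probabilities
#'
#' @param classifier a [train_tile_classifier()] result.
#' @param x matrix containing the classifier's features.
#' @return probability of the positive (poor-response) class per tile.
#' @export
predict_tile_prob <- function(classifier, x) {
  stopifnot(inherits(classifier, "tile_classifier"))
  x <- as.matrix(x)[, classifier$features, drop = FALSE]
  pr <- attr(predict(classifier$model, x, probability = TRUE), "probabilities")
  unname(pr[, "1"])
}

#' Aggregate tile probabilities to patient level
#'
#' A patient's characteristic is the arithmetic mean of the tile-classifier
#' probabilities of all of that patient's selected tiles; it is invariant to
#' tile ordering and to duplicating every tile.
#'
#' @param tile_probs numeric vector of tile probabilities in `[0, 1]`.
#' @param patient_ids patient id per tile.
#' @return data.frame: patient_id, mean_prob, n_tiles.
#' @export
aggregate_patients <- function(tile_probs, patient_ids) {
  stopifnot(length(tile_probs) == length(patient_ids))
  if (!length(tile_probs)) stop("no tiles to aggregate", call. = FALSE)
  m <- tapply(tile_probs, patient_ids, mean)
  n <- tapply(tile_probs, patient_ids, length)
  data.frame(patient_id = names(m), mean_prob = as.vector(m),
             n_tiles = as.vector(n), stringsAsFactors = FALSE,
             row.names = NULL)
}

# Ridge-penalized logistic fit used when ML fitting separates perfectly.
ridge_logistic <- function(m, y, penalty = 1e-4) {
  nll <- function(b) {
    z <- -(2 * y - 1) * (b[1] + b[2] * m)
    sum(pmax(z, 0) + log1p(exp(-abs(z)))) + penalty * sum(b^2) / 2
  }
  optim(c(0, 0), nll, method = "BFGS")$par
}

#' Fit the patient-level pathology signature
#'
#' Univariable maximum-likelihood logistic regression of outcome on the
#' patient mean tile probability; the pathology score is the fitted
#' probability `plogis(beta0 + beta1 * m)`, strictly monotone in `m` so it
#' preserves the AUC of the mean probability. Under perfect separation the
#' fit falls back to a tiny ridge penalty (1e-4) with a warning.
#'
#' @param mean_prob patient mean tile probabilities.
#' @param labels binary patient outcomes.
#' @return object of class `pathology_signature` (`beta0`, `beta1`,
#'   `separation` flag, `positive`).
#' @export
fit_signature <- function(mean_prob, labels) {
  y <- as_binary_label(labels)
  if (min(table(y)) < 2) stop("need >= 2 patients per class", call. = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ mean_prob, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || !fit$converged || any(abs(coef(fit)) > 50)) {
    warning("perfect separation in signature fit; using ridge penalty 1e-4",
            call. = FALSE)
    b <- ridge_logistic(mean_prob, y)
    separated <- TRUE
  } else {
    b <- unname(coef(fit))
  }
  structure(list(beta0 = b[1], beta1 = b[2], separation = separated,
                 positive = attr(y, "positive")),
            class = "pathology_signature")
}

#' Pathology score of a patient mean probability
#'
#' @param signature a [fit_signature()] result.
#' @param mean_prob patient mean tile probability (vectorised).
#' @return pathology score(s) in (0, 1).
#' @export
pathology_score <- function(signature, mean_prob) {
  stopifnot(inherits(signature, "pathology_signature"))
  plogis(signature$beta0 + signature$beta1 * mean_prob)
}

#' Multivariable logistic adjustment model
#'
#' Logistic regression of outcome on age, gender, T stage, N stage, CEA level
#' and the pathology score, with fixed reference categories (male, T3, N0,
#' CEA normal). Collinear columns abort with an error naming them.
#'
#' @param data data.frame with columns `label`, `age`, `gender`, `t_stage`,
#'   `n_stage`, `cea` and the score column.
#' @param score_col name of the pathology-score column.
#' @return object of class `multivariable_model`: `table` (term, estimate,
#'   odds_ratio, se, z, p_value) and `fit`.
#' @export
fit_multivariable <- function(data, score_col = "pathology_score") {
  needed <- c("label", "age", "gender", "t_stage", "n_stage", "cea", score_col)
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- data[complete.cases(data[needed]), needed]
  df$y <- as_binary_label(df$label)
  relevel_safe <- function(v, ref) {
    f <- factor(v)
    if (ref %in% levels(f)) stats::relevel(f, ref = ref) else f
  }
  df$gender <- relevel_safe(df$gender, "male")
  df$t_stage <- relevel_safe(df$t_stage, "T3")
  df$n_stage <- relevel_safe(df$n_stage, "N0")
  df$cea <- relevel_safe(df$cea, "normal")
  form <- stats::as.formula(paste("y ~ age + gender + t_stage + n_stage + cea +",
                                  score_col))
  mm <- stats::model.matrix(form, df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("collinear column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(glm(form, family = binomial(), data = df))
  s <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(s), estimate = s[, 1],
                    odds_ratio = exp(s[, 1]), se = s[, 2], z = s[, 3],
                    p_value = s[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, fit = fit), class = "multivariable_model")
}
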
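#' Build a feature matrix for impairment classification
#'
#' Selects the normal-speed sessions, joins the impairment label (clinician
#' gait-item rating > 0) and assembles the requested feature set: insole-only
#' (the per-cycle temporal feature aggregates), IMU-only (the single-sensor
#' temporal + energy/asymmetry set), or their combination. Columns that are
#' constant or entirely missing are dropped; remaining missing values are
#' median-imputed. Standardisation is deliberately NOT applied here - it is
#' fitted inside training folds during cross-validation to avoid leakage.
#'
#' @param insole_features,imu_features per-session feature tables.
#' @param manifest the cohort manifest.
#' @param set `"insole"`, `"imu"` or `"combined"`.
#' @param speed which speed class to keep (default `"normal"`).
#' @return object of class `feature_matrix`: list with `x` (numeric matrix),
#'   `y` (logical impaired), `groups` (subject ids), `session_id`, `set`.
#' @export
build_feature_table <- function(insole_features, imu_features, manifest,
                                set = c("insole", "imu", "combined"),
                                speed = "normal") {
  set <- match.arg(set)
  man <- manifest[manifest$speed == speed, , drop = FALSE]
  if (nrow(man) == 0L) stop("no sessions at speed '", speed, "'", call. = FALSE)
  pick <- function(tab, prefix) {
    m <- tab[match(man$session_id, tab$session_id), , drop = FALSE]
    x <- as.matrix(m[, setdiff(names(m), "session_id"), drop = FALSE])
    colnames(x) <- paste0(prefix, colnames(x))
    x
  }
  x <- switch(set,
    insole = pick(insole_features, "ins_"),
    imu = pick(imu_features, "imu_"),
    combined = cbind(pick(insole_features, "ins_"),
                     pick(imu_features, "imu_")))
  # drop all-missing / constant columns, impute the rest by the median
  keep <- apply(x, 2L, function(v) sum(is.finite(v)) >= 2L &&
                  stats::sd(v, na.rm = TRUE) > 0)
  x <- x[, keep, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) x[bad, j] <- stats::median(x[, j], na.rm = TRUE)
  }
  if (ncol(x) == 0L) stop("empty feature selection", call. = FALSE)
  structure(list(x = x, y = man$impaired, groups = man$subject_id,
                 session_id = man$session_id, set = set),
            class = "feature_matrix")
}

# Subject-grouped, stratified fold assignment: subjects are stratified by
# whether they contribute any unimpaired session, shuffled within stratum,
# and dealt round-robin so each fold sees both classes where possible.
make_group_folds <- function(y, groups, k = 5L, seed = 1L) {
  subj <- unique(groups)
  has_neg <- vapply(subj, function(s) any(!y[groups == s]), logical(1))
  with_seed(seed, {
    fold_of <- integer(length(subj))
    names(fold_of) <- subj
    slot <- 0L
    for (stratum in list(subj[has_neg], subj[!has_neg])) {
      stratum <- sample(stratum)
      for (s in stratum) {
        fold_of[s] <- (slot %% k) + 1L
        slot <- slot + 1L
      }
    }
    fold_of[groups]
  })
}

# --- the four classifiers, each exposing fit(x, y) and predict_prob(model, x)

fit_one_model <- function(name, x, y, seed) {
  yf <- factor(y, levels = c(FALSE, TRUE), labels = c("no", "yes"))
  with_seed(seed, switch(name,
    svm = e1071::svm(x, yf, kernel = "radial", cost = 1, probability = TRUE),
    rf = randomForest::randomForest(x, yf, ntree = 100),
    gb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.1, max_depth = 3,
                    tree_method = "exact", nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1),
      nrounds = 100, verbose = 0),
    ab = adaboost_fit(x, y, n_iter = 50),
    stop("unknown classifier: ", name)))
}

predict_prob <- function(name, model, x) {
  switch(name,
    svm = {
      pr <- attr(stats::predict(model, x, probability = TRUE), "probabilities")
      pr[, "yes"]
    },
    rf = stats::predict(model, x, type = "prob")[, "yes"],
    gb = stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1)),
    ab = adaboost_prob(model, x))
}

# SAMME AdaBoost over depth-1 rpart stumps (binary case: alpha = log((1-e)/e)).
adaboost_fit <- function(x, y, n_iter = 50) {
  n <- nrow(x)
  yy <- ifelse(y, 1, -1)
  w <- rep(1 / n, n)
  df <- data.frame(x, check.names = FALSE)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_iter)) {
    fit <- rpart::rpart(yy ~ ., data = cbind(yy = factor(yy), df), weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2,
                                                       xval = 0))
    pred <- as.numeric(as.character(stats::predict(fit, df, type = "class")))
    err <- sum(w[pred != yy])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  structure(list(stumps = stumps, alphas = alphas), class = "dualgait_adaboost")
}

adaboost_score <- function(model, x) {
  df <- data.frame(x, check.names = FALSE)
  f <- numeric(nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- as.numeric(as.character(
      stats::predict(model$stumps[[m]], df, type = "class")))
    f <- f + model$alphas[m] * pred
  }
  f
}

adaboost_prob <- function(model, x) 1 / (1 + exp(-2 * adaboost_score(model, x)))

binary_metrics <- function(y, prob) {
  pred <- prob >= 0.5
  tp <- sum(pred & y); fp <- sum(pred & !y)
  fn <- sum(!pred & y); tn <- sum(!pred & !y)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  auc <- if (length(unique(y)) == 2L)
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                   levels = c(FALSE, TRUE),
                                   direction = "<", quiet = TRUE)))
  else NA_real_
  c(auc = auc, accuracy = (tp + tn) / length(y), f1 = f1,
    precision = precision, recall = recall)
}

#' Cross-validated impairment classification
#'
#' Evaluates the four classifiers (radial-kernel SVM, random forest, gradient
#' boosting, AdaBoost over decision stumps) under subject-grouped stratified
#' k-fold cross-validation. Features are z-scored with means/SDs fitted on
#' the training fold only. Threshold metrics (accuracy, F1, precision,
#' recall, with "impaired" as the positive class) are computed on the pooled
#' held-out predictions; AUC is the mean over fold-level AUCs (computable
#' folds only), since pooling mixes per-fold probability scales and can
#' depress the AUC of a perfectly ranked classifier. Fold-level AUC
#' dispersion is reported alongside. Folds whose training part is single-class are refolded with a
#' warning (fresh seed), up to 10 attempts.
#'
#' @param fm a [build_feature_table()] result.
#' @param classifiers subset of `c("svm", "rf", "gb", "ab")`.
#' @param k number of folds.
#' @param seed seed fixing fold assignment and model randomness.
#' @return object of class `classification_report`: `metrics` (one row per
#'   classifier), `predictions` (pooled held-out probabilities), `folds`.
#' @export
evaluate_classifiers <- function(fm, classifiers = c("svm", "rf", "gb", "ab"),
                                 k = 5L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$x; y <- fm$y
  if (length(unique(y)) < 2L)
    stop("need both classes present for classification", call. = FALSE)
  folds <- NULL
  for (attempt in 0:9) {
    cand <- make_group_folds(y, fm$groups, k = k, seed = seed + attempt)
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[cand != f])) == 2L, logical(1)))
    if (ok) { folds <- cand; break }
    warning("single-class training fold; refolding with a new seed")
  }
  if (is.null(folds))
    stop("could not build folds with both classes in every training set",
         call. = FALSE)

  prob <- matrix(NA_real_, nrow = length(y), ncol = length(classifiers),
                 dimnames = list(NULL, classifiers))
  fold_auc <- matrix(NA_real_, nrow = k, ncol = length(classifiers),
                     dimnames = list(NULL, classifiers))
  for (f in seq_len(k)) {
    tr <- folds != f
    if (!any(!tr)) next
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sg[sg == 0] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2L, mu), 2L, sg, "/")
    xte <- sweep(sweep(x[!tr, , drop = FALSE], 2L, mu), 2L, sg, "/")
    for (cl in classifiers) {
      model <- fit_one_model(cl, xtr, y[tr], seed = seed + f)
      p <- predict_prob(cl, model, xte)
      prob[!tr, cl] <- p
      if (length(unique(y[!tr])) == 2L)
        fold_auc[f, cl] <- binary_metrics(y[!tr], p)[["auc"]]
    }
  }
  metrics <- do.call(rbind, lapply(classifiers, function(cl) {
    m <- binary_metrics(y, prob[, cl])
    if (any(is.finite(fold_auc[, cl])))
      m[["auc"]] <- mean(fold_auc[, cl], na.rm = TRUE)
    data.frame(classifier = cl, t(m),
               auc_fold_sd = stats::sd(fold_auc[, cl], na.rm = TRUE))
  }))
  structure(list(metrics = metrics, predictions = prob, folds = folds,
                 set = fm$set, k = k, seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 3, ...) {
  cat(sprintf("Impairment classification (%s features, %d-fold grouped CV):\n",
              x$set, x$k))
  m <- x$metrics
  m[, -1] <- round(m[, -1], digits)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Permutation feature importance on held-out folds
#'
#' Model-agnostic importance: within each cross-validation fold a model is
#' fitted on the training part and the increase in held-out log-loss (mean
#' binomial deviance) is measured when one feature column is permuted
#' (averaged over `n_repeats` permutations). Log-loss rather than AUC is
#' scored because it stays sensitive when the classifier separates the
#' classes perfectly and is defined on single-class held-out folds.
#' Importances are averaged over folds and over `n_seeds` repetitions of the
#' whole cross-validation (fresh fold assignment and model seed each time;
#' permutation rankings among correlated features are otherwise unstable),
#' then returned ranked. Constant features receive importance 0. This is the default, deterministic-contract engine;
#' for the gradient-boosting model xgboost's native TreeSHAP values are also
#' available via `engine = "shap_gb"`.
#'
#' @param fm a [build_feature_table()] result.
#' @param classifier which model to explain (default random forest).
#' @param engine `"permutation"` or `"shap_gb"` (xgboost TreeSHAP; implies
#'   `classifier = "gb"`).
#' @param k folds.
#' @param n_repeats permutations per feature and fold.
#' @param n_seeds cross-validation repetitions averaged into the ranking.
#' @param seed seed.
#' @return data.frame with columns `feature`, `importance`, sorted
#'   decreasing.
#' @export
feature_importance <- function(fm, classifier = "rf",
                               engine = c("permutation", "shap_gb"),
                               k = 5L, n_repeats = 3L, n_seeds = 3L,
                               seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  engine <- match.arg(engine)
  x <- fm$x; y <- fm$y
  if (engine == "shap_gb") {
    model <- fit_one_model("gb", x, y, seed = seed)
    contrib <- stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1),
                              predcontrib = TRUE)
    imp <- colMeans(abs(contrib[, colnames(x), drop = FALSE]))
    out <- data.frame(feature = names(imp), importance = as.numeric(imp))
    return(out[order(-out$importance), , drop = FALSE])
  }
  log_loss <- function(y, p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(ifelse(y, log(p), log(1 - p)))
  }
  one_repetition <- function(seed) {
  folds <- make_group_folds(y, fm$groups, k = k, seed = seed)
  imp_mat <- matrix(0, nrow = k, ncol = ncol(x),
                    dimnames = list(NULL, colnames(x)))
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- which(!tr)
    if (length(unique(y[tr])) < 2L || length(te) == 0L) next
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sg[sg == 0] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2L, mu), 2L, sg, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2L, mu), 2L, sg, "/")
    model <- fit_one_model(classifier, xtr, y[tr], seed = seed + f)
    base_ll <- log_loss(y[te], predict_prob(classifier, model, xte))
    with_seed(seed + 100L + f, {
      for (j in seq_len(ncol(x))) {
        if (stats::sd(xte[, j]) == 0) next
        drops <- numeric(n_repeats)
        for (r in seq_len(n_repeats)) {
          xp <- xte
          xp[, j] <- sample(xp[, j])
          drops[r] <- log_loss(y[te], predict_prob(classifier, model, xp)) - base_ll
        }
        imp_mat[f, j] <- mean(drops)
      }
    })
  }
  colMeans(imp_mat)
  }
  imp <- rowMeans(vapply(seq_len(n_seeds),
                         function(i) one_repetition(seed + (i - 1L) * 1000L),
                         numeric(ncol(x))))
  out <- data.frame(feature = colnames(x), importance = as.numeric(imp))
  out[order(-out$importance), , drop = FALSE]
}
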
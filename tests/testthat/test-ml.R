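test_that("feature-set selectors control which system's columns are present", {
  co <- ml_cohort(1)
  ins <- build_feature_table(co$insole, co$imu, co$manifest, set = "insole")
  expect_true(all(startsWith(colnames(ins$x), "ins_")))
  imu <- build_feature_table(co$insole, co$imu, co$manifest, set = "imu")
  expect_true(all(startsWith(colnames(imu$x), "imu_")))
  comb <- build_feature_table(co$insole, co$imu, co$manifest, set = "combined")
  expect_true(any(startsWith(colnames(comb$x), "ins_")) &&
                any(startsWith(colnames(comb$x), "imu_")))
  # 19 subjects x 2 states x 2 reps at normal speed
  expect_lte(nrow(ins$x), 76)
  expect_false(any(!is.finite(ins$x)))
  # labels follow the rating threshold
  man <- co$manifest[co$manifest$speed == "normal", ]
  expect_identical(ins$y, man$rating > 0)
})

test_that("a perfectly separable toy problem yields AUC 1 for all four classifiers", {
  rep <- evaluate_classifiers(toy_matrix(), seed = 3)
  expect_equal(rep$metrics$auc, rep(1, 4))
  expect_setequal(rep$metrics$classifier, c("svm", "rf", "gb", "ab"))
  expect_true(all(rep$metrics$accuracy > 0.9))
})

test_that("cross-validation folds never split a subject across train and test", {
  fm <- toy_matrix()
  rep <- evaluate_classifiers(fm, classifiers = "rf", seed = 2)
  split_subjects <- tapply(rep$folds, fm$groups, function(f) length(unique(f)))
  expect_true(all(split_subjects == 1))
})

test_that("classification demands two classes", {
  fm <- toy_matrix()
  fm$y <- rep(TRUE, length(fm$y))
  expect_error(evaluate_classifiers(fm), "both classes")
})

test_that("the label-defining feature ranks first in permutation importance", {
  imp <- feature_importance(toy_matrix(n = 80), classifier = "rf", seed = 4)
  expect_equal(imp$feature[1], "f1")
  expect_gt(imp$importance[1], 5 * max(abs(imp$importance[-1])))
})

test_that("labels independent of all features give importances near zero", {
  fm <- toy_matrix(n = 80)
  set.seed(9)
  fm$y <- sample(fm$y)
  imp <- feature_importance(fm, classifier = "rf", seed = 4)
  expect_lt(max(abs(imp$importance)), 0.2)
})

test_that("fixed seeds reproduce the classification report exactly", {
  co <- ml_cohort(1)
  fm <- build_feature_table(co$insole, co$imu, co$manifest, set = "imu")
  a <- evaluate_classifiers(fm, classifiers = c("rf", "ab"), seed = 6)
  b <- evaluate_classifiers(fm, classifiers = c("rf", "ab"), seed = 6)
  expect_identical(a$metrics, b$metrics)
})

test_that("detection performance rises with the simulated impairment effect", {
  auc_at <- function(effect) {
    co <- ml_cohort(effect)
    fm <- build_feature_table(co$insole, co$imu, co$manifest, set = "insole")
    mean(vapply(1:3, function(s)
      evaluate_classifiers(fm, classifiers = "rf", seed = s)$metrics$auc,
      numeric(1)))
  }
  a0 <- auc_at(0)
  a1 <- auc_at(1)
  a3 <- auc_at(3)
  expect_lt(a0, 0.75)           # no effect -> near chance
  expect_gt(a3, 0.85)           # strong effect -> high discrimination
  expect_gte(a1 + 0.05, a0)     # non-decreasing up to simulation noise
  expect_gte(a3 + 0.05, a1)
})
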
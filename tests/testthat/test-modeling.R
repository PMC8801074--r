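test_that("leave-lot-out folds hold out whole lots", {
  lot <- rep(sprintf("L%02d", 1:11), each = 12) # 3 wells x 4 FOVs
  folds <- leaveLotOutSplits(lot)
  expect_length(folds, 11)
  for (f in folds) {
    expect_length(f$test, 12)
    expect_equal(sort(c(f$train, f$test)), seq_along(lot))
    expect_false(any(lot[f$train] == f$lot))
    expect_true(all(lot[f$test] == f$lot))
  }
  f2 <- leaveLotOutSplits(c("a", "a", "b"))
  expect_length(f2, 2)
  expect_equal(f2[[1]]$test, f2[[2]]$train)
  expect_error(leaveLotOutSplits(rep("a", 5)), ">= 2 distinct lots")
})

test_that("standardization uses training statistics only", {
  set.seed(3)
  Xtr <- matrix(rnorm(60, 5, 2), 12, 5)
  sc <- standardizeTrainTest(Xtr, Xtr)
  expect_equal(colMeans(sc$train), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(sc$train, 2, sd), rep(1, 5), tolerance = 1e-12)
  # constant feature passes through centered
  Xtr[, 3] <- 7
  sc2 <- standardizeTrainTest(Xtr, Xtr)
  expect_true(all(sc2$train[, 3] == 0))
  # leakage probe: a shifted test set keeps the train-estimated offset;
  # pooled statistics would remove it
  Xte <- Xtr + 10
  sc3 <- standardizeTrainTest(Xtr, Xte)
  expect_gt(min(colMeans(sc3$test)[-3]), 3) # offset preserved
  pooled <- scale(rbind(Xtr, Xte))
  expect_lt(abs(mean(pooled)), 1e-12) # what leakage would have produced
})

test_that("kNN equals the exhaustive brute-force oracle", {
  set.seed(5)
  for (rep in 1:5) {
    Xtr <- matrix(rnorm(40 * 6), 40, 6)
    ytr <- rep(c(0, 1), 20)
    Xte <- matrix(rnorm(50 * 6), 50, 6)
    got <- fitPredictClassifier("kNN", Xtr, ytr, Xte,
                                lot_tr = rep(letters[1:8], each = 5),
                                hyper = list(k = 5))$pred
    expect_identical(got, bf_knn(Xtr, ytr, Xte, 5))
  }
  # k = 1 on a duplicated training point returns that point's label
  Xtr <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  got <- fitPredictClassifier("kNN", Xtr, c(1, 0), Xtr,
                              lot_tr = c("a", "b"), hyper = list(k = 1))$pred
  expect_equal(got, c(1, 0))
  expect_error(
    fitPredictClassifier("kNN", Xtr, c(1, 1), Xtr, lot_tr = c("a", "b")),
    "single-class")
})

test_that("LASSO classifies separable data perfectly and reports folds", {
  dm <- make_separable_dm()
  # the toy fixture is tiny; glmnet warns about small class counts
  rep <- suppressWarnings(runLeaveLotOut(dm, "LASSO", seed = 1))
  expect_equal(unname(rep@metrics["accuracy"]), 1)
  expect_length(rep@lassoFolds, 6)
  lr <- lassoReport(rep)
  expect_equal(lr$feature[1], "f1") # the separating feature leads
  expect_equal(lr$n_selected[1], 6) # selected in every fold
  expect_true(all(lr$n_selected <= 6))
  expect_equal(sum(lr$top), 6) # only 6 features exist
  expect_error(lassoReport(runLeaveLotOut(dm, "kNN")), "LASSO")
})

test_that("regressors fit trivial and sparse targets", {
  set.seed(11)
  n <- 60
  lot <- rep(sprintf("L%d", 1:10), each = 6)
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:5)))
  # constant target: intercept-only under full shrinkage
  dmc <- new("DesignMatrix", X = X, lot = lot, y = rep(3.3, n),
             task = "regression")
  repc <- runLeaveLotOut(dmc, "LASSO")
  expect_equal(unname(repc@predictions$pred), rep(3.3, n), tolerance = 1e-6)
  # exact linear function of one feature: near-zero RMSE, support recovered
  y <- 2 * X[, 2] + 1
  dml <- new("DesignMatrix", X = X, lot = lot, y = y, task = "regression")
  repl <- runLeaveLotOut(dml, "LASSO")
  # lambda.min keeps a little shrinkage: near-zero against sd(y) ~ 2
  expect_lt(unname(repl@metrics["rmse"]), 0.1)
  lr <- lassoReport(repl)
  expect_equal(lr$feature[1], "f2")
  expect_equal(lr$n_selected[1], 10)
  # RF predicts a realizable smooth target reasonably
  repr <- runLeaveLotOut(dml, "RF", hyper = list(ntree = 100), seed = 2)
  expect_lt(unname(repr@metrics["rmse"]), sd(y))
})

test_that("classification metrics follow the confusion-matrix arithmetic", {
  # all predicted Low-risk on the 7:4 lot panel (84 pos / 48 neg)
  truth <- rep(c(1, 0), c(84, 48))
  sc <- scoreClassification(truth, rep(1, 132))
  expect_equal(unname(sc$metrics["accuracy"]), 84 / 132)
  expect_equal(unname(sc$metrics["specificity"]), 0)
  # mixed confusion: TP=80 FN=4 TN=44 FP=4
  pred <- c(rep(1, 80), rep(0, 4), rep(0, 44), rep(1, 4))
  sc2 <- scoreClassification(truth, pred)
  expect_equal(unname(sc2$metrics["accuracy"]), 124 / 132)
  expect_equal(unname(sc2$metrics["precision"]), 80 / 84)
  expect_equal(unname(sc2$metrics["specificity"]), 44 / 48)
  expect_equal(sum(sc2$confusion), 132)
  # perfect predictions
  sc3 <- scoreClassification(truth, truth)
  expect_equal(unname(sc3$metrics), c(1, 1, 1))
  expect_error(scoreClassification(numeric(), numeric()), "no predictions")
})

test_that("the sweep enumerates its factorial grid", {
  panel <- generateLotPanel(3, 3, seed = 31)
  cells <- simulateTimecourse(panel, n_wells = 2, n0_cells = 120, seed = 31)
  prof <- assembleProfiles(aggregateFrames(cells, min_cells = 20))
  y <- riskToLabel(riskClass(panel))
  names(y) <- lotIds(panel)
  reps <- suppressWarnings(
    sweepModels(prof, y, "classification",
                methods = c("kNN", "LASSO"),
                modes = c("only_SD", "without_SD"),
                window_ends = c(24, 96), seed = 1))
  expect_length(reps, 2 * 2 * 2)
  smry <- cvSummary(reps)
  expect_setequal(unique(smry$window_end_h), c(24, 96))
  expect_true(all(c("accuracy", "precision", "specificity") %in% smry$metric))
  # window 12 h with only_SD leaves 16 features
  dm <- buildDesignMatrix(
    windowProfile(subsetParameters(prof, "only_SD"), 12), y,
    "classification")
  expect_equal(ncol(dm@X), 16)
  expect_error(sweepModels(prof, y, "classification", window_ends = 17),
               "scheduled")
})
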
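#' DesignMatrix: samples x flattened profile features
#'
#' Rows are samples (FOV pseudo-samples for classification, wells for
#' regression), columns are parameter x time features from a flattened
#' \code{\link{MorphProfileSet}}. \code{y} holds the teacher signal: the risk
#' label coded 0 = High-risk, 1 = Low-risk, or the fold-change growth rate.
#'
#' @slot X Numeric matrix without missing entries.
#' @slot lot Lot id per row (the cross-validation grouping unit).
#' @slot y Numeric teacher signal per row.
#' @slot task \code{"classification"} or \code{"regression"}.
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", lot = "character", y = "numeric",
                 task = "character"))

setValidity("DesignMatrix", function(object) {
  msg <- character()
  if (anyNA(object@X)) msg <- c(msg, "X must have no missing entries")
  if (length(object@lot) != nrow(object@X))
    msg <- c(msg, "lot must have one entry per row")
  if (length(object@y) != nrow(object@X))
    msg <- c(msg, "y must have one entry per row")
  if (!object@task %in% c("classification", "regression"))
    msg <- c(msg, "task must be classification or regression")
  if (object@task == "classification" && !all(object@y %in% c(0, 1)))
    msg <- c(msg, "classification y must be coded 0 (High) / 1 (Low)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix:", nrow(object@X), "samples x", ncol(object@X),
      "features;", length(unique(object@lot)), "lots;",
      object@task, "\n")
})

#' Risk classes to the numeric label coding
#'
#' @param risk Character vector of \code{"Low"} / \code{"High"}.
#' @return Numeric labels: 0 for High-risk lots, 1 for Low-risk lots.
#' @export
riskToLabel <- function(risk) as.numeric(risk == "Low")

#' Build a design matrix from a profile set
#'
#' Flattens a \code{\link{MorphProfileSet}} (possibly already subset by
#' \code{\link{subsetParameters}} and \code{\link{windowProfile}}) into a
#' samples x features matrix and attaches the teacher signal.
#'
#' @param x A \code{\link{MorphProfileSet}}.
#' @param y Teacher signal: a vector named by sample id, or named by lot id
#'   (each sample then inherits its lot's value).
#' @param task \code{"classification"} (y must be 0/1, 1 = Low-risk) or
#'   \code{"regression"}.
#' @return A \code{\link{DesignMatrix}}.
#' @export
buildDesignMatrix <- function(x, y,
                              task = c("classification", "regression")) {
  task <- match.arg(task)
  X <- t(SummarizedExperiment::assay(x, "profile"))
  cd <- SummarizedExperiment::colData(x)
  sid <- rownames(cd)
  lot <- as.character(cd$lot)
  yv <- if (all(sid %in% names(y))) unname(y[sid])
        else if (all(lot %in% names(y))) unname(y[lot])
        else stop("y must be named by sample ids or lot ids")
  rownames(X) <- sid
  new("DesignMatrix", X = X, lot = lot, y = as.numeric(yv), task = task)
}

#' Leave-lot-out cross-validation folds
#'
#' One fold per distinct lot; all rows of that lot (every well and FOV
#' pseudo-sample) form the test set, so pseudo-samples never straddle the
#' train/test boundary of their lot.
#'
#' @param dm A \code{\link{DesignMatrix}} (or just a character vector of lot
#'   ids per row).
#' @return List of folds, each a list \code{(lot, train, test)} of row
#'   indices.
#' @export
leaveLotOutSplits <- function(dm) {
  lot <- if (is(dm, "DesignMatrix")) dm@lot else as.character(dm)
  lots <- unique(lot)
  if (length(lots) < 2) stop("need >= 2 distinct lots for leave-lot-out CV")
  lapply(lots, function(l)
    list(lot = l, train = which(lot != l), test = which(lot == l)))
}

# Per-feature z-scoring with train-estimated statistics only (no leakage);
# zero-SD features are centered and passed through.
.standardize <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

#' Standardize train/test feature matrices
#'
#' Exposed form of the fold-internal z-scoring: means and SDs are estimated
#' on the training rows only and applied to both matrices; zero-SD features
#' are centered and passed through unscaled.
#'
#' @param Xtr,Xte Training and test matrices with matching columns.
#' @return List with elements \code{train} and \code{test}.
#' @export
standardizeTrainTest <- function(Xtr, Xte) .standardize(Xtr, Xte)

# deterministic kNN: Euclidean distances, distance ties broken by smaller
# training-row index, majority vote (k odd -> no vote ties in binary tasks)
.knnPredict <- function(Xtr, ytr, Xte, k = 5) {
  k <- min(k, nrow(Xtr))
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  apply(d2, 1, function(dr) {
    nn <- order(dr, seq_along(dr))[seq_len(k)]
    v <- ytr[nn]
    as.numeric(sum(v == 1) > sum(v == 0))
  })
}

# inner-CV fold ids grouped by lot; for classification additionally
# stratified so every inner training set keeps both classes
.innerFoldIds <- function(lot, y = NULL, nfolds = 3) {
  lots <- sort(unique(lot))
  fid <- integer(length(lots))
  if (is.null(y)) {
    fid <- (seq_along(lots) - 1L) %% nfolds + 1L
  } else {
    cls <- vapply(lots, function(l) y[match(l, lot)], numeric(1))
    for (cl in unique(cls)) {
      i <- which(cls == cl)
      fid[i] <- (seq_along(i) - 1L) %% nfolds + 1L
    }
    # stratification can starve folds on tiny panels; fall back to plain
    # cyclic assignment over lots, then over rows, to keep >= 3 inner folds
    if (length(unique(fid)) < min(nfolds, 3) && length(lots) >= 3)
      fid <- (seq_along(lots) - 1L) %% nfolds + 1L
  }
  out <- fid[match(lot, lots)]
  if (length(unique(out)) < min(nfolds, 3))
    out <- (seq_along(lot) - 1L) %% min(nfolds, 3L) + 1L
  out
}

#' Fit a classifier on one fold and predict the held-out lot
#'
#' The three learners compared for risk classification: \code{"kNN"}
#' (majority vote over the k = 5 nearest training rows by Euclidean
#' distance, distance ties broken by smaller row index), \code{"LASSO"}
#' (L1-penalised logistic regression, lambda chosen by inner 3-fold CV
#' grouped by lot and stratified by class) and \code{"RF"} (500 trees,
#' sqrt(p) features per split).
#'
#' @param method \code{"kNN"}, \code{"LASSO"} or \code{"RF"}.
#' @param Xtr,ytr Standardized training matrix and 0/1 labels.
#' @param Xte Standardized test matrix.
#' @param lot_tr Lot id per training row (for the inner CV).
#' @param hyper Named list overriding defaults: \code{k}, \code{ntree},
#'   \code{mtry}, \code{nlambda}.
#' @param seed Seed for the seed-controlled learners (RF).
#' @return List: \code{pred} (numeric 0/1 per test row) and \code{coef}
#'   (named coefficient vector, LASSO only, else NULL).
#' @export
fitPredictClassifier <- function(method, Xtr, ytr, Xte, lot_tr,
                                 hyper = list(), seed = 1) {
  if (length(unique(ytr)) < 2)
    stop("single-class training fold (lots: ",
         paste(unique(lot_tr), collapse = ", "), ")")
  method <- match.arg(method, c("kNN", "LASSO", "RF"))
  if (method == "kNN") {
    k <- hyper$k %||% 5
    return(list(pred = .knnPredict(Xtr, ytr, Xte, k), coef = NULL))
  }
  if (method == "LASSO") {
    foldid <- .innerFoldIds(lot_tr, ytr, hyper$nfolds %||% 3)
    set.seed(seed)
    fit <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = 1,
                             foldid = foldid,
                             nlambda = hyper$nlambda %||% 100,
                             standardize = FALSE)
    pred <- as.numeric(predict(fit, Xte, s = "lambda.min", type = "class"))
    cf <- as.matrix(stats::coef(fit, s = "lambda.min"))
    return(list(pred = pred, coef = setNames(cf[, 1], rownames(cf))))
  }
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = Xtr, y = factor(ytr, levels = c(0, 1)),
    ntree = hyper$ntree %||% 500,
    mtry = hyper$mtry %||% max(1, floor(sqrt(ncol(Xtr)))))
  list(pred = as.numeric(as.character(predict(fit, Xte))), coef = NULL)
}

#' Fit a regressor on one fold and predict the held-out lot
#'
#' \code{"LASSO"} is L1-penalised linear regression with inner lot-grouped
#' 3-fold lambda selection; \code{"RF"} a 500-tree random forest.
#' Predictions are left unclipped.
#'
#' @inheritParams fitPredictClassifier
#' @param ytr Numeric training targets (growth rates).
#' @return List: \code{pred}, \code{coef} (LASSO only).
#' @export
fitPredictRegressor <- function(method, Xtr, ytr, Xte, lot_tr,
                                hyper = list(), seed = 1) {
  method <- match.arg(method, c("LASSO", "RF"))
  if (method == "LASSO") {
    if (sd(ytr) == 0) # fully shrunk: intercept-only model
      return(list(pred = rep(mean(ytr), nrow(Xte)),
                  coef = setNames(c(mean(ytr), numeric(ncol(Xtr))),
                                  c("(Intercept)", colnames(Xtr)))))
    foldid <- .innerFoldIds(lot_tr, NULL, hyper$nfolds %||% 3)
    set.seed(seed)
    fit <- glmnet::cv.glmnet(Xtr, ytr, family = "gaussian", alpha = 1,
                             foldid = foldid,
                             nlambda = hyper$nlambda %||% 100,
                             standardize = FALSE)
    pred <- as.numeric(predict(fit, Xte, s = "lambda.min"))
    cf <- as.matrix(stats::coef(fit, s = "lambda.min"))
    return(list(pred = pred, coef = setNames(cf[, 1], rownames(cf))))
  }
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = Xtr, y = ytr,
    ntree = hyper$ntree %||% 500,
    mtry = hyper$mtry %||% max(1, floor(sqrt(ncol(Xtr)))))
  list(pred = as.numeric(predict(fit, Xte)), coef = NULL)
}

#' Classification metrics from pooled held-out predictions
#'
#' Positive class = Low-risk (label 1, following the 0 = High / 1 = Low
#' coding). Precision = TP / (TP + FP), specificity = TN / (TN + FP). The
#' confusion matrix is returned so either convention can be recomputed.
#'
#' @param truth,pred Numeric 0/1 vectors pooled over all folds.
#' @return List: \code{metrics} (accuracy, precision, specificity) and
#'   \code{confusion} (2 x 2 matrix, truth in rows).
#' @export
scoreClassification <- function(truth, pred) {
  if (!length(pred)) stop("no predictions to score")
  tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
  tn <- sum(truth == 0 & pred == 0); fn <- sum(truth == 1 & pred == 0)
  cm <- matrix(c(tn, fp, fn, tp), 2, 2,
               dimnames = list(truth = c("High(0)", "Low(1)"),
                               pred = c("High(0)", "Low(1)")))
  list(metrics = c(
    accuracy = (tp + tn) / length(truth),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    confusion = cm)
}

#' Run one leave-lot-out cross-validation
#'
#' Per fold: z-score features on the training lots only, fit the learner,
#' predict the held-out lot; pool held-out predictions over all folds and
#' compute pooled metrics.
#'
#' @param dm A \code{\link{DesignMatrix}}.
#' @param method Learner name (see \code{\link{fitPredictClassifier}} /
#'   \code{\link{fitPredictRegressor}}).
#' @param hyper Hyperparameter overrides.
#' @param seed Seed forwarded to seed-controlled learners.
#' @param parameterMode,windowEndH Metadata recorded in the report.
#' @return A \code{\link{CVReport}}.
#' @export
runLeaveLotOut <- function(dm, method, hyper = list(), seed = 1,
                           parameterMode = NA_character_,
                           windowEndH = NA_real_) {
  folds <- leaveLotOutSplits(dm)
  preds <- numeric(nrow(dm@X))
  foldlab <- character(nrow(dm@X))
  lassoFolds <- list()
  for (f in folds) {
    sc <- .standardize(dm@X[f$train, , drop = FALSE],
                       dm@X[f$test, , drop = FALSE])
    res <- if (dm@task == "classification")
      fitPredictClassifier(method, sc$train, dm@y[f$train], sc$test,
                           dm@lot[f$train], hyper, seed)
    else
      fitPredictRegressor(method, sc$train, dm@y[f$train], sc$test,
                          dm@lot[f$train], hyper, seed)
    preds[f$test] <- res$pred
    foldlab[f$test] <- f$lot
    if (!is.null(res$coef)) lassoFolds[[f$lot]] <- res$coef
  }
  if (dm@task == "classification") {
    sc <- scoreClassification(dm@y, preds)
    metrics <- sc$metrics; confusion <- sc$confusion
  } else {
    metrics <- c(rmse = sqrt(mean((preds - dm@y)^2)))
    confusion <- matrix(numeric(), 0, 0)
  }
  new("CVReport", method = method, task = dm@task,
      parameterMode = parameterMode, windowEndH = windowEndH,
      predictions = DataFrame(sample_id = rownames(dm@X), lot = dm@lot,
                              truth = dm@y, pred = preds, fold = foldlab),
      metrics = metrics, confusion = confusion,
      lassoFolds = lassoFolds, hyper = hyper)
}

#' Sweep learners, parameter modes and time windows
#'
#' Full factorial sweep over \code{methods} x \code{modes} x
#' \code{window_ends}: for each cell the base \code{"mean+SD"} profile set is
#' subset and windowed, a design matrix built and a leave-lot-out CV run.
#'
#' @param profiles A \code{\link{MorphProfileSet}} in \code{"mean+SD"} mode
#'   over the full schedule.
#' @param y Teacher signal (named by lot or sample id).
#' @param task \code{"classification"} or \code{"regression"}.
#' @param methods Learners to compare.
#' @param modes Parameter modes to compare.
#' @param window_ends Window end times (must be scheduled times).
#' @param hyper,seed Passed through to \code{\link{runLeaveLotOut}}.
#' @return List of \code{\link{CVReport}}s; see \code{\link{cvSummary}}.
#' @export
sweepModels <- function(profiles, y, task,
                        methods = if (task == "classification")
                          c("kNN", "LASSO", "RF") else c("LASSO", "RF"),
                        modes = c("mean+SD", "without_SD", "only_SD"),
                        window_ends = metadata(profiles)$schedule,
                        hyper = list(), seed = 1) {
  sched <- metadata(profiles)$schedule
  if (!all(window_ends %in% sched))
    stop("window_ends must be scheduled times")
  reports <- list()
  for (mode in modes) {
    pm <- subsetParameters(profiles, mode)
    for (wend in window_ends) {
      dm <- buildDesignMatrix(windowProfile(pm, wend), y, task)
      for (method in methods) {
        key <- paste(method, mode, wend, sep = "|")
        reports[[key]] <- tryCatch(
          runLeaveLotOut(dm, method, hyper, seed, mode, wend),
          error = function(e) stop(sprintf(
            "sweep cell (%s, %s, %g h) failed: %s",
            method, mode, wend, conditionMessage(e)), call. = FALSE))
      }
    }
  }
  reports
}

#' Tidy metric table from a list of CV reports
#'
#' @param reports List of \code{\link{CVReport}}s (from
#'   \code{\link{sweepModels}}).
#' @return data.frame: method, parameter_mode, window_end_h, metric, value.
#' @export
cvSummary <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(method = r@method, parameter_mode = r@parameterMode,
               window_end_h = r@windowEndH, metric = names(r@metrics),
               value = unname(r@metrics), row.names = NULL)))
}

#' LASSO selection counts and mean weights across folds
#'
#' For every feature: in how many leave-lot-out folds its LASSO coefficient
#' was nonzero, and its mean signed weight across all folds. Sorted by
#' selection count (descending), ties broken by absolute mean weight; the
#' first 15 rows reproduce the "top 15 selected parameters" view.
#'
#' @param report A \code{\link{CVReport}} from a LASSO run.
#' @param top Number of top rows to mark (default 15).
#' @return data.frame: feature, n_selected, mean_weight, top.
#' @export
lassoReport <- function(report, top = 15) {
  if (report@method != "LASSO" || !length(report@lassoFolds))
    stop("lassoReport requires a fitted LASSO CVReport")
  cf <- do.call(cbind, report@lassoFolds)
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  out <- data.frame(
    feature = rownames(cf),
    n_selected = rowSums(cf != 0),
    mean_weight = rowMeans(cf),
    row.names = NULL)
  out <- out[order(-out$n_selected, -abs(out$mean_weight)), ]
  out$top <- seq_len(nrow(out)) <= top
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
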
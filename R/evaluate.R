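#' Coefficient of determination
#'
#' \code{1 - SS_res / SS_tot}; can be negative for out-of-sample predictions
#' worse than the mean.
#'
#' @param truth,predictions numeric vectors of equal length (>= 2).
#' @export
r_squared <- function(truth, predictions) {
  stopifnot(length(truth) == length(predictions), length(truth) >= 2)
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) stop("r_squared undefined: truth has zero variance")
  1 - sum((truth - predictions)^2) / sst
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outranks
#' a random negative, ties counting one half.
#'
#' @param truth binary vector; the positive class is the factor's second
#'   level (or may be named via \code{positive}).
#' @param scores numeric scores, higher meaning more positive.
#' @param positive optional positive-class label.
#' @export
roc_auc <- function(truth, scores, positive = NULL) {
  f <- factor(truth)
  if (nlevels(f) != 2) stop("roc_auc needs exactly two classes present")
  if (is.null(positive)) positive <- levels(f)[2]
  if (anyNA(scores) || any(!is.finite(scores))) stop("roc_auc needs finite scores")
  pos <- f == positive
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mean class accuracy (macro-averaged recall)
#'
#' Unweighted mean over the truth's classes of per-class recall. Predicted
#' labels outside the truth's alphabet count as wrong, with a warning.
#'
#' @param truth categorical vector.
#' @param predicted predicted labels.
#' @export
mean_class_accuracy <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  extra <- setdiff(unique(predicted), unique(truth))
  if (length(extra) > 0) {
    warning("predicted label(s) outside the truth alphabet counted as wrong: ",
            paste(extra, collapse = ", "))
  }
  classes <- sort(unique(truth))
  mean(vapply(classes, function(cl) {
    mean(predicted[truth == cl] == cl)
  }, numeric(1)))
}

#' Plain accuracy
#' @inheritParams mean_class_accuracy
#' @export
accuracy <- function(truth, predicted) {
  mean(as.character(truth) == as.character(predicted))
}

#' The headline metric for a task
#' @param task one of \code{"regression"}, \code{"binary"}, \code{"multiclass"}.
#' @return a function(truth, predictions, probabilities) -> score, and its
#'   name as the \code{"metric_name"} attribute.
#' @export
task_metric <- function(task) {
  fn <- switch(task,
    regression = function(truth, pred, prob = NULL) r_squared(truth, pred),
    binary = function(truth, pred, prob = NULL) {
      if (is.null(prob) || anyNA(prob)) return(NA_real_)  # probability metric missing
      pos <- colnames(prob)[ncol(prob)]
      roc_auc(truth, prob[, pos], positive = pos)
    },
    multiclass = function(truth, pred, prob = NULL) mean_class_accuracy(truth, pred),
    stop("unknown task: ", task))
  attr(fn, "metric_name") <- switch(task, regression = "R2", binary = "AUC",
                                    multiclass = "mean_class_accuracy")
  fn
}

#' Rescue batch predictions containing NaN by predicting one sample at a time
#'
#' When a batch prediction contains non-finite values, every test row is
#' re-predicted individually; rows that still fail are excluded and listed.
#'
#' @param predict_fun function(test-row matrix) -> list with \code{pred} (and
#'   optionally \code{prob}).
#' @param test_x test-row matrix.
#' @return list with \code{pred}, \code{prob}, \code{excluded} (rownames of
#'   rows that could not be predicted), \code{rescued} (logical: was the
#'   per-sample path taken).
#' @export
rescue_nan_predictions <- function(predict_fun, test_x) {
  batch <- predict_fun(test_x)
  bad <- is_bad_pred(batch$pred)
  if (!any(bad)) {
    return(list(pred = batch$pred, prob = batch$prob,
                excluded = character(0), rescued = FALSE))
  }
  preds <- vector("list", nrow(test_x))
  probs <- vector("list", nrow(test_x))
  excluded <- character(0)
  for (i in seq_len(nrow(test_x))) {
    one <- tryCatch(predict_fun(test_x[i, , drop = FALSE]),
                    error = function(e) list(pred = NA, prob = NULL))
    if (is_bad_pred(one$pred)) {
      excluded <- c(excluded, rownames(test_x)[i])
      preds[[i]] <- NULL
    } else {
      preds[[i]] <- one$pred
      probs[[i]] <- one$prob
    }
  }
  keep <- !vapply(preds, is.null, logical(1))
  if (!any(keep)) {
    warning("per-sample rescue failed for every test row")
    return(list(pred = NULL, prob = NULL, excluded = rownames(test_x),
                rescued = TRUE))
  }
  pred <- unlist(preds[keep], use.names = FALSE)
  if (is.factor(batch$pred)) pred <- factor(pred, levels = levels(batch$pred))
  prob <- if (all(vapply(probs[keep], is.null, logical(1)))) NULL else {
    do.call(rbind, probs[keep])
  }
  names(pred) <- rownames(test_x)[keep]
  list(pred = pred, prob = prob, excluded = excluded, rescued = TRUE)
}

is_bad_pred <- function(p) {
  if (is.null(p) || length(p) == 0) return(TRUE)
  if (is.factor(p) || is.character(p)) is.na(p) else !is.finite(p)
}

#' Bootstrap standard deviation of a pooled-prediction metric
#'
#' The point estimate is the metric on the full prediction set; B resamples
#' of size n with replacement give the empirical SD. Resamples on which the
#' metric is undefined (e.g. a single class drawn) are redrawn and counted.
#'
#' @param truth,predictions pooled out-of-fold truths and predictions.
#' @param metric function(truth, predictions) -> score.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param max_redraw cap on total redraws.
#' @return list with \code{estimate}, \code{sd}, \code{redraws}.
#' @export
bootstrap_ci <- function(truth, predictions, metric, B = 1000, seed = 1L,
                         max_redraw = 10 * B) {
  stopifnot(length(truth) == length(predictions), length(truth) > 0)
  point <- metric(truth, predictions)
  if (!is.finite(point)) stop("metric undefined on the full prediction set")
  ord <- order(as.character(truth), as.character(predictions))  # row-order invariance
  truth <- truth[ord]; predictions <- predictions[ord]
  set.seed(seed)
  n <- length(truth)
  vals <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(suppressWarnings(metric(truth[idx], predictions[idx])),
                    error = function(e) NA_real_)
      if (is.finite(v)) break
      redraws <- redraws + 1L
      if (redraws > max_redraw) stop("bootstrap metric undefined on too many resamples")
    }
    vals[b] <- v
  }
  list(estimate = point, sd = stats::sd(vals), redraws = redraws)
}

#' Compare an experimental model to the demographics-only baseline
#'
#' Delta of point estimates, flagged significant when the two +/- 1
#' bootstrap-SD intervals do not overlap.
#'
#' @param experimental,baseline \code{model_result}s (or lists with
#'   \code{estimate}, \code{sd}, \code{metric_name}).
#' @return list with \code{delta}, \code{significant}.
#' @export
compare_to_baseline <- function(experimental, baseline) {
  if (!identical(experimental$metric_name, baseline$metric_name)) {
    stop("cannot compare results on different metrics: ",
         experimental$metric_name, " vs ", baseline$metric_name)
  }
  delta <- experimental$estimate - baseline$estimate
  lo_e <- experimental$estimate - experimental$sd
  hi_e <- experimental$estimate + experimental$sd
  lo_b <- baseline$estimate - baseline$sd
  hi_b <- baseline$estimate + baseline$sd
  list(delta = delta, significant = (lo_e > hi_b) || (lo_b > hi_e))
}

#' Exploratory principal component analysis
#'
#' Standard PCA on columns scaled to unit variance; constant columns are
#' dropped with a warning. Explained-variance fractions sum to one.
#'
#' @param table an \code{abund_table} (or numeric matrix).
#' @return list with \code{scores}, \code{explained} (variance fractions),
#'   \code{rotation}.
#' @export
pca_overview <- function(table) {
  m <- unclass(table)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    warning(sum(sds == 0 | is.na(sds)), " constant column(s) dropped from PCA")
    m <- m[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  if (ncol(m) < 2) stop("PCA needs at least 2 non-constant features")
  pc <- stats::prcomp(m, scale. = TRUE)
  list(scores = pc$x, explained = pc$sdev^2 / sum(pc$sdev^2),
       rotation = pc$rotation)
}
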
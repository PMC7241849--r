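# Estimator registry: 11 configurations over 8 algorithm families behind a
# uniform fit/predict contract. Each config declares its task support, fixed
# settings, tunable hyperparameter specs and how it consumes class weights
# ("case" = per-sample weights, "class" = per-class weights, "none").

#' The estimator configurations
#'
#' Eleven configurations across the algorithm families: two elastic nets
#' (full alpha/lambda search vs lambda-only at fixed mixing), two random
#' forests (conventional mtry-fraction search vs the 1001-tree
#' balanced-sampling variant with a geometric mtry ladder), two gradient
#' boosted machines (depth/learning-rate search vs the fixed stump learner
#' with tree-count doubling), three SVM kernels, k-nearest neighbors and
#' naive Bayes.
#'
#' @param task \code{"regression"}, \code{"binary"} or \code{"multiclass"}.
#' @param families optional subset of configuration names.
#' @return named list of \code{estimator_config}s supporting the task.
#' @export
estimator_registry <- function(task = c("regression", "binary", "multiclass"),
                               families = NULL) {
  task <- match.arg(task)
  all <- list(
    elastic_net = list(
      family = "elastic_net", engine = "glmnet", weight_mode = "case",
      tasks = c("regression", "binary", "multiclass"),
      fixed = list(),
      make_specs = function(p, n) list(
        hyper_spec("alpha", 0, 1, 0.5, hard_lo = 0, hard_hi = 1, n_fine = 3),
        hyper_spec("lambda", -4, 0, 2, transform = "pow10",
                   hard_lo = -8, hard_hi = 2, n_fine = 3))),
    elastic_net2 = list(
      family = "elastic_net", engine = "glmnet", weight_mode = "case",
      tasks = c("regression", "binary", "multiclass"),
      fixed = list(alpha = 0.5),
      make_specs = function(p, n) list(
        hyper_spec("lambda", -4, 0, 2, transform = "pow10",
                   hard_lo = -8, hard_hi = 2, n_fine = 3))),
    rf = list(
      family = "rf", engine = "randomForest", weight_mode = "class",
      tasks = c("regression", "binary", "multiclass"),
      fixed = list(ntree = 300),
      make_specs = function(p, n) list(
        hyper_spec("mtry_frac", 0.1, 0.9, 0.4, hard_lo = 0.01,
                   hard_hi = 1, n_fine = 3))),
    rf2 = list(
      family = "rf", engine = "randomForest2", weight_mode = "none",
      tasks = c("regression", "binary", "multiclass"),
      fixed = list(ntree = 1001),
      make_specs = function(p, n) list(
        hyper_spec("mtry", values = as.list(mtry_ladder(p, max_candidates = 10))))),
    gbm = list(
      family = "gbm", engine = "xgboost", weight_mode = "case",
      tasks = c("regression", "binary", "multiclass"),
      fixed = list(nrounds = 150, subsample = 0.8),
      make_specs = function(p, n) list(
        hyper_spec("max_depth", 1, 3, 1, hard_lo = 1, hard_hi = 8,
                   integer = TRUE, n_fine = 3),
        hyper_spec("eta", -1.5, -0.5, 1, transform = "pow10",
                   hard_lo = -3, hard_hi = 0, n_fine = 2))),
    gbm2 = list(
      family = "gbm", engine = "xgboost2", weight_mode = "case",
      tasks = c("regression", "binary", "multiclass"),
      fixed = list(max_depth = 1, min_child_weight = 10, eta = 0.1,
                   nrounds_init = 1000, max_doublings = 4),
      make_specs = function(p, n) list()),
    svm_linear = list(
      family = "svm", engine = "svm", weight_mode = "class",
      tasks = c("regression", "binary", "multiclass"),
      fixed = list(kernel = "linear"),
      make_specs = function(p, n) list(
        hyper_spec("cost", -3, 3, 3, transform = "pow2",
                   hard_lo = -12, hard_hi = 12, n_fine = 3))),
    svm_poly2 = list(
      family = "svm", engine = "svm", weight_mode = "class",
      tasks = c("regression", "binary", "multiclass"),
      fixed = list(kernel = "polynomial", degree = 2, coef0 = 1),
      make_specs = function(p, n) list(
        hyper_spec("cost", -3, 3, 3, transform = "pow2",
                   hard_lo = -12, hard_hi = 12, n_fine = 3))),
    svm_radial = list(
      family = "svm", engine = "svm", weight_mode = "class",
      tasks = c("regression", "binary", "multiclass"),
      fixed = list(kernel = "radial"),
      make_specs = function(p, n) list(
        hyper_spec("cost", -3, 3, 3, transform = "pow2",
                   hard_lo = -12, hard_hi = 12, n_fine = 3),
        hyper_spec("gamma", -6, 0, 3, transform = "pow2",
                   hard_lo = -15, hard_hi = 5, n_fine = 3))),
    knn = list(
      family = "knn", engine = "knn", weight_mode = "none",
      tasks = c("regression", "binary", "multiclass"),
      fixed = list(),
      make_specs = function(p, n) list(
        hyper_spec("k", 1, 9, 4, hard_lo = 1, hard_hi = 99,
                   integer = TRUE, n_fine = 3))),
    naive_bayes = list(
      family = "naive_bayes", engine = "naive_bayes", weight_mode = "none",
      tasks = c("binary", "multiclass"),
      fixed = list(),
      make_specs = function(p, n) list(
        hyper_spec("laplace", 0, 1, 1, hard_lo = 0, hard_hi = 10, n_fine = 3)))
  )
  keep <- vapply(all, function(cfg) task %in% cfg$tasks, logical(1))
  out <- all[keep]
  if (!is.null(families)) {
    unknown <- setdiff(families, names(all))
    if (length(unknown) > 0) stop("unknown estimator(s): ", paste(unknown, collapse = ", "))
    absent <- setdiff(families, names(out))
    if (length(absent) > 0) stop(paste(absent, collapse = ", "),
                                 " do(es) not support task '", task, "'")
    out <- out[families]
  }
  for (nm in names(out)) out[[nm]]$name <- nm
  out
}

#' Geometric mtry candidate ladder
#'
#' Candidate mtry values \code{round(p * 0.9^k)} for k = 0, 1, ...,
#' deduplicated and floored at 1.
#'
#' @param p number of predictors.
#' @param step geometric step (default 0.9).
#' @param max_candidates cap on the ladder length.
#' @export
mtry_ladder <- function(p, step = 0.9, max_candidates = 30) {
  v <- unique(pmax(1, round(p * step^(0:200))))
  utils::head(v[v >= 1], max_candidates)
}

#' Fixed settings and the mtry search plan for the second random forest
#'
#' 1001 trees; for regression a per-tree sample size of
#' \code{round(0.632 * n_rows)}; for classification an equal per-class
#' sample size of the smallest class count; mtry candidates from the
#' geometric ladder, to be selected by inner cross-validation.
#'
#' @param task task string.
#' @param n_rows training rows.
#' @param class_counts named class counts (classification).
#' @param p number of predictors.
#' @export
rf2_config <- function(task, n_rows, class_counts = NULL, p = NULL) {
  out <- list(ntree = 1001)
  if (task == "regression") {
    out$sampsize <- round(0.632 * n_rows)
  } else {
    if (is.null(class_counts) || any(class_counts == 0)) {
      stop("classification rf2 needs nonzero counts for every class")
    }
    out$sampsize <- stats::setNames(rep(min(class_counts), length(class_counts)),
                                    names(class_counts))
  }
  if (!is.null(p)) out$mtry_candidates <- mtry_ladder(p)
  out
}

#' Decide whether a boosted model should be refit with twice the trees
#'
#' TRUE when the best iteration falls in the last 10\% of iterations and the
#' mean performance of the last 10\% improves by at least \code{min_improve}
#' (relative) over the preceding 10\%.
#'
#' @param perf per-iteration performance, higher is better.
#' @param min_improve relative improvement threshold (default 0.001 = 0.1\%).
#' @export
gbm2_escalate <- function(perf, min_improve = 0.001) {
  n <- length(perf)
  if (n < 20) return(FALSE)
  dec <- max(1L, floor(n / 10))
  best_iter <- which.max(perf)
  if (best_iter <= n - dec) return(FALSE)
  last <- mean(perf[(n - dec + 1):n])
  prev <- mean(perf[(n - 2 * dec + 1):(n - dec)])
  is.finite(last) && is.finite(prev) &&
    (last - prev) >= min_improve * abs(prev)
}

prep_x <- function(x) {
  m <- as.matrix(unclass(x))
  storage.mode(m) <- "double"
  m
}

pad_two_cols <- function(m) {
  if (ncol(m) >= 2) return(m)
  cbind(m, `.pad` = 0)
}

class_weight_map <- function(y) {
  f <- table(as.character(y)) / length(y)
  w <- 1 / f
  w / mean(w[as.character(y)])  # mean-1 over samples
}

#' Fit an estimator and predict test rows
#'
#' Uniform adapter over the underlying learners. Failures (convergence,
#' memory, degenerate inputs) are caught and returned as a structured
#' failure, never a crash. Classification configs return a class-probability
#' matrix when the engine produces one; probabilities that come back NaN
#' (as naive Bayes often does) are passed through as-is so that
#' probability-based metrics can be marked missing while label-based ones
#' still work.
#'
#' @param config an entry of [estimator_registry()].
#' @param hyper named list of hyperparameter values.
#' @param train_x,train_y training matrix and target.
#' @param weights per-sample weights (ignored by engines without support).
#' @param test_x rows to predict.
#' @param seed integer seed set before stochastic fits.
#' @return list with \code{pred}, \code{prob} (matrix or NULL),
#'   \code{failure} (NULL or message), \code{model}.
#' @export
fit_predict <- function(config, hyper, train_x, train_y, weights = NULL,
                        test_x = train_x, seed = NULL) {
  res <- tryCatch({
    if (!is.null(seed)) set.seed(seed)
    model <- fit_engine(config, hyper, prep_x(train_x), train_y, weights)
    out <- predict_engine(config, model, prep_x(test_x))
    out$model <- model
    out$failure <- NULL
    out
  }, error = function(e) {
    list(pred = NULL, prob = NULL, model = NULL, failure = conditionMessage(e))
  })
  res
}

task_of <- function(y) {
  if (is.numeric(y)) "regression"
  else if (nlevels(factor(y)) == 2) "binary"
  else "multiclass"
}

fit_engine <- function(config, hyper, x, y, weights) {
  task <- task_of(y)
  hp <- utils::modifyList(config$fixed, hyper)
  engine <- config$engine
  if (engine == "glmnet") {
    fam <- switch(task, regression = "gaussian", binary = "binomial",
                  multiclass = "multinomial")
    xx <- pad_two_cols(x)
    yy <- if (task == "regression") y else factor(y)
    w <- if (is.null(weights)) rep(1, nrow(x)) else weights
    fit <- glmnet::glmnet(xx, yy, family = fam, alpha = hp$alpha,
                          lambda = hp$lambda, weights = w,
                          maxit = 200000)
    list(fit = fit, levels = if (task != "regression") levels(yy), padded = ncol(x) < 2)
  } else if (engine %in% c("randomForest", "randomForest2")) {
    args <- list(x = as.data.frame(x), ntree = hp$ntree)
    if (task == "regression") {
      args$y <- y
    } else {
      args$y <- factor(y)
    }
    if (engine == "randomForest2") {
      cc <- if (task == "regression") NULL else table(factor(y))
      rc <- rf2_config(task, nrow(x), class_counts = cc)
      args$sampsize <- rc$sampsize
      args$mtry <- min(hp$mtry, ncol(x))
      args$replace <- task != "regression"
      if (task != "regression") args$strata <- args$y
    } else {
      args$mtry <- max(1, min(ncol(x), round(hp$mtry_frac * ncol(x))))
      if (task != "regression" && config$weight_mode == "class") {
        cw <- class_weight_map(y)
        args$classwt <- as.numeric(cw[levels(args$y)])
      }
    }
    fit <- do.call(randomForest::randomForest, args)
    list(fit = fit, levels = if (task != "regression") levels(args$y))
  } else if (engine %in% c("xgboost", "xgboost2")) {
    yy <- if (task == "regression") y else as.integer(factor(y)) - 1L
    levs <- if (task != "regression") levels(factor(y))
    obj <- switch(task, regression = "reg:squarederror",
                  binary = "binary:logistic", multiclass = "multi:softprob")
    params <- list(objective = obj, max_depth = hp$max_depth %||% 6,
                   eta = hp$eta %||% 0.3, nthread = 1)
    if (!is.null(hp$min_child_weight)) params$min_child_weight <- hp$min_child_weight
    if (!is.null(hp$subsample)) params$subsample <- hp$subsample
    if (task == "multiclass") params$num_class <- length(levs)
    dtrain <- xgboost::xgb.DMatrix(x, label = yy,
                                   weight = weights %||% rep(1, nrow(x)))
    if (engine == "xgboost2") {
      fit <- fit_gbm2(params, dtrain, hp, task)
    } else {
      fit <- xgboost::xgb.train(params, dtrain, nrounds = hp$nrounds, verbose = 0)
    }
    list(fit = fit, levels = levs)
  } else if (engine == "svm") {
    args <- list(x = x, y = if (task == "regression") y else factor(y),
                 kernel = hp$kernel, cost = hp$cost, probability = task != "regression")
    if (!is.null(hp$degree)) args$degree <- hp$degree
    if (!is.null(hp$coef0)) args$coef0 <- hp$coef0
    if (!is.null(hp$gamma)) args$gamma <- hp$gamma
    if (task != "regression" && config$weight_mode == "class") {
      cw <- class_weight_map(y)
      args$class.weights <- stats::setNames(as.numeric(cw), names(cw))
    }
    fit <- do.call(e1071::svm, args)
    list(fit = fit, levels = if (task != "regression") levels(factor(y)))
  } else if (engine == "knn") {
    k <- max(1, min(hp$k, nrow(x) - 1))
    if (task == "regression") {
      list(fit = caret::knnreg(x, y, k = k), levels = NULL)
    } else {
      list(train_x = x, train_y = factor(y), k = k, levels = levels(factor(y)))
    }
  } else if (engine == "naive_bayes") {
    fit <- e1071::naiveBayes(as.data.frame(x), factor(y), laplace = hp$laplace %||% 0)
    list(fit = fit, levels = levels(factor(y)))
  } else stop("unknown engine: ", engine)
}

# grow the tree count for the stump booster while the loss keeps improving
# at the end of training (evaluated on a held-out slice of the training data)
fit_gbm2 <- function(params, dtrain, hp, task) {
  n <- nrow(dtrain)
  idx_val <- as.integer(seq(1, n, by = 5))   # deterministic 20% validation slice
  dval <- xgboost::xgb.slice.DMatrix(dtrain, idx_val)
  dsub <- xgboost::xgb.slice.DMatrix(dtrain, setdiff(seq_len(n), idx_val))
  metric <- switch(task, regression = "rmse", binary = "logloss",
                   multiclass = "mlogloss")
  params$eval_metric <- metric
  nrounds <- hp$nrounds_init
  doublings <- 0
  repeat {
    fit <- xgboost::xgb.train(params, dsub, nrounds = nrounds,
                              evals = list(val = dval), verbose = 0)
    log <- attributes(fit)$evaluation_log
    perf <- -log[[paste0("val_", metric)]]   # losses: higher perf = lower loss
    if (!gbm2_escalate(perf) || doublings >= hp$max_doublings) break
    nrounds <- nrounds * 2
    doublings <- doublings + 1
  }
  # refit on the full training data at the selected tree count
  final <- xgboost::xgb.train(params, dtrain, nrounds = nrounds, verbose = 0)
  attr(final, "gbm2_nrounds") <- nrounds
  final
}

predict_engine <- function(config, model, test_x) {
  engine <- config$engine
  levs <- model$levels
  if (engine == "glmnet") {
    xx <- if (isTRUE(model$padded)) pad_two_cols(test_x) else test_x
    if (is.null(levs)) {
      p <- as.numeric(stats::predict(model$fit, xx))
      list(pred = stats::setNames(p, rownames(test_x)), prob = NULL)
    } else if (length(levs) == 2) {
      pr <- as.numeric(stats::predict(model$fit, xx, type = "response"))
      prob <- cbind(1 - pr, pr); colnames(prob) <- levs
      pred <- factor(levs[(pr > 0.5) + 1], levels = levs)
      list(pred = stats::setNames(pred, rownames(test_x)), prob = prob)
    } else {
      pr <- stats::predict(model$fit, xx, type = "response")[, , 1]
      if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
      pred <- factor(colnames(pr)[max.col(pr)], levels = levs)
      list(pred = stats::setNames(pred, rownames(test_x)), prob = pr[, levs, drop = FALSE])
    }
  } else if (engine %in% c("randomForest", "randomForest2")) {
    if (is.null(levs)) {
      p <- stats::predict(model$fit, as.data.frame(test_x))
      list(pred = stats::setNames(as.numeric(p), rownames(test_x)), prob = NULL)
    } else {
      prob <- stats::predict(model$fit, as.data.frame(test_x), type = "prob")
      pred <- stats::predict(model$fit, as.data.frame(test_x))
      list(pred = pred, prob = prob[, levs, drop = FALSE])
    }
  } else if (engine %in% c("xgboost", "xgboost2")) {
    dm <- xgboost::xgb.DMatrix(test_x)
    pr <- stats::predict(model$fit, dm)
    if (is.null(levs)) {
      list(pred = stats::setNames(as.numeric(pr), rownames(test_x)), prob = NULL)
    } else if (length(levs) == 2) {
      prob <- cbind(1 - pr, pr); colnames(prob) <- levs
      pred <- factor(levs[(pr > 0.5) + 1], levels = levs)
      list(pred = stats::setNames(pred, rownames(test_x)), prob = prob)
    } else {
      pm <- if (is.matrix(pr)) pr else
        matrix(pr, ncol = length(levs), byrow = TRUE)
      colnames(pm) <- levs
      pred <- factor(levs[max.col(pm)], levels = levs)
      list(pred = stats::setNames(pred, rownames(test_x)), prob = pm)
    }
  } else if (engine == "svm") {
    if (is.null(levs)) {
      p <- stats::predict(model$fit, test_x)
      list(pred = stats::setNames(as.numeric(p), rownames(test_x)), prob = NULL)
    } else {
      p <- stats::predict(model$fit, test_x, probability = TRUE)
      prob <- attr(p, "probabilities")
      prob <- if (is.null(prob)) NULL else prob[, levs, drop = FALSE]
      list(pred = stats::setNames(factor(as.character(p), levels = levs),
                                  rownames(test_x)), prob = prob)
    }
  } else if (engine == "knn") {
    if (is.null(levs)) {
      p <- stats::predict(model$fit, test_x)
      list(pred = stats::setNames(as.numeric(p), rownames(test_x)), prob = NULL)
    } else {
      p <- class::knn(model$train_x, test_x, model$train_y, k = model$k,
                      prob = TRUE)
      win <- attr(p, "prob")
      prob <- NULL
      if (length(levs) == 2) {
        pr_pos <- ifelse(p == levs[2], win, 1 - win)
        prob <- cbind(1 - pr_pos, pr_pos); colnames(prob) <- levs
      }
      list(pred = stats::setNames(factor(as.character(p), levels = levs),
                                  rownames(test_x)), prob = prob)
    }
  } else if (engine == "naive_bayes") {
    df <- as.data.frame(test_x)
    pred <- stats::predict(model$fit, df)
    prob <- stats::predict(model$fit, df, type = "raw")
    list(pred = stats::setNames(pred, rownames(test_x)),
         prob = prob[, levs, drop = FALSE])
  } else stop("unknown engine: ", engine)
}

#' Per-feature importances from a fitted estimator
#'
#' Elastic nets: |coefficient| times the feature SD (standardized
#' coefficients, averaged over classes for multinomial fits); random
#' forests: impurity importance; boosted trees: gain. Other families have
#' no native importance; a permutation fallback (metric degradation on held
#' -out rows) is available via [permutation_importance()].
#'
#' @param config estimator config.
#' @param model fitted model (from [fit_predict()]).
#' @param train_x training matrix (for coefficient standardization).
#' @return named non-negative numeric vector over the training features.
#' @export
native_importance <- function(config, model, train_x) {
  feats <- colnames(train_x)
  engine <- config$engine
  if (engine == "glmnet") {
    cf <- stats::coef(model$fit)
    if (is.list(cf)) {  # multinomial: one coefficient vector per class
      cm <- do.call(cbind, lapply(cf, function(m) abs(as.numeric(m)[-1])))
      beta <- rowMeans(cm)
      names(beta) <- rownames(cf[[1]])[-1]
    } else {
      beta <- abs(as.numeric(cf)[-1])
      names(beta) <- rownames(cf)[-1]
    }
    sds <- apply(train_x, 2, stats::sd)
    imp <- beta[feats] * sds
    imp[is.na(imp)] <- 0
    stats::setNames(as.numeric(imp), feats)
  } else if (engine %in% c("randomForest", "randomForest2")) {
    im <- randomForest::importance(model$fit)
    imp <- stats::setNames(rep(0, length(feats)), feats)
    imp[rownames(im)] <- pmax(im[, 1], 0)
    imp
  } else if (engine %in% c("xgboost", "xgboost2")) {
    it <- xgboost::xgb.importance(model = model$fit)
    imp <- stats::setNames(rep(0, length(feats)), feats)
    if (!is.null(it) && nrow(it) > 0) imp[it$Feature] <- it$Gain
    imp
  } else {
    stop("estimator '", config$name %||% engine,
         "' has no native importance; use permutation_importance()")
  }
}

#' Permutation feature importance
#'
#' Mean degradation of the task metric on held-out rows when each feature
#' column is permuted; negative degradations are clipped at zero.
#'
#' @param config,model as in [native_importance()].
#' @param x,y held-out rows and truths.
#' @param metric function(truth, pred, prob) -> score.
#' @param n_perm permutations per feature.
#' @param seed integer seed.
#' @export
permutation_importance <- function(config, model, x, y, metric, n_perm = 3,
                                   seed = 1L) {
  set.seed(seed)
  x <- prep_x(x)
  base <- predict_engine(config, model, x)
  s0 <- metric(y, base$pred, base$prob)
  imp <- stats::setNames(numeric(ncol(x)), colnames(x))
  for (j in seq_len(ncol(x))) {
    d <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      xp <- x
      xp[, j] <- sample(xp[, j])
      pr <- predict_engine(config, model, xp)
      d[r] <- s0 - metric(y, pr$pred, pr$prob)
    }
    imp[j] <- max(mean(d), 0)
  }
  imp
}

#' Tune, fit and importance-score one estimator on one outer fold
#'
#' Runs the three-stage hyperparameter search with subject-grouped inner
#' cross-validation on the outer training set (scored by the task metric,
#' averaged over inner folds, with the training-prediction guard), fits the
#' best combination on the full outer training set and predicts the outer
#' test rows with per-sample NaN rescue.
#'
#' @param config estimator config.
#' @param x,y full feature matrix and target (all samples).
#' @param train_idx,test_idx row indices of the outer split.
#' @param inner named sample -> inner-fold map over the training rows.
#' @param weights per-sample weights over all rows (classification), or NULL.
#' @param seed integer seed.
#' @return list with \code{pred}, \code{prob}, \code{excluded},
#'   \code{best_hyper}, \code{trace}, \code{importance}, \code{failure}.
#' @export
tune_fit_fold <- function(config, x, y, train_idx, test_idx, inner,
                          weights = NULL, seed = 1L) {
  xtr <- x[train_idx, , drop = FALSE]
  ytr <- y[train_idx]
  wtr <- if (is.null(weights)) NULL else weights[train_idx]
  task <- task_of(y)
  metric <- task_metric(task)
  inner_ids <- inner[rownames(xtr)]
  specs <- config$make_specs(ncol(xtr), nrow(xtr))

  # headline metric, falling back to label accuracy when the probability
  # metric is unavailable (NaN probabilities, single-class evaluation fold)
  safe_metric <- function(truth, pred, prob) {
    s <- tryCatch(suppressWarnings(metric(truth, pred, prob)),
                  error = function(e) NA_real_)
    if (task != "regression" && !is.finite(s)) s <- accuracy(truth, pred)
    s
  }

  evaluator <- function(values) {
    scores <- c()
    for (f in sort(unique(inner_ids))) {
      tr <- which(inner_ids != f); te <- which(inner_ids == f)
      if (length(te) == 0 || length(tr) == 0) next
      if (task != "regression" && length(unique(ytr[tr])) < 2) next
      fp <- fit_predict(config, values, xtr[tr, , drop = FALSE], ytr[tr],
                        weights = wtr[tr], test_x = xtr[te, , drop = FALSE],
                        seed = hash_seed(seed, paste0("inner", f)))
      if (!is.null(fp$failure)) stop(fp$failure)
      scores <- c(scores, safe_metric(ytr[te], fp$pred, fp$prob))
    }
    if (length(scores) == 0 || !any(is.finite(scores))) return(NA_real_)
    mean(scores, na.rm = TRUE)
  }
  guard <- function(values) {
    fp <- fit_predict(config, values, xtr, ytr, weights = wtr, test_x = xtr,
                      seed = hash_seed(seed, "guard"))
    if (!is.null(fp$failure)) return(NA_real_)
    fp$pred
  }

  tuned <- if (length(specs) == 0) {
    list(best_values = list(), trace = NULL)
  } else {
    tryCatch(tune_hypers(specs, evaluator, guard = guard),
             error = function(e) e)
  }
  if (inherits(tuned, "error")) {
    return(list(pred = NULL, prob = NULL, excluded = character(0),
                best_hyper = NULL, trace = NULL, importance = NULL,
                failure = conditionMessage(tuned)))
  }
  final <- fit_predict(config, tuned$best_values, xtr, ytr, weights = wtr,
                       test_x = xtr[1, , drop = FALSE],
                       seed = hash_seed(seed, "final"))
  if (!is.null(final$failure)) {
    return(list(pred = NULL, prob = NULL, excluded = character(0),
                best_hyper = tuned$best_values, trace = tuned$trace,
                importance = NULL, failure = final$failure))
  }
  pf <- function(rows) predict_engine(config, final$model, prep_x(rows))
  out <- rescue_nan_predictions(pf, x[test_idx, , drop = FALSE])
  imp <- tryCatch(native_importance(config, final$model, xtr),
                  error = function(e) {
                    permutation_importance(config, final$model,
                                           x[test_idx, , drop = FALSE],
                                           y[test_idx], safe_metric,
                                           seed = hash_seed(seed, "perm"))
                  })
  list(pred = out$pred, prob = out$prob, excluded = out$excluded,
       best_hyper = tuned$best_values, trace = tuned$trace,
       importance = imp, failure = NULL)
}
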
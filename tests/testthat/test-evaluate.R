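test_that("r_squared matches its closed forms, including negative values", {
  y <- c(1, 2, 3, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(0, 1), c(1, 0)), -3)
  expect_error(r_squared(c(2, 2), c(1, 2)), "zero variance")
})

test_that("roc_auc is the Mann-Whitney probability with half-weight ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8), positive = "1"), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), positive = "1"), 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1), positive = "1"), 0)
  expect_equal(roc_auc(c(0, 1), c(0.5, 0.5), positive = "1"), 0.5)  # tie = 1/2
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "two classes")
  expect_error(roc_auc(c(0, 1), c(NaN, 0.3)), "finite")
})

test_that("roc_auc complement identity holds across random score vectors", {
  set.seed(77)
  for (i in 1:300) {
    n <- sample(4:40, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_equal(roc_auc(truth, scores, positive = "1") +
                   roc_auc(truth, -scores, positive = "1"), 1,
                 tolerance = 1e-12)
  }
})

test_that("mean class accuracy averages per-class recall, unweighted", {
  truth <- rep(c("A", "B"), c(100, 20))
  pred <- c(rep("A", 90), rep("B", 10), rep("B", 10), rep("A", 10))
  expect_equal(mean_class_accuracy(truth, pred), 0.7)
  expect_equal(mean_class_accuracy(truth, truth), 1)
  maj <- rep("A", 120)
  expect_equal(mean_class_accuracy(rep(c("A", "B"), c(108, 12)), maj), 0.5)
  expect_warning(m <- mean_class_accuracy(c("A", "B"), c("A", "Z")), "alphabet")
  expect_equal(m, 0.5)
})

test_that("random multiclass predictions average to 1/k classes", {
  set.seed(55)
  n <- 400; k <- 4
  truth <- sample(letters[1:k], n, replace = TRUE)
  vals <- replicate(60, mean_class_accuracy(truth, sample(letters[1:k], n, TRUE)))
  mc_sd <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1 / k), 3 * mc_sd + 1e-3)
})

test_that("NaN batches are rescued per sample and poison rows excluded", {
  x <- matrix(seq_len(10), 10, 1, dimnames = list(paste0("s", 1:10), "f"))
  poison <- c("s4")
  pf <- function(rows) {
    p <- rows[, 1] * 2
    if (any(rownames(rows) %in% poison)) p[] <- NaN  # one bad row poisons the batch
    list(pred = p, prob = NULL)
  }
  out <- rescue_nan_predictions(pf, x)
  expect_true(out$rescued)
  expect_identical(out$excluded, "s4")
  expect_equal(length(out$pred), 9)
  expect_equal(unname(out$pred["s7"]), 14)

  clean <- function(rows) list(pred = rows[, 1] * 2, prob = NULL)
  out2 <- rescue_nan_predictions(clean, x)
  expect_false(out2$rescued)
  expect_length(out2$excluded, 0)

  poison <- c("s2", "s5", "s9")
  out3 <- rescue_nan_predictions(pf, x)
  expect_setequal(out3$excluded, poison)
  expect_equal(length(out3$pred), 7)
})

test_that("bootstrap SD is zero for constant-correct predictions and order-invariant", {
  truth <- rep(c("a", "b"), 10)
  b <- bootstrap_ci(truth, truth, accuracy, B = 200, seed = 1)
  expect_equal(b$estimate, 1)
  expect_equal(b$sd, 0)

  set.seed(2)
  y <- rnorm(50); p <- y + rnorm(50, 0, 0.5)
  b1 <- bootstrap_ci(y, p, r_squared, B = 300, seed = 9)
  ord <- sample(50)
  b2 <- bootstrap_ci(y[ord], p[ord], r_squared, B = 300, seed = 9)
  expect_equal(b1$sd, b2$sd, tolerance = 1e-12)

  expect_error(bootstrap_ci(c(1, 1), c(1, 2), r_squared, B = 10, seed = 1),
               "undefined")
})

test_that("degenerate bootstrap resamples are redrawn and counted", {
  truth <- c(rep("neg", 18), "pos", "pos")
  scores <- runif(20)
  b <- bootstrap_ci(truth, scores,
                    function(t, s) roc_auc(t, s, positive = "pos"),
                    B = 300, seed = 4)
  expect_gt(b$redraws, 0)
  expect_true(is.finite(b$sd))
})

test_that("baseline comparison flags non-overlapping 1-SD intervals", {
  exp_r <- list(estimate = 0.625, sd = 0.021, metric_name = "R2")
  base_r <- list(estimate = 0.120, sd = 0.013, metric_name = "R2")
  cmp <- compare_to_baseline(exp_r, base_r)
  expect_equal(cmp$delta, 0.505)
  expect_true(cmp$significant)

  cmp2 <- compare_to_baseline(list(estimate = 0.796, sd = 0.013, metric_name = "AUC"),
                              list(estimate = 0.786, sd = 0.013, metric_name = "AUC"))
  expect_equal(cmp2$delta, 0.010)
  expect_false(cmp2$significant)

  same <- list(estimate = 0.5, sd = 0.05, metric_name = "AUC")
  cmp3 <- compare_to_baseline(same, same)
  expect_equal(cmp3$delta, 0)
  expect_false(cmp3$significant)

  expect_error(compare_to_baseline(exp_r, same), "different metrics")
})

test_that("PCA on scaled columns returns unit-sum explained variance", {
  set.seed(31)
  z <- rnorm(40)
  m <- cbind(a = z, b = 2 * z + 3, c = rnorm(40))
  rownames(m) <- paste0("s", 1:40)
  p <- pca_overview(m)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)

  m2 <- cbind(a = z, b = 5 * z)  # perfectly correlated pair
  rownames(m2) <- paste0("s", 1:40)
  p2 <- pca_overview(m2)
  expect_equal(p2$explained[1], 1, tolerance = 1e-9)

  m3 <- cbind(m, flat = rep(1, 40))
  expect_warning(p3 <- pca_overview(m3), "constant")
  expect_equal(ncol(p3$scores), 3)
})
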
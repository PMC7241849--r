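test_that("count normalization divides by gene length then sample coverage", {
  counts <- matrix(c(10, 10, 10), 1, 3,
                   dimnames = list("s1", c("g1", "g2", "g3")))
  ab <- normalize_counts(counts, c(100, 200, 400))
  expect_equal(as.numeric(ab), c(4 / 7, 2 / 7, 1 / 7), tolerance = 1e-12)

  one <- normalize_counts(matrix(5, 1, 1, dimnames = list("s1", "g1")), 300)
  expect_equal(as.numeric(one), 1)

  two <- matrix(c(3, 8, 5, 1), 2, 2, dimnames = list(c("s1", "s2"), c("g1", "g2")))
  a1 <- normalize_counts(two, c(120, 80))
  a2 <- normalize_counts(two * c(2, 7), c(120, 80))  # per-sample rescaling
  expect_equal(unclass(a1), unclass(a2), tolerance = 1e-12)

  bad <- matrix(c(1, 0, 2, 0), 2, 2, dimnames = list(c("s1", "s2"), c("g1", "g2")))
  expect_error(normalize_counts(bad, c(10, 10)), "s2")
})

test_that("quantile aggregation uses linear interpolation between order statistics", {
  m <- matrix(c(0.1, 0.2, 0.3, 0.4), 1, 4,
              dimnames = list("s1", paste0("g", 1:4)))
  tab <- abundance_table(m, "gene")
  agg <- aggregate_quantile(tab, list(grp = paste0("g", 1:4)), q = 0.75)
  expect_equal(as.numeric(agg), 0.325, tolerance = 1e-12)

  eq <- abundance_table(matrix(0.25, 2, 4, dimnames = list(c("s1", "s2"),
                                                           paste0("g", 1:4))), "gene")
  expect_true(all(aggregate_quantile(eq, list(g = paste0("g", 1:4))) == 0.25))

  single <- aggregate_quantile(tab, list(g1 = "g1", rest = paste0("g", 2:4)),
                               q = 0.75)
  expect_equal(as.numeric(single[, "g1"]), 0.1)

  expect_error(aggregate_quantile(tab, list(grp = character(0))), "empty")
})

test_that("quantile aggregation is monotone in member abundances", {
  set.seed(42)
  for (i in 1:25) {
    x <- runif(6)
    base <- manual_quantile(x, 0.75)
    j <- sample(6, 1)
    x2 <- x; x2[j] <- x2[j] + runif(1)
    expect_gte(manual_quantile(x2, 0.75), base)
    m <- matrix(c(x, x2), 2, 6, byrow = TRUE,
                dimnames = list(c("a", "b"), paste0("g", 1:6)))
    agg <- aggregate_quantile(abundance_table(m, "gene", closed = FALSE),
                              list(grp = paste0("g", 1:6)))
    expect_gte(agg["b", 1], agg["a", 1])
  }
})

test_that("pathway-style many-to-many membership is supported", {
  set.seed(9)
  m <- matrix(runif(30), 5, 6,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:6)))
  tab <- abundance_table(m, "gene", closed = FALSE)
  mem <- list(pwA = c("g1", "g2", "g3"), pwB = c("g3", "g4", "g5", "g6"))
  agg <- aggregate_quantile(tab, mem, kind = "pathway")
  expect_equal(as.numeric(agg[2, "pwA"]),
               manual_quantile(m[2, c("g1", "g2", "g3")], 0.75))
  expect_equal(as.numeric(agg[4, "pwB"]),
               manual_quantile(m[4, c("g3", "g4", "g5", "g6")], 0.75))
})

make_filter_fixture <- function(n, p, n_assoc, seed = 1) {
  set.seed(seed)
  y <- rnorm(n)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%04d", 1:p)))
  if (n_assoc > 0) {
    for (j in seq_len(n_assoc)) x[, j] <- x[, j] + y * (0.5 + j / n_assoc)
  }
  rownames(x) <- sprintf("s%04d", 1:n)
  list(x = abundance_table(x, "gene", closed = FALSE), y = y)
}

test_that("filter rule 1: >cap significant features -> top cap by |scaled coefficient|", {
  fx <- make_filter_fixture(n = 150, p = 300, n_assoc = 200, seed = 2)
  rep <- filter_features(fx$x, fx$y, max_features = 100)
  expect_identical(rep$rule, "coef-top-k")
  expect_length(rep$selected, 100)
  sig <- rep$stats[rep$stats$p_value < 0.05, ]
  expect_gt(nrow(sig), 100)
  top_by_coef <- sig$feature[order(-abs(sig$coef))][1:100]
  expect_setequal(rep$selected, top_by_coef)
})

test_that("filter rule 2: few significant -> top cap by ascending p, incl. non-significant", {
  fx <- make_filter_fixture(n = 80, p = 200, n_assoc = 10, seed = 3)
  rep <- filter_features(fx$x, fx$y, max_features = 120)
  expect_identical(rep$rule, "p-top-k")
  expect_length(rep$selected, 120)
  ord <- rep$stats$feature[order(rep$stats$p_value)]
  expect_setequal(rep$selected, ord[1:120])
  expect_gt(max(rep$stats$p_value[rep$stats$feature %in% rep$selected]), 0.05)
})

test_that("filter rule 3: fewer features than cap -> all selected", {
  fx <- make_filter_fixture(n = 60, p = 40, n_assoc = 5, seed = 4)
  rep <- filter_features(fx$x, fx$y, max_features = 100)
  expect_identical(rep$rule, "all")
  expect_setequal(rep$selected, colnames(fx$x))
})

test_that("filtering works for binary and multiclass targets via logistic fits", {
  set.seed(5)
  n <- 90
  y2 <- factor(rep(c("a", "b"), length.out = n))
  x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  x[, 1] <- x[, 1] + 1.5 * (y2 == "b")
  rownames(x) <- paste0("s", 1:n)
  rep2 <- filter_features(abundance_table(x, "gene", closed = FALSE), y2)
  expect_lt(rep2$stats$p_value[rep2$stats$feature == "f1"], 0.01)

  y3 <- factor(rep(c("a", "b", "c"), length.out = n))
  x[, 2] <- x[, 2] + 1.5 * (y3 == "c")
  rep3 <- filter_features(abundance_table(x, "gene", closed = FALSE), y3)
  expect_lt(rep3$stats$p_value[rep3$stats$feature == "f2"], 0.01)
})

test_that("top-CAG gene extraction applies the Bonferroni rule", {
  set.seed(8)
  n <- 100
  y <- rnorm(n)
  genes <- paste0("g", 1:30)
  x <- matrix(rnorm(n * 30), n, 30, dimnames = list(paste0("s", 1:n), genes))
  x[, 1:6] <- x[, 1:6] + y  # strong signal genes in CAG0001
  tab <- abundance_table(x, "gene", closed = FALSE)
  memb <- setNames(rep(c("CAG0001", "CAG0002", "CAG0003"), each = 10), genes)
  asg <- cag_assignment(memb)
  imp <- c(CAG0001 = 0.7, CAG0002 = 0.2, CAG0003 = 0.1)
  expect_warning(
    sub <- extract_genes_from_top_cags(imp, asg, tab, y, n_cags = 10),
    "nonzero importance")
  expect_true(all(paste0("g", 1:6) %in% colnames(sub)))
  expect_lte(ncol(sub), 30)

  # no signal at all: everything fails Bonferroni -> empty table with warning
  x0 <- matrix(rnorm(n * 30), n, 30, dimnames = list(paste0("s", 1:n), genes))
  tab0 <- abundance_table(x0, "gene", closed = FALSE)
  expect_warning(
    expect_warning(sub0 <- extract_genes_from_top_cags(imp, asg, tab0, y),
                   "Bonferroni"),
    "nonzero importance")
  expect_equal(ncol(sub0), 0)
})

test_that("class weights are inverse-frequency with mean one", {
  w <- class_weights(rep(c("A", "B"), c(80, 20)))
  expect_equal(unique(w[names(w) == "A"]), 0.625)
  expect_equal(unique(w[names(w) == "B"]), 2.5)
  expect_equal(mean(w), 1)
  expect_equal(sum(w), 100)  # sum over samples equals n

  wb <- class_weights(rep(c("A", "B"), 50))
  expect_true(all(wb == 1))

  w3 <- class_weights(rep(c("A", "B", "C"), c(50, 30, 20)))
  wa <- unique(w3[names(w3) == "A"]); wb <- unique(w3[names(w3) == "B"])
  wc <- unique(w3[names(w3) == "C"])
  expect_equal(unname(wb / wa), 50 / 30, tolerance = 1e-10)
  expect_equal(unname(wc / wa), 50 / 20, tolerance = 1e-10)
  expect_equal(sum(w3), 100)
  expect_error(class_weights(rep("A", 10)), "two classes")
})
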
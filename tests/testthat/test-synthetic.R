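test_that("metadata generation is deterministic and respects subject structure", {
  d <- tiny_design(n_subjects = 100, seed = 7, samples = c(2, 6))
  md1 <- generate_metadata(d)
  md2 <- generate_metadata(d)
  expect_identical(md1, md2)

  per_subj <- table(md1$subject_id)
  expect_true(all(per_subj >= 2 & per_subj <= 6))
  for (col in c("sex", "country", "delivery", "cohort")) {
    n_levels <- tapply(md1[[col]], md1$subject_id, function(v) length(unique(v)))
    expect_true(all(n_levels == 1), label = paste(col, "constant per subject"))
  }
  ages_sorted <- tapply(md1$age_days, md1$subject_id, function(a) all(diff(a) >= 0))
  expect_true(all(ages_sorted))
})

test_that("categorical prevalences land within binomial sampling bounds", {
  d <- study_design(n_subjects = 400, samples_per_subject = c(1, 1), seed = 21)
  md <- generate_metadata(d)
  p <- 0.1
  frac <- mean(md$delivery == "cesarean")
  bound <- 3 * sqrt(p * (1 - p) / nrow(md))
  expect_lt(abs(frac - p), bound)
})

test_that("invalid prevalence maps are rejected", {
  expect_error(study_design(phenotype_prevalences = list(
    sex = c(female = 0.6, male = 0.6),
    country = c(FIN = 1), delivery = c(vaginal = 1),
    breastfeeding = c(yes = 1), antibiotics = c(no = 1))),
    "prevalence")
  expect_error(signal_spec(data.frame(block = "B1", n_genes = 5, rho = 1.2)),
               "rho")
  expect_error(signal_spec(data.frame(block = "B1", n_genes = 5, rho = 0.9),
                           effects = data.frame(block = "B1", phenotype = "sex",
                                                effect = 1, form = "linear"),
                           null = TRUE),
               "null")
})

test_that("gene abundances close to one and hit the within-block correlation target", {
  d <- tiny_design(n_subjects = 25, seed = 11)  # ~60 samples
  sig <- signal_spec(data.frame(
    block = c("B001", sprintf("U%02d", 1:30)),
    n_genes = c(10, rep(1, 30)),
    rho = c(0.95, rep(0.99, 30))))
  out <- generate_gene_abundances(d, sig)
  expect_true(all(abs(rowSums(out$genes) - 1) < 1e-9))
  expect_true(all(out$genes >= 0))

  g <- out$genes[, grep("^B001_", colnames(out$genes)), drop = FALSE]
  cm <- stats::cor(g)
  expect_gte(min(cm[upper.tri(cm)]), 0.90)  # target - 0.05
  # ground truth contains only multi-gene blocks
  expect_identical(sort(unique(out$truth$membership)), "B001")
})

test_that("oversized effect/block configurations error", {
  expect_error(signal_spec(data.frame(block = "B1", n_genes = 5, rho = 0.9),
                           effects = data.frame(block = "B9", phenotype = "sex",
                                                effect = 1, form = "linear")),
               "unknown blocks")
})

test_that("taxa are block sums renormalized, one per ground-truth block", {
  d <- tiny_design(n_subjects = 15, seed = 3)
  sig <- uniform_blocks(4, 3, rho = 0.95)
  sim <- simulate_study(d, sig)
  expect_equal(ncol(sim$taxa), length(unique(sim$truth$membership)))
  expect_true(all(abs(rowSums(sim$taxa) - 1) < 1e-9))
  # sum-aggregation identity: block gene sums, renormalized
  manual <- vapply(split(names(sim$truth$membership), sim$truth$membership),
                   function(g) rowSums(sim$genes[, g, drop = FALSE]),
                   numeric(nrow(sim$genes)))
  manual <- manual / rowSums(manual)
  expect_equal(unname(unclass(sim$taxa)), unname(manual), tolerance = 1e-12,
               ignore_attr = TRUE)

  # single block containing all genes -> taxon abundance 1 everywhere
  sig1 <- uniform_blocks(1, 6, rho = 0.95)
  sim1 <- simulate_study(tiny_design(n_subjects = 10, seed = 5), sig1)
  expect_true(all(abs(sim1$taxa - 1) < 1e-12))
})

test_that("null data yields uniform univariate p-values for every feature", {
  # p-value distribution per feature across seeds; KS with a Bonferroni
  # correction across the feature family
  n_seeds <- 40
  pmat <- NULL
  for (s in seq_len(n_seeds)) {
    d <- tiny_design(n_subjects = 25, seed = 1000 + s)
    sig <- uniform_blocks(5, 3, rho = 0.9, null = TRUE)
    out <- generate_gene_abundances(d, sig)
    rep <- filter_features(out$genes, out$metadata$age_days)
    pv <- rep$stats$p_value[match(colnames(out$genes), rep$stats$feature)]
    pmat <- rbind(pmat, pv)
  }
  ks_p <- apply(pmat, 2, function(p) stats::ks.test(p, "punif")$p.value)
  expect_true(all(ks_p > 0.01 / ncol(pmat)))
})

test_that("stronger planted effects raise univariate association monotonically", {
  mean_abs_t <- function(effect) {
    vals <- c()
    for (s in 1:8) {
      d <- tiny_design(n_subjects = 30, seed = 400 + s)
      eff <- if (effect == 0) NULL else
        data.frame(block = "B001", phenotype = "sex", effect = effect,
                   form = "linear")
      sig <- signal_spec(data.frame(block = c("B001", "B002"),
                                    n_genes = c(4, 4), rho = 0.95),
                         effects = eff)
      out <- generate_gene_abundances(d, sig)
      rep <- filter_features(out$genes, factor(out$metadata$sex))
      sub <- rep$stats[grep("^B001_", rep$stats$feature), ]
      vals <- c(vals, mean(abs(sub$coef)))
    }
    mean(vals)
  }
  a0 <- mean_abs_t(0); a1 <- mean_abs_t(0.8); a2 <- mean_abs_t(1.6)
  expect_lt(a0, a1)
  expect_lt(a1, a2)
})
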
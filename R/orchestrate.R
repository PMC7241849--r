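#' Configuration for an end-to-end benchmarking run
#'
#' @param design a [study_design()] (ignored when \code{data} is supplied).
#' @param signal a [signal_spec()] (ignored when \code{data} is supplied).
#' @param data optional pre-built input list with \code{metadata},
#'   \code{genes}, and optionally \code{taxa}; when absent the synthetic
#'   generator runs.
#' @param phenotypes phenotypes to model.
#' @param data_types microbiome data types to evaluate (\code{"cag"},
#'   \code{"taxon"}, \code{"gene"}, \code{"combined"}); the demographics-only
#'   baseline is always added.
#' @param estimators estimator configuration names (see
#'   [estimator_registry()]).
#' @param k outer folds; \code{k_inner} inner folds.
#' @param B bootstrap resamples.
#' @param seed master seed; every cell derives its own seed from it.
#' @param max_features,alpha univariate filter settings.
#' @param canopy [canopy_params()] for CAG construction.
#' @export
run_config <- function(design = study_design(), signal = uniform_blocks(20, 5),
                       data = NULL,
                       phenotypes = c("age_days", "delivery"),
                       data_types = c("cag", "taxon"),
                       estimators = c("elastic_net", "rf"),
                       k = 10, k_inner = k, B = 1000, seed = 1L,
                       max_features = 1000, alpha = 0.05,
                       canopy = canopy_params()) {
  if (length(phenotypes) == 0) stop("at least one phenotype is required")
  if (length(estimators) == 0) stop("at least one estimator is required")
  bad <- setdiff(data_types, c("cag", "taxon", "gene", "combined"))
  if (length(bad) > 0) stop("unknown data type(s): ", paste(bad, collapse = ", "))
  structure(list(design = design, signal = signal, data = data,
                 phenotypes = phenotypes, data_types = data_types,
                 estimators = estimators, k = k, k_inner = k_inner, B = B,
                 seed = as.integer(seed), max_features = max_features,
                 alpha = alpha, canopy = canopy),
            class = "run_config")
}

phenotype_task <- function(metadata, phenotype) {
  v <- metadata[[phenotype]]
  if (is.numeric(v)) "regression"
  else if (length(unique(v)) == 2) "binary" else "multiclass"
}

#' Evaluate one (phenotype, data type, estimator) cell under nested CV
#'
#' Per outer fold: univariate feature filtering on the training rows (for
#' microbiome kinds), the three-stage hyperparameter search on
#' subject-grouped inner folds, a final fit on the outer training set, and
#' out-of-fold prediction with NaN rescue. Pooled predictions are scored and
#' bootstrapped; per-fold importances are averaged.
#'
#' @param table \code{abund_table} of predictors (all samples).
#' @param metadata cleaned metadata aligned to \code{table} rows.
#' @param phenotype target column.
#' @param config_name estimator configuration name.
#' @param plan a \code{fold_plan} for this phenotype.
#' @param B bootstrap resamples; \code{seed} cell seed.
#' @param max_features,alpha filter settings; filtering is skipped for
#'   demographic tables.
#' @return a \code{model_result}.
#' @export
evaluate_cell <- function(table, metadata, phenotype, config_name, plan,
                          B = 1000, seed = 1L, max_features = 1000,
                          alpha = 0.05) {
  task <- phenotype_task(metadata, phenotype)
  config <- estimator_registry(task, families = config_name)[[1]]
  y <- metadata[[phenotype]]
  if (!is.numeric(y)) y <- factor(y)
  x_all <- unclass(table)[metadata$sample_id, , drop = FALSE]
  weights <- if (task == "regression") NULL else {
    as.numeric(class_weights(as.character(y)))
  }
  do_filter <- !identical(table_kind(table), "demographic")

  pooled <- list(); fold_imps <- list(); traces <- list()
  excluded <- character(0); failures <- list(); filter_rules <- character(0)
  outer_of <- plan$outer[metadata$sample_id]
  for (f in seq_len(plan$k)) {
    train_idx <- which(outer_of != f)
    test_idx <- which(outer_of == f)
    if (length(test_idx) == 0) next
    xx <- x_all
    if (do_filter) {
      rep_f <- filter_features(table[metadata$sample_id[train_idx], , drop = FALSE],
                               y[train_idx], max_features = max_features,
                               alpha = alpha)
      xx <- x_all[, rep_f$selected, drop = FALSE]
      filter_rules <- c(filter_rules, rep_f$rule)
    }
    inner <- plan$inner[[f]]
    res <- tune_fit_fold(config, xx, y, train_idx, test_idx, inner,
                         weights = weights,
                         seed = hash_seed(seed, paste0("fold", f)))
    if (!is.null(res$failure)) {
      failures[[as.character(f)]] <- res$failure
      next
    }
    pooled[[f]] <- list(ids = names(res$pred), truth = y[test_idx][
                          match(names(res$pred), metadata$sample_id[test_idx])],
                        pred = res$pred, prob = res$prob, fold = f)
    fold_imps[[f]] <- res$importance
    traces[[f]] <- res$trace
    excluded <- c(excluded, res$excluded)
  }
  if (length(pooled) == 0) {
    stop("every outer fold failed for ", config_name, " on ", phenotype,
         " (first failure: ", failures[[1]], ")")
  }
  truth <- unlist(lapply(pooled, function(p) as.character(p$truth)), use.names = FALSE)
  if (task == "regression") truth <- as.numeric(truth)
  else truth <- factor(truth, levels = levels(y))
  preds <- unlist(lapply(pooled, function(p) as.character(p$pred)), use.names = FALSE)
  if (task == "regression") preds <- as.numeric(preds)
  ids <- unlist(lapply(pooled, function(p) p$ids), use.names = FALSE)
  folds <- unlist(lapply(pooled, function(p) rep(p$fold, length(p$ids))))
  prob <- NULL
  if (task != "regression") {
    probs <- lapply(pooled, `[[`, "prob")
    if (!any(vapply(probs, is.null, logical(1)))) prob <- do.call(rbind, probs)
  }

  metric_name <- attr(task_metric(task), "metric_name")
  boot <- switch(task,
    regression = bootstrap_ci(truth, preds, r_squared, B = B,
                              seed = hash_seed(seed, "boot")),
    binary = {
      pos <- levels(truth)[2]
      if (is.null(prob) || anyNA(prob[, pos])) {
        NULL  # probability metric missing (e.g. NaN probabilities)
      } else {
        bootstrap_ci(truth, prob[, pos],
                     function(t, s) roc_auc(t, s, positive = pos),
                     B = B, seed = hash_seed(seed, "boot"))
      }
    },
    multiclass = bootstrap_ci(truth, factor(preds, levels = levels(truth)),
                              mean_class_accuracy, B = B,
                              seed = hash_seed(seed, "boot")))

  acc <- if (task == "regression") NULL else {
    bootstrap_ci(truth, factor(preds, levels = levels(truth)), accuracy,
                 B = B, seed = hash_seed(seed, "boot2"))
  }

  all_feats <- sort(unique(unlist(lapply(fold_imps, names))))
  imp_mat <- vapply(fold_imps[!vapply(fold_imps, is.null, logical(1))],
                    function(v) {
                      out <- stats::setNames(rep(0, length(all_feats)), all_feats)
                      out[names(v)] <- v
                      out
                    }, numeric(length(all_feats)))
  if (is.null(dim(imp_mat))) imp_mat <- matrix(imp_mat, nrow = length(all_feats),
                                               dimnames = list(all_feats))
  importance <- rowMeans(imp_mat)

  structure(list(phenotype = phenotype, data_type = table_kind(table),
                 estimator = config_name, task = task,
                 metric_name = metric_name,
                 estimate = if (is.null(boot)) NA_real_ else boot$estimate,
                 sd = if (is.null(boot)) NA_real_ else boot$sd,
                 accuracy = if (is.null(acc)) NULL else acc$estimate,
                 n = length(ids),
                 predictions = data.frame(sample_id = ids, fold = folds,
                                          truth = as.character(truth),
                                          pred = as.character(preds),
                                          stringsAsFactors = FALSE),
                 prob = prob, importance = importance, traces = traces,
                 filter_rules = filter_rules, excluded = excluded,
                 failures = failures),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s | %s | %s: %s = %.3f +/- %.3f (n = %d)\n",
              x$phenotype, x$data_type, x$estimator, x$metric_name,
              x$estimate, x$sd, x$n))
  invisible(x)
}

#' Run the full benchmarking experiment
#'
#' Simulates (or loads) the study data, builds CAGs by canopy clustering and
#' 0.75-quantile aggregation, plans subject-grouped nested folds per
#' phenotype, evaluates every (phenotype x data type x estimator) cell —
#' always including the demographics-only baseline — and assembles the
#' summary table and per-data-type importance-concordance matrices.
#' Failed cells are recorded and do not stop the run; reruns with the same
#' config are deterministic for deterministic estimators.
#'
#' @param config a [run_config()].
#' @return a results bundle: list with \code{results} (model_results keyed by
#'   \code{phenotype|data_type|estimator}), \code{summary} (data.frame),
#'   \code{concordance}, \code{assignment}, \code{data}, \code{failed_cells},
#'   \code{config}.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dat <- config$data
  if (is.null(dat)) {
    design <- config$design
    design$seed <- hash_seed(config$seed, "simulate")
    dat <- simulate_study(design, config$signal)
  }
  tables <- list(gene = dat$genes)
  if (!is.null(dat$taxa)) tables$taxon <- dat$taxa
  cleaned <- clean_samples(tables, dat$metadata,
                           phenotypes = intersect(PHENOTYPES, names(dat$metadata)))
  md <- cleaned$metadata

  assignment <- NULL
  built <- list()
  if ("cag" %in% config$data_types || "combined" %in% config$data_types) {
    assignment <- canopy_cluster(cleaned$tables$gene, config$canopy)
    built$cag <- aggregate_quantile(cleaned$tables$gene, assignment)
  }
  if ("taxon" %in% config$data_types || "combined" %in% config$data_types) {
    if (is.null(cleaned$tables$taxon)) stop("taxon data type requested but no taxa table supplied")
    built$taxon <- cleaned$tables$taxon
  }
  if ("gene" %in% config$data_types) built$gene <- cleaned$tables$gene

  results <- list(); failed <- list()
  for (ph in config$phenotypes) {
    plan <- plan_folds(md, ph, k = config$k,
                       seed = hash_seed(config$seed, paste0("folds|", ph)),
                       k_inner = config$k_inner)
    demo <- encode_demographics(md, ph)
    cell_tables <- built
    if ("combined" %in% config$data_types) {
      comb <- do.call(cbind, c(lapply(built[intersect(c("cag", "taxon"),
                                                      names(built))], unclass),
                               list(unclass(demo))))
      cell_tables$combined <- abundance_table(comb, "cag", closed = FALSE)
      attr(cell_tables$combined, "kind") <- "combined"
    }
    cell_tables <- cell_tables[intersect(config$data_types, names(cell_tables))]
    cell_tables$demographic <- demo
    task <- phenotype_task(md, ph)
    for (dt in names(cell_tables)) {
      for (est in config$estimators) {
        supported <- tryCatch({estimator_registry(task, families = est); TRUE},
                              error = function(e) FALSE)
        key <- paste(ph, dt, est, sep = "|")
        if (!supported) { failed[[key]] <- "task not supported"; next }
        res <- tryCatch(
          evaluate_cell(cell_tables[[dt]], md, ph, est, plan,
                        B = config$B,
                        seed = hash_seed(config$seed, key),
                        max_features = config$max_features,
                        alpha = config$alpha),
          error = function(e) e)
        if (inherits(res, "error")) failed[[key]] <- conditionMessage(res)
        else results[[key]] <- res
      }
    }
  }
  summary_df <- summarize_results(results)
  conc <- concordance_by_data_type(results)
  list(results = results, summary = summary_df, concordance = conc,
       assignment = assignment, data = list(metadata = md,
                                            tables = cleaned$tables),
       failed_cells = failed, config = config)
}

#' Summarize a results bundle into a best-per-phenotype table
#'
#' Per phenotype: the best experimental (microbiome) cell and the best
#' demographics-only baseline by point estimate (ties broken by smaller
#' bootstrap SD, then estimator name), their delta, and the +/- 1-SD
#' non-overlap significance flag.
#'
#' @param results named list of \code{model_result}s.
#' @return data.frame, one row per phenotype.
#' @export
summarize_results <- function(results) {
  if (length(results) == 0) return(data.frame())
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(phenotype = r$phenotype, data_type = r$data_type,
               estimator = r$estimator, metric = r$metric_name,
               estimate = r$estimate, sd = r$sd, n = r$n,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  rows <- list()
  for (ph in unique(df$phenotype)) {
    sub <- df[df$phenotype == ph & is.finite(df$estimate), , drop = FALSE]
    pick <- function(d) {
      if (nrow(d) == 0) return(NULL)
      d[order(-d$estimate, d$sd, d$estimator), , drop = FALSE][1, , drop = FALSE]
    }
    be <- pick(sub[sub$data_type != "demographic", , drop = FALSE])
    bb <- pick(sub[sub$data_type == "demographic", , drop = FALSE])
    if (is.null(be) && is.null(bb)) next
    cmp <- if (!is.null(be) && !is.null(bb)) {
      compare_to_baseline(list(estimate = be$estimate, sd = be$sd,
                               metric_name = be$metric),
                          list(estimate = bb$estimate, sd = bb$sd,
                               metric_name = bb$metric))
    } else list(delta = NA_real_, significant = NA)
    rows[[ph]] <- data.frame(
      phenotype = ph, metric = (be %||% bb)$metric,
      best_data_type = if (is.null(be)) NA_character_ else be$data_type,
      best_estimator = if (is.null(be)) NA_character_ else be$estimator,
      best_estimate = if (is.null(be)) NA_real_ else be$estimate,
      best_sd = if (is.null(be)) NA_real_ else be$sd,
      baseline_estimator = if (is.null(bb)) NA_character_ else bb$estimator,
      baseline_estimate = if (is.null(bb)) NA_real_ else bb$estimate,
      baseline_sd = if (is.null(bb)) NA_real_ else bb$sd,
      delta = cmp$delta, significant = cmp$significant,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per (phenotype, data type): Spearman concordance of importance vectors
# across estimators; genes are excluded (their per-phenotype feature sets
# are not comparable)
concordance_by_data_type <- function(results) {
  keys <- names(results)
  meta <- do.call(rbind, lapply(results, function(r) {
    data.frame(phenotype = r$phenotype, data_type = r$data_type,
               estimator = r$estimator, stringsAsFactors = FALSE)
  }))
  out <- list()
  if (is.null(meta)) return(out)
  groups <- unique(meta[meta$data_type != "gene" &
                          meta$data_type != "demographic",
                        c("phenotype", "data_type")])
  for (i in seq_len(nrow(groups))) {
    sel <- which(meta$phenotype == groups$phenotype[i] &
                   meta$data_type == groups$data_type[i])
    if (length(sel) < 2) next
    imps <- lapply(results[sel], `[[`, "importance")
    universe <- sort(unique(unlist(lapply(imps, names))))
    vecs <- list()
    for (j in seq_along(sel)) {
      v <- tryCatch(importance_vector(imps[[j]], universe,
                                      provenance = as.list(meta[sel[j], ])),
                    error = function(e) NULL)
      if (!is.null(v)) vecs[[meta$estimator[sel[j]]]] <- v
    }
    if (length(vecs) < 2) next
    out[[paste(groups$phenotype[i], groups$data_type[i], sep = "|")]] <-
      pairwise_spearman(vecs)
  }
  out
}

#' Write a results bundle to a directory
#'
#' \code{summary.tsv} (the per-phenotype table), \code{results.tsv} (one row
#' per cell), per-group concordance TSVs, and \code{run.json} (seed and
#' settings), making the output self-describing.
#'
#' @param bundle result of [run_experiment()].
#' @param dir output directory (created).
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
    df
  }
  utils::write.table(fmt(bundle$summary), file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cells <- do.call(rbind, lapply(bundle$results, function(r) {
    data.frame(phenotype = r$phenotype, data_type = r$data_type,
               estimator = r$estimator, metric = r$metric_name,
               estimate = r$estimate, sd = r$sd, n = r$n,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(fmt(cells), file.path(dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$concordance)) {
    utils::write.table(round(bundle$concordance[[nm]], 6),
                       file.path(dir, paste0("concordance_",
                                             gsub("[|]", "_", nm), ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  jsonlite::write_json(list(seed = bundle$config$seed,
                            k = bundle$config$k, B = bundle$config$B,
                            phenotypes = bundle$config$phenotypes,
                            data_types = bundle$config$data_types,
                            estimators = bundle$config$estimators,
                            package_version = as.character(utils::packageVersion("microvoe"))),
                       file.path(dir, "run.json"), auto_unbox = TRUE)
  invisible(dir)
}
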
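PHENOTYPES <- c("age_days", "sex", "country", "delivery", "breastfeeding", "antibiotics")

#' Complete-case cleaning across abundance tables and metadata
#'
#' Retains the intersection of samples present in every supplied abundance
#' table whose phenotypes are all complete; removal counts are recorded by
#' reason.
#'
#' @param tables named list of \code{abund_table}s.
#' @param metadata sample-metadata data.frame with a \code{sample_id} column.
#' @param phenotypes phenotype columns required to be complete.
#' @return list with \code{tables} (row-subset, sample-aligned),
#'   \code{metadata}, and \code{removed} (named counts by reason).
#' @export
clean_samples <- function(tables, metadata, phenotypes = PHENOTYPES) {
  stopifnot(is.list(tables), length(tables) > 0, "sample_id" %in% names(metadata))
  missing_ph <- setdiff(phenotypes, names(metadata))
  if (length(missing_ph) > 0) stop("metadata lacks phenotype column(s): ",
                                   paste(missing_ph, collapse = ", "))
  ids <- metadata$sample_id
  removed <- c()
  complete <- stats::complete.cases(metadata[, phenotypes, drop = FALSE])
  removed["missing_phenotype"] <- sum(!complete)
  keep <- ids[complete]
  for (nm in names(tables)) {
    before <- length(keep)
    keep <- intersect(keep, rownames(tables[[nm]]))
    removed[paste0("absent_from_", nm)] <- before - length(keep)
  }
  if (length(keep) == 0) stop("no sample survives complete-case cleaning")
  list(tables = lapply(tables, function(t) t[keep, , drop = FALSE]),
       metadata = metadata[match(keep, metadata$sample_id), , drop = FALSE],
       removed = removed)
}

#' Encode demographic covariates as a predictor matrix
#'
#' Categorical covariates become indicator (dummy) columns — one per level,
#' or with the first level dropped as reference for linear-model use;
#' continuous covariates (age in days) pass through. Columns derived from
#' the target phenotype are never included.
#'
#' @param metadata sample-metadata data.frame.
#' @param target the phenotype being predicted (excluded from predictors).
#' @param covariates candidate covariate columns.
#' @param drop_reference drop the first level of each factor (reference coding).
#' @return a \code{demographic} \code{abund_table} (rows = samples).
#' @export
encode_demographics <- function(metadata, target,
                                covariates = PHENOTYPES,
                                drop_reference = FALSE) {
  if (!target %in% names(metadata)) stop("unknown target: ", target)
  covariates <- setdiff(covariates, target)
  if (length(covariates) == 0) stop("no demographic covariates left after excluding the target")
  cols <- list()
  for (cv in covariates) {
    v <- metadata[[cv]]
    if (is.numeric(v)) {
      cols[[cv]] <- matrix(v, ncol = 1, dimnames = list(NULL, cv))
    } else {
      f <- factor(v)
      levs <- levels(f)
      use <- if (drop_reference || length(levs) == 2) levs[-1] else levs
      m <- vapply(use, function(l) as.numeric(f == l), numeric(length(f)))
      if (is.null(dim(m))) m <- matrix(m, ncol = length(use))
      colnames(m) <- paste(cv, use, sep = "_")
      cols[[cv]] <- m
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- metadata$sample_id
  abundance_table(out, "demographic", closed = FALSE)
}

#' Plan subject-grouped, stratified nested cross-validation folds
#'
#' All samples of a subject land in the same outer fold; within each outer
#' training set, inner folds obey the same constraint. For categorical
#' targets, assignment is stratified at the subject level using each
#' subject's majority class; for continuous targets folds are balanced on
#' sample count only. Packing is greedy — subjects in decreasing sample-count
#' order (ties broken by seeded random priorities) are placed into the
#' currently smallest compatible fold — so plans are deterministic given the
#' seed and invariant to the row order of \code{metadata}.
#'
#' @param metadata sample-metadata data.frame.
#' @param target phenotype the folds will be used to predict.
#' @param k number of outer folds (default 10).
#' @param seed integer seed.
#' @param k_inner number of inner folds per outer training set (default
#'   \code{k}).
#' @return a \code{fold_plan}: list with \code{k}, \code{outer} (named
#'   sample -> fold integer vector), \code{inner} (per-outer-fold named
#'   sample -> fold maps over that fold's training set), \code{seed}.
#' @export
plan_folds <- function(metadata, target, k = 10, seed = 1L, k_inner = k) {
  stopifnot(target %in% names(metadata))
  md <- metadata[order(metadata$sample_id), , drop = FALSE]
  subjects <- sort(unique(md$subject_id))
  if (length(subjects) < k) {
    stop("cannot build ", k, " subject-grouped folds from ", length(subjects), " subjects")
  }
  outer <- assign_subject_folds(md, subjects, target, k, hash_seed(seed, "outer"))
  inner <- vector("list", k)
  for (f in seq_len(k)) {
    train_md <- md[outer[md$sample_id] != f, , drop = FALSE]
    train_subj <- sort(unique(train_md$subject_id))
    ki <- min(k_inner, length(train_subj))
    inner[[f]] <- assign_subject_folds(train_md, train_subj, target, ki,
                                       hash_seed(seed, paste0("inner", f)))
  }
  structure(list(k = k, outer = outer, inner = inner, seed = seed,
                 target = target, k_inner = k_inner),
            class = "fold_plan")
}

# greedy stratified bin-packing of subjects into folds
assign_subject_folds <- function(md, subjects, target, k, seed) {
  set.seed(seed)
  prio <- stats::setNames(stats::runif(length(subjects)), subjects)
  sizes <- table(md$subject_id)[subjects]
  tv <- md[[target]]
  if (is.numeric(tv)) {
    strata <- stats::setNames(rep("all", length(subjects)), subjects)
  } else {
    # subject's majority class; ties resolved to the alphabetically first class
    strata <- vapply(subjects, function(s) {
      tb <- sort(table(as.character(tv[md$subject_id == s])), decreasing = TRUE)
      names(tb)[1]
    }, character(1))
  }
  fold_sizes <- numeric(k)
  fold_class <- matrix(0, k, length(unique(strata)),
                       dimnames = list(NULL, sort(unique(strata))))
  assignment <- stats::setNames(integer(length(subjects)), subjects)
  for (cl in sort(unique(strata))) {
    grp <- subjects[strata == cl]
    grp <- grp[order(-as.numeric(sizes[grp]), prio[grp])]
    for (s in grp) {
      # fewest subjects of this class first, then fewest samples, then priority
      cand <- order(fold_class[, cl], fold_sizes,
                    stats::runif(k))[1]
      assignment[s] <- cand
      fold_sizes[cand] <- fold_sizes[cand] + sizes[s]
      fold_class[cand, cl] <- fold_class[cand, cl] + 1
    }
  }
  out <- assignment[md$subject_id]
  names(out) <- md$sample_id
  out
}

#' Serialize / read a fold plan as JSON
#' @param plan a \code{fold_plan}.
#' @param path file path.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(
    list(k = plan$k, seed = plan$seed, target = plan$target,
         outer = as.list(plan$outer),
         inner = lapply(plan$inner, as.list)),
    path, auto_unbox = TRUE)
  invisible(path)
}
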
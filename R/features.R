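#' Co-abundance group assignment
#'
#' A many-to-one map from gene ids to group ids, plus the parameters of the
#' clustering run that produced it. Every assigned gene belongs to exactly
#' one group and every group has at least two members (singletons are
#' dropped by the clustering step).
#'
#' @param membership named character vector: names are gene ids, values are
#'   group ids.
#' @param params list of clustering parameters (recorded, not validated).
#' @export
cag_assignment <- function(membership, params = list()) {
  if (is.null(names(membership))) stop("membership must be a named gene -> group vector")
  if (anyDuplicated(names(membership))) stop("a gene may belong to only one group")
  sizes <- table(membership)
  structure(list(membership = membership,
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 params = params),
            class = "cag_assignment")
}

#' @export
print.cag_assignment <- function(x, ...) {
  cat(sprintf("<cag_assignment> %d genes in %d groups (sizes %d-%d)\n",
              length(x$membership), length(x$sizes),
              min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' Write / read a CAG assignment as a two-column TSV (gene, group)
#' @param x a [cag_assignment()].
#' @param path TSV path; parameters go to \code{<path>.json}.
#' @export
write_cag_tsv <- function(x, path) {
  utils::write.table(data.frame(gene = names(x$membership), group = x$membership),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$params, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cag_tsv
#' @export
read_cag_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  params <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"))
  } else list()
  cag_assignment(stats::setNames(df$group, df$gene), params)
}

#' Length- and depth-normalize gene read counts
#'
#' Converts raw per-sample gene counts to relative abundances: each count is
#' divided by its gene length, then by the sample's total length-normalized
#' coverage, so rows sum to one.
#'
#' @param counts samples x genes matrix of non-negative counts.
#' @param gene_lengths per-gene lengths in bp, aligned to \code{counts} columns.
#' @return gene \code{abund_table}.
#' @export
normalize_counts <- function(counts, gene_lengths) {
  stopifnot(is.matrix(counts), ncol(counts) == length(gene_lengths))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- sweep(counts, 2, gene_lengths, "/")
  tot <- rowSums(rate)
  if (any(tot == 0)) {
    bad <- rownames(counts)[tot == 0]
    stop("sample(s) with all-zero counts: ", paste(bad, collapse = ", "))
  }
  abundance_table(rate / tot, "gene")
}

#' Aggregate gene abundances into group values by quantile
#'
#' Per sample, a group's value is the \code{q}-quantile (linear interpolation
#' between order statistics, R type 7) of its member genes' abundances. The
#' default q = 0.75 matches the CAG and pathway aggregation rule. Membership
#' may be many-to-one (CAGs) or many-to-many (pathways).
#'
#' @param gene_table gene \code{abund_table}.
#' @param membership a [cag_assignment()], a named gene -> group vector, or a
#'   list mapping group id -> character vector of member genes.
#' @param q quantile in [0, 1].
#' @param kind feature kind of the output table.
#' @return \code{abund_table} with one column per group.
#' @export
aggregate_quantile <- function(gene_table, membership, q = 0.75, kind = "cag") {
  stopifnot(inherits(gene_table, "abund_table"), q >= 0, q <= 1)
  groups <- if (inherits(membership, "cag_assignment")) {
    split(names(membership$membership), membership$membership)
  } else if (is.list(membership)) {
    membership
  } else {
    split(names(membership), membership)
  }
  if (length(groups) == 0 || any(lengths(groups) == 0)) stop("empty group in membership")
  missing_genes <- setdiff(unique(unlist(groups)), colnames(gene_table))
  if (length(missing_genes) > 0) {
    stop("membership refers to genes absent from the table: ",
         paste(utils::head(missing_genes, 3), collapse = ", "))
  }
  out <- vapply(groups, function(g) {
    sub <- gene_table[, g, drop = FALSE]
    apply(sub, 1, stats::quantile, probs = q, names = FALSE, type = 7)
  }, numeric(nrow(gene_table)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(rownames(gene_table), names(groups)))
  rownames(out) <- rownames(gene_table)
  abundance_table(out, kind, closed = FALSE)
}

# fast per-feature univariate screens; features are scaled to unit SD first.
# continuous target: simple linear regression Wald test in closed form;
# categorical target: per-feature logistic fits, one-vs-rest for multinomial,
# keeping each feature's minimum p and maximum |coefficient|.
univariate_screen <- function(x, y) {
  p <- ncol(x)
  coefs <- pvals <- rep(NA_real_, p)
  if (is.numeric(y)) {
    n <- nrow(x)
    r <- suppressWarnings(stats::cor(x, y))
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    pvals <- 2 * stats::pt(-abs(tstat), df = n - 2)
    coefs <- as.numeric(r) * stats::sd(y)  # slope on unit-SD feature
  } else {
    y <- factor(y)
    levs <- levels(y)
    targets <- if (length(levs) == 2) list(y == levs[2]) else lapply(levs, function(l) y == l)
    for (j in seq_len(p)) {
      best_p <- Inf; best_c <- 0
      for (tv in targets) {
        fit <- tryCatch(
          suppressWarnings(stats::glm(tv ~ x[, j], family = stats::binomial())),
          error = function(e) NULL)
        if (is.null(fit) || nrow(stats::coef(summary(fit))) < 2) next
        sm <- stats::coef(summary(fit))[2, ]
        if (is.finite(sm["Pr(>|z|)"]) && sm["Pr(>|z|)"] < best_p) best_p <- sm["Pr(>|z|)"]
        if (is.finite(sm["Estimate"]) && abs(sm["Estimate"]) > abs(best_c)) best_c <- sm["Estimate"]
      }
      pvals[j] <- if (is.finite(best_p)) best_p else NA_real_
      coefs[j] <- best_c
    }
  }
  data.frame(feature = colnames(x), coef = as.numeric(coefs),
             p_value = as.numeric(pvals), stringsAsFactors = FALSE)
}

#' Univariate feature filtering on a training fold
#'
#' Each feature is scaled to unit SD and regressed one at a time against the
#' target (linear regression for a continuous target, logistic for a
#' categorical one; multinomial targets use one-vs-rest fits keeping the
#' minimum p and maximum |coefficient|). Selection, with
#' \code{max_features = 1000} and \code{alpha = 0.05}:
#' \itemize{
#'   \item more than 1,000 features with p < alpha: the 1,000 with the largest
#'     |scaled coefficient| among them (\code{rule = "coef-top-k"});
#'   \item otherwise, if the table has more than 1,000 features: the 1,000
#'     smallest p-values (\code{rule = "p-top-k"});
#'   \item a table with at most 1,000 features: all of them (\code{rule = "all"}).
#' }
#' Zero-variance features are excluded before regression with a warning.
#'
#' @param train_table \code{abund_table} restricted to training-fold rows.
#' @param target the target vector aligned to \code{train_table} rows.
#' @param max_features selection cap.
#' @param alpha liberal significance threshold for the first rule.
#' @return a \code{filter_report}: list with \code{stats} (per-feature scaled
#'   coefficient and p-value), \code{selected}, \code{rule}.
#' @export
filter_features <- function(train_table, target, max_features = 1000, alpha = 0.05) {
  stopifnot(nrow(train_table) == length(target))
  if (anyNA(target)) stop("target must be complete on the training fold")
  sds <- apply(train_table, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    drop <- colnames(train_table)[sds == 0 | is.na(sds)]
    warning(length(drop), " zero-variance feature(s) excluded from filtering")
    train_table <- train_table[, !(colnames(train_table) %in% drop), drop = FALSE]
    sds <- sds[!(names(sds) %in% drop)]
  }
  x <- sweep(unclass(train_table), 2, sds, "/")
  stats_df <- univariate_screen(x, target)
  ok <- is.finite(stats_df$p_value)
  n_total <- nrow(stats_df)
  sig <- which(ok & stats_df$p_value < alpha)
  if (n_total <= max_features) {
    selected <- stats_df$feature
    rule <- "all"
  } else if (length(sig) > max_features) {
    ord <- sig[order(-abs(stats_df$coef[sig]), stats_df$feature[sig])]
    selected <- stats_df$feature[ord[seq_len(max_features)]]
    rule <- "coef-top-k"
  } else {
    ord <- order(stats_df$p_value, stats_df$feature)
    selected <- stats_df$feature[ord[seq_len(max_features)]]
    rule <- "p-top-k"
  }
  structure(list(stats = stats_df, selected = selected, rule = rule,
                 alpha = alpha, max_features = max_features),
            class = "filter_report")
}

#' Extract member genes of the most predictive CAGs
#'
#' Restricts the gene table to members of the \code{n_cags} highest-importance
#' CAGs from a fitted model, then keeps only genes whose univariate
#' association with the target passes a Bonferroni-corrected threshold
#' (\code{alpha / number of candidate genes}).
#'
#' @param importances named numeric vector of CAG importances (e.g. from a
#'   \code{model_result}).
#' @param assignment the [cag_assignment()] used to build the CAG table.
#' @param gene_table gene \code{abund_table}.
#' @param target target vector aligned to \code{gene_table} rows.
#' @param n_cags number of top CAGs to expand (default 10).
#' @param alpha family-wise error rate for the Bonferroni rule.
#' @return gene \code{abund_table} restricted to passing genes (possibly with
#'   zero columns, with a warning).
#' @export
extract_genes_from_top_cags <- function(importances, assignment, gene_table,
                                        target, n_cags = 10, alpha = 0.05) {
  imp <- sort(importances[importances > 0], decreasing = TRUE)
  if (length(imp) < n_cags) {
    warning("only ", length(imp), " CAGs with nonzero importance; using all of them")
    n_cags <- length(imp)
  }
  top <- names(imp)[seq_len(n_cags)]
  genes <- names(assignment$membership)[assignment$membership %in% top]
  genes <- intersect(genes, colnames(gene_table))
  if (length(genes) == 0) stop("top CAGs contribute no genes present in the table")
  sub <- gene_table[, genes, drop = FALSE]
  sds <- apply(sub, 2, stats::sd)
  sub <- sub[, sds > 0, drop = FALSE]
  x <- sweep(unclass(sub), 2, apply(sub, 2, stats::sd), "/")
  scr <- univariate_screen(x, target)
  thr <- alpha / length(genes)
  pass <- scr$feature[is.finite(scr$p_value) & scr$p_value < thr]
  if (length(pass) == 0) {
    warning("no gene passes the Bonferroni threshold ", format(thr),
            "; returning an empty gene table")
  }
  out <- gene_table[, pass, drop = FALSE]
  abundance_table(as.matrix(out), "gene", closed = FALSE)
}

#' Inverse-frequency class weights
#'
#' Per-sample weights proportional to the inverse of the class frequency,
#' normalized to mean one (so the weighted total equals the sample count).
#'
#' @param labels categorical vector with at least two classes present.
#' @return numeric vector of per-sample weights, named by class.
#' @export
class_weights <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels must be complete")
  freq <- table(labels) / length(labels)
  if (length(freq) < 2) stop("class weights need at least two classes present")
  w <- 1 / freq[labels]
  w <- as.numeric(w / mean(w))
  stats::setNames(w, labels)
}
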
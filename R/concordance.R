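#' Importance-weighted feature-ranking vector
#'
#' The estimator's native relative importances over the filtered feature
#' universe, normalized to sum one; features absent from the model's
#' importance output get weight zero. Provenance (phenotype, data type,
#' estimator, fold policy) is carried for grouping.
#'
#' @param importances named non-negative numeric vector (e.g. the per-fold
#'   average from a \code{model_result}).
#' @param feature_universe character vector of the compared feature set.
#' @param provenance named list (phenotype, data_type, estimator, ...).
#' @return an \code{importance_vector}: numeric vector named by
#'   \code{feature_universe} with a \code{provenance} attribute.
#' @export
importance_vector <- function(importances, feature_universe,
                              provenance = list()) {
  if (is.null(names(importances))) stop("importances must be named by feature")
  if (any(!is.finite(importances))) stop("importances must be finite")
  if (any(importances < 0)) stop("importances must be non-negative")
  w <- stats::setNames(rep(0, length(feature_universe)), feature_universe)
  common <- intersect(names(importances), feature_universe)
  w[common] <- importances[common]
  if (sum(w) == 0) stop("degenerate model: all importances are zero on the universe")
  w <- w / sum(w)
  structure(w, provenance = provenance, class = c("importance_vector", "numeric"))
}

#' Pairwise Spearman concordance between importance vectors
#'
#' Spearman rho (average-rank tie handling) between every pair of vectors,
#' which must share an identical feature universe.
#'
#' @param vectors named list of \code{importance_vector}s.
#' @return symmetric \code{concordance_matrix} with unit diagonal.
#' @export
pairwise_spearman <- function(vectors) {
  if (length(vectors) < 2) stop("need at least 2 importance vectors")
  universes <- lapply(vectors, names)
  for (i in seq_along(universes)[-1]) {
    if (!identical(universes[[1]], universes[[i]])) {
      stop("importance vectors must share an identical feature universe")
    }
  }
  m <- do.call(cbind, lapply(vectors, as.numeric))
  colnames(m) <- names(vectors) %||% paste0("v", seq_along(vectors))
  rho <- stats::cor(m, method = "spearman")
  structure(rho, class = c("concordance_matrix", "matrix", "array"))
}

#' Per-label average concordance
#'
#' For each label, the mean of the off-diagonal Spearman rhos involving it.
#'
#' @param matrix a \code{concordance_matrix}.
#' @return named numeric vector of average rhos.
#' @export
average_concordance <- function(matrix) {
  if (nrow(matrix) < 2) stop("average concordance undefined for a single label")
  if (max(abs(matrix - t(matrix))) > 1e-8) stop("concordance matrix must be symmetric")
  out <- vapply(seq_len(nrow(matrix)), function(i) {
    mean(matrix[i, -i])
  }, numeric(1))
  stats::setNames(out, rownames(matrix))
}
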
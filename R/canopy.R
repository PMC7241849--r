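#' Canopy clustering parameters
#'
#' Defaults mirror the standard co-abundance gene-grouping settings: canopies
#' are grown around seed profiles within a correlation distance of 0.1
#' (Pearson >= 0.9), genes within 0.4 of a centroid are retired from the seed
#' pool, canopies whose centroids lie within 0.1 of each other are merged,
#' and centroids are refined over at most 5 walks stopping when a centroid
#' moves less than 0.005.
#'
#' @param max_canopy_dist membership radius (1 - Pearson).
#' @param max_close_dist seed-retirement radius.
#' @param max_merge_dist centroid merge radius.
#' @param min_step_dist centroid-walk convergence threshold.
#' @param max_num_canopy_walks maximum centroid refinement iterations.
#' @param stop_fraction stop seeding once this fraction of genes is covered.
#' @param min_correlation member correlation implied by
#'   \code{max_canopy_dist} (recorded for provenance).
#' @export
canopy_params <- function(max_canopy_dist = 0.1, max_close_dist = 0.4,
                          max_merge_dist = 0.1, min_step_dist = 0.005,
                          max_num_canopy_walks = 5, stop_fraction = 1,
                          min_correlation = 0.9) {
  dists <- c(max_canopy_dist, max_close_dist, max_merge_dist, min_step_dist)
  if (any(dists < 0 | dists > 2)) stop("correlation distances must lie in [0, 2]")
  if (max_num_canopy_walks < 0) stop("max_num_canopy_walks must be >= 0")
  if (stop_fraction <= 0 || stop_fraction > 1) stop("stop_fraction must be in (0, 1]")
  list(max_canopy_dist = max_canopy_dist, max_close_dist = max_close_dist,
       max_merge_dist = max_merge_dist, min_step_dist = min_step_dist,
       max_num_canopy_walks = max_num_canopy_walks,
       stop_fraction = stop_fraction, min_correlation = min_correlation)
}

# 1 - Pearson distance between a profile vector and the columns of a matrix
cor_dist <- function(centroid, profiles) {
  1 - suppressWarnings(as.numeric(stats::cor(centroid, profiles)))
}

#' Cluster co-abundant genes into CAGs by canopy clustering
#'
#' Works on 1 - Pearson distance between gene abundance profiles. Candidate
#' seeds are processed in order of decreasing mean abundance (ties broken
#' lexicographically by gene id). Each seed grows a canopy of genes within
#' \code{max_canopy_dist} of the centroid; the centroid (element-wise mean
#' profile of members) is re-walked up to \code{max_num_canopy_walks} times,
#' stopping early when it moves less than \code{min_step_dist}. Genes within
#' \code{max_close_dist} of an accepted centroid leave the seed pool.
#' Canopies whose centroids are within \code{max_merge_dist} are merged
#' (iteratively, closest pair first). Each gene is finally assigned to the
#' nearest qualifying centroid, and singleton groups are dropped.
#'
#' Zero-variance genes (Pearson undefined) are excluded with a warning.
#'
#' @param gene_table gene \code{abund_table} with at least 2 samples.
#' @param params a [canopy_params()] list.
#' @return a [cag_assignment()]; groups are named \code{CAG0001, ...} in
#'   decreasing size order.
#' @export
canopy_cluster <- function(gene_table, params = canopy_params()) {
  if (nrow(gene_table) < 2) stop("canopy clustering needs at least 2 samples")
  profiles <- t(unclass(gene_table))            # genes x samples -> transpose later
  sds <- apply(profiles, 1, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    warning(sum(sds == 0 | is.na(sds)), " zero-variance gene(s) excluded from clustering")
    profiles <- profiles[sds > 0 & !is.na(sds), , drop = FALSE]
  }
  genes <- rownames(profiles)
  if (length(genes) < 2) stop("fewer than 2 clusterable genes")
  pm <- t(profiles)                             # samples x genes, for cor()

  mean_ab <- colMeans(pm)
  seed_order <- genes[order(-mean_ab, genes)]
  in_pool <- stats::setNames(rep(TRUE, length(genes)), genes)
  covered <- stats::setNames(rep(FALSE, length(genes)), genes)

  centroids <- list(); members <- list()
  for (g in seed_order) {
    if (!in_pool[[g]]) next
    if (mean(covered) >= params$stop_fraction) break
    centroid <- pm[, g]
    mem <- g
    for (walk in seq_len(max(params$max_num_canopy_walks, 1))) {
      d <- cor_dist(centroid, pm)
      mem <- genes[!is.na(d) & d <= params$max_canopy_dist]
      if (length(mem) == 0) mem <- g
      new_centroid <- rowMeans(pm[, mem, drop = FALSE])
      moved <- cor_dist(new_centroid, matrix(centroid, ncol = 1))
      centroid <- new_centroid
      if (is.na(moved) || moved < params$min_step_dist ||
          walk >= params$max_num_canopy_walks) break
    }
    centroids[[length(centroids) + 1L]] <- centroid
    members[[length(members) + 1L]] <- mem
    d_close <- cor_dist(centroid, pm)
    in_pool[!is.na(d_close) & d_close <= params$max_close_dist] <- FALSE
    in_pool[[g]] <- FALSE
    covered[mem] <- TRUE
  }

  # merge canopies whose centroids are within max_merge_dist, closest pair first
  repeat {
    k <- length(centroids)
    if (k < 2) break
    cm <- do.call(cbind, centroids)
    dd <- 1 - suppressWarnings(stats::cor(cm))
    diag(dd) <- Inf
    if (min(dd, na.rm = TRUE) > params$max_merge_dist) break
    idx <- which(dd == min(dd, na.rm = TRUE), arr.ind = TRUE)[1, ]
    i <- min(idx); j <- max(idx)
    mem <- union(members[[i]], members[[j]])
    members[[i]] <- mem
    centroids[[i]] <- rowMeans(pm[, mem, drop = FALSE])
    members[[j]] <- NULL; centroids[[j]] <- NULL
  }

  # final assignment: each gene to its nearest centroid within max_canopy_dist
  cm <- do.call(cbind, centroids)
  dmat <- 1 - suppressWarnings(stats::cor(pm, cm))   # genes x canopies
  nearest <- apply(dmat, 1, which.min)
  nearest_d <- dmat[cbind(seq_along(nearest), nearest)]
  keep <- !is.na(nearest_d) & nearest_d <= params$max_canopy_dist
  assign <- stats::setNames(nearest[keep], genes[keep])

  sizes <- table(assign)
  groups_keep <- names(sizes)[sizes >= 2]
  assign <- assign[assign %in% as.integer(groups_keep)]
  if (length(assign) == 0) stop("no co-abundance group with >= 2 members found")
  # relabel in decreasing size order
  ord <- names(sort(table(assign), decreasing = TRUE))
  relabel <- stats::setNames(sprintf("CAG%04d", seq_along(ord)), ord)
  cag_assignment(stats::setNames(relabel[as.character(assign)], names(assign)),
                 params = params)
}
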
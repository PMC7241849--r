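# shared fixture builders; all randomness is seeded by the caller

tiny_design <- function(n_subjects = 30, seed = 1L, samples = c(2, 3)) {
  study_design(n_subjects = n_subjects, samples_per_subject = samples, seed = seed)
}

# two well-separated gene blocks plus unclustered background genes
two_block_spec <- function(n1 = 6, n2 = 5, rho = 0.96, n_background = 12) {
  blocks <- data.frame(
    block = c("B001", "B002", sprintf("U%03d", seq_len(n_background))),
    n_genes = c(n1, n2, rep(1, n_background)),
    rho = c(rho, rho, rep(0.99, n_background)))
  signal_spec(blocks)
}

# independent oracle: exhaustive threshold clustering — connected components
# of the "Pearson >= r" gene graph, singletons dropped
oracle_threshold_clusters <- function(mat, r = 0.9) {
  cm <- suppressWarnings(stats::cor(mat))
  adj <- !is.na(cm) & cm >= r
  diag(adj) <- TRUE
  n <- ncol(mat)
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  names(comp) <- colnames(mat)
  comp <- comp[comp %in% as.integer(names(table(comp))[table(comp) >= 2])]
  split(names(comp), comp)
}

# canonical form of a partition for comparison: sorted list of sorted member sets
partition_sets <- function(groups) {
  gs <- lapply(groups, sort)
  unname(gs[order(vapply(gs, `[`, "", 1))])
}

cag_partition <- function(assignment) {
  partition_sets(split(names(assignment$membership), assignment$membership))
}

# independent order-statistics quantile (linear interpolation between order
# statistics), written without stats::quantile
manual_quantile <- function(x, q) {
  x <- sort(unname(x))
  n <- length(x)
  if (n == 1) return(x)
  h <- (n - 1) * q + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
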
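#' Describe a synthetic longitudinal study design
#'
#' The generator emulates an infant-cohort metagenomic study: several hundred
#' subjects sampled repeatedly over their first years of life across a handful
#' of cohorts, with subject-level demographics (sex, country, delivery mode)
#' and sample-level phenotypes (exclusive breastfeeding, antibiotic usage,
#' age at collection).
#'
#' @param n_subjects number of infants.
#' @param samples_per_subject integer range \code{c(lo, hi)}; each subject
#'   contributes a uniform number of samples in this range.
#' @param cohorts named numeric vector of cohort sampling probabilities.
#' @param age_range_days \code{c(lo, hi)} age window in days.
#' @param phenotype_prevalences named list of named class-probability vectors
#'   for the categorical phenotypes (\code{sex}, \code{country},
#'   \code{delivery}, \code{breastfeeding}, \code{antibiotics}).
#' @param seed integer seed; all generator randomness flows from it.
#' @return a \code{study_design} list.
#' @export
study_design <- function(n_subjects = 300,
                         samples_per_subject = c(3, 7),
                         cohorts = c(cohort_a = 0.35, cohort_b = 0.25,
                                     cohort_c = 0.25, cohort_d = 0.15),
                         age_range_days = c(14, 1095),
                         phenotype_prevalences = list(
                           sex = c(female = 0.5, male = 0.5),
                           country = c(FIN = 0.4, EST = 0.3, RUS = 0.3),
                           delivery = c(vaginal = 0.9, cesarean = 0.1),
                           breastfeeding = c(no = 0.4, yes = 0.6),
                           antibiotics = c(no = 0.7, yes = 0.3)
                         ),
                         seed = 1L) {
  stopifnot(n_subjects >= 2, length(samples_per_subject) == 2,
            samples_per_subject[1] >= 1,
            samples_per_subject[1] <= samples_per_subject[2],
            age_range_days[1] < age_range_days[2])
  check_probs <- function(p, what) {
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("invalid prevalence map for ", what, ": named, non-negative, summing to 1 required")
    }
  }
  check_probs(cohorts, "cohorts")
  for (ph in names(phenotype_prevalences)) check_probs(phenotype_prevalences[[ph]], ph)
  structure(list(n_subjects = as.integer(n_subjects),
                 samples_per_subject = as.integer(samples_per_subject),
                 cohorts = cohorts,
                 age_range_days = age_range_days,
                 phenotype_prevalences = phenotype_prevalences,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Describe planted co-abundance structure and phenotype effects
#'
#' Genes are organized into blocks sharing a latent log-normal abundance
#' factor; blocks of size >= 2 are the ground-truth co-abundance groups.
#' Effects shift a block's latent log-abundance as a function of a phenotype:
#' \code{linear} adds \code{effect * scale(age)}, \code{threshold} adds a step
#' at the age midpoint, \code{unimodal} adds a Gaussian bump in age, and for
#' categorical phenotypes the shift applies to the non-reference class
#' (so an effect of 1 separates the classes by one latent SD, roughly one
#' log-odds unit per SD of block abundance).
#'
#' @param blocks data.frame with columns \code{block} (id), \code{n_genes},
#'   \code{rho} (within-block Pearson target on the abundance scale, in (0,1]).
#' @param effects data.frame with columns \code{block}, \code{phenotype},
#'   \code{effect}, \code{form} (\code{linear}, \code{threshold} or
#'   \code{unimodal}); empty for null data.
#' @param noise_sd floor on the gene-level residual log-SD (the residual is
#'   otherwise calibrated to hit the block correlation target).
#' @param null logical; TRUE asserts no planted effects.
#' @param block_sd latent block-factor log-SD.
#' @param subject_sd SD of subject-level random intercepts on block factors
#'   (drives repeated-measures correlation).
#' @return a \code{signal_spec} list.
#' @export
signal_spec <- function(blocks, effects = NULL, noise_sd = 0.05, null = FALSE,
                        block_sd = 0.8, subject_sd = 0.25) {
  stopifnot(is.data.frame(blocks),
            all(c("block", "n_genes", "rho") %in% names(blocks)))
  if (any(blocks$rho <= 0 | blocks$rho > 1)) stop("within-block rho targets must be in (0, 1]")
  if (any(blocks$n_genes < 1)) stop("block sizes must be >= 1")
  if (anyDuplicated(blocks$block)) stop("duplicate block ids")
  if (is.null(effects)) {
    effects <- data.frame(block = character(), phenotype = character(),
                          effect = numeric(), form = character())
  }
  stopifnot(all(c("block", "phenotype", "effect", "form") %in% names(effects)))
  if (!all(is.finite(effects$effect))) stop("effect sizes must be finite")
  if (!all(effects$form %in% c("linear", "threshold", "unimodal"))) {
    stop("effect forms must be linear, threshold or unimodal")
  }
  if (!all(effects$block %in% blocks$block)) stop("effects refer to unknown blocks")
  if (null && nrow(effects) > 0) stop("null = TRUE requires an empty effects list")
  if (noise_sd <= 0 || block_sd <= 0 || subject_sd < 0) stop("SDs must be positive")
  structure(list(blocks = blocks, effects = effects, noise_sd = noise_sd,
                 null = null, block_sd = block_sd, subject_sd = subject_sd),
            class = "signal_spec")
}

#' Convenience: a spec of equally sized blocks
#' @param n_blocks number of blocks.
#' @param genes_per_block genes per block.
#' @param rho within-block Pearson target.
#' @param ... passed to [signal_spec()].
#' @export
uniform_blocks <- function(n_blocks, genes_per_block, rho = 0.95, ...) {
  signal_spec(data.frame(block = sprintf("B%03d", seq_len(n_blocks)),
                         n_genes = genes_per_block, rho = rho), ...)
}

#' Generate per-sample metadata for a study design
#'
#' Subject-level attributes (cohort, sex, country, delivery mode) are constant
#' across a subject's samples; ages increase across a subject's repeated
#' samples; breastfeeding status follows a weaning curve (exclusive
#' breastfeeding becomes rarer with age) and antibiotic usage is drawn per
#' sample with a subject-level propensity. Deterministic for a fixed seed.
#'
#' @param design a [study_design()].
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{subject_id}, \code{cohort}, \code{age_days}, \code{sex},
#'   \code{country}, \code{delivery}, \code{breastfeeding}, \code{antibiotics}.
#' @export
generate_metadata <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  pv <- design$phenotype_prevalences
  draw <- function(p, n) names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
  ns <- design$n_subjects
  subj <- sprintf("S%04d", seq_len(ns))
  n_samp <- sample(seq(design$samples_per_subject[1], design$samples_per_subject[2]),
                   ns, replace = TRUE)
  cohort <- draw(design$cohorts, ns)
  sex <- draw(pv$sex, ns)
  country <- draw(pv$country, ns)
  delivery <- draw(pv$delivery, ns)
  abx_propensity <- stats::rbeta(ns, 2, 2)  # subject-level antibiotic propensity
  lo <- design$age_range_days[1]; hi <- design$age_range_days[2]
  rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    m <- n_samp[i]
    ages <- sort(round(stats::runif(m, lo, hi)))
    # exclusive breastfeeding declines with age toward the stated prevalence
    p_bf <- pv$breastfeeding[["yes"]] * 2 * (1 - stats::plogis((ages - lo) / (hi - lo) * 6 - 2))
    bf <- ifelse(stats::runif(m) < pmin(p_bf, 0.95), "yes", "no")
    p_abx <- pv$antibiotics[["yes"]] * 2 * abx_propensity[i]
    abx <- ifelse(stats::runif(m) < pmin(p_abx, 0.95), "yes", "no")
    rows[[i]] <- data.frame(
      sample_id = sprintf("%s_T%02d", subj[i], seq_len(m)),
      subject_id = subj[i], cohort = cohort[i], age_days = ages,
      sex = sex[i], country = country[i], delivery = delivery[i],
      breastfeeding = bf, antibiotics = abx,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# latent Gaussian correlation needed so that corr(exp X, exp Y) hits `rho`
# when X, Y are N(., s^2): invert (e^{r s^2} - 1)/(e^{s^2} - 1) = rho
latent_rho <- function(rho, s) {
  r <- log(1 + rho * (exp(s^2) - 1)) / s^2
  min(r, 1)
}

#' Generate a gene relative-abundance matrix with planted block structure
#'
#' Member genes of a block share a log-normal latent factor (with
#' subject-level random intercepts for repeated measures) plus independent
#' gene-level log-normal noise calibrated so the realized pairwise Pearson
#' correlation on the abundance scale matches the block's target. Phenotype
#' effects shift block factors per the [signal_spec()]. Rows are closed to
#' sum to one.
#'
#' @param design a [study_design()].
#' @param signal a [signal_spec()].
#' @param metadata optional metadata from [generate_metadata()]; generated
#'   from \code{design} if omitted.
#' @return list with \code{genes} (an \code{abund_table}), \code{truth}
#'   (ground-truth [cag_assignment()] of blocks with >= 2 genes) and
#'   \code{metadata}.
#' @export
generate_gene_abundances <- function(design, signal, metadata = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(signal, "signal_spec"))
  if (is.null(metadata)) metadata <- generate_metadata(design)
  set.seed(hash_seed(design$seed, "gene-abundances"))
  blocks <- signal$blocks
  n_genes <- sum(blocks$n_genes)
  n <- nrow(metadata)
  subj_idx <- match(metadata$subject_id, unique(metadata$subject_id))
  n_subj <- max(subj_idx)

  age_z <- as.numeric(scale(metadata$age_days))
  pheno_shift <- function(eff) {
    ph <- metadata[[eff$phenotype]]
    if (is.null(ph)) stop("effect refers to unknown phenotype: ", eff$phenotype)
    if (eff$phenotype == "age_days" || is.numeric(ph)) {
      switch(eff$form,
             linear = eff$effect * age_z,
             threshold = eff$effect * (metadata$age_days >
                                         mean(range(metadata$age_days))),
             unimodal = {
               # bump centers tile the age axis in effect-list order, the
               # way successional taxa peak at different ages
               rng <- range(metadata$age_days)
               ctr <- rng[1] + (0.1 + 0.8 * eff$.tile) * diff(rng)
               wid <- diff(rng) / 6
               eff$effect * exp(-(metadata$age_days - ctr)^2 / (2 * wid^2))
             })
    } else {
      # categorical: shift applies to the non-reference (last-alphabetical) class
      lev <- sort(unique(ph))
      eff$effect * (ph == lev[length(lev)])
    }
  }

  s_total <- sqrt(signal$block_sd^2 + signal$subject_sd^2)
  # pass 1: block latent factors and noise-free gene log-abundances
  zmat <- matrix(0, n, nrow(blocks))
  log0 <- matrix(0, n, n_genes)
  gene_ids <- character(n_genes)
  gene_block <- character(n_genes)
  col <- 0L
  for (b in seq_len(nrow(blocks))) {
    bid <- blocks$block[b]
    k <- blocks$n_genes[b]
    mu_b <- stats::rnorm(1, 0, 1.2)           # heavy-tailed block means
    u <- stats::rnorm(n_subj, 0, signal$subject_sd)[subj_idx]
    z <- mu_b + u + stats::rnorm(n, 0, signal$block_sd)
    effs <- signal$effects[signal$effects$block == bid, , drop = FALSE]
    if (nrow(effs) > 0) {
      for (e in seq_len(nrow(effs))) {
        eff <- as.list(effs[e, ])
        # position of this effect among the unimodal effects of its
        # phenotype, as a fraction in (0, 1): spreads bump centers
        uni <- which(signal$effects$form == "unimodal" &
                       signal$effects$phenotype == eff$phenotype)
        pos <- match(rownames(effs)[e], rownames(signal$effects)[uni])
        eff$.tile <- if (is.na(pos)) 0.5 else (pos - 0.5) / length(uni)
        z <- z + s_total * pheno_shift(eff)
      }
    }
    zmat[, b] <- z
    for (g in seq_len(k)) {
      col <- col + 1L
      gene_ids[col] <- sprintf("%s_g%03d", bid, g)
      gene_block[col] <- bid
      m_g <- stats::rnorm(1, 0, 0.4)          # per-gene abundance offset
      log0[, col] <- z + m_g
    }
  }
  # pass 2: gene-level noise calibrated against the shared variance that
  # survives closure. After closing, a member gene's shared component is
  # z - log(total); its variance (not the latent block variance) is what the
  # gene residual must be balanced against for the abundance-scale Pearson
  # to hit the block target. noise_sd is a floor on the residual.
  logT0 <- log(rowSums(exp(log0)))
  log_ab <- log0
  for (b in seq_len(nrow(blocks))) {
    s_eff2 <- stats::var(zmat[, b] - logT0)
    rho <- blocks$rho[b]
    v_needed <- log(1 + (exp(s_eff2) - 1) / rho)
    sd_g <- sqrt(max(v_needed - s_eff2, signal$noise_sd^2, 1e-12))
    cols_b <- which(gene_block == blocks$block[b])
    log_ab[, cols_b] <- log0[, cols_b] +
      matrix(stats::rnorm(n * length(cols_b), 0, sd_g), n, length(cols_b))
  }
  ab <- exp(log_ab)
  ab <- ab / rowSums(ab)
  dimnames(ab) <- list(metadata$sample_id, gene_ids)

  keep <- blocks$block[blocks$n_genes >= 2]
  membership <- stats::setNames(gene_block, gene_ids)[gene_block %in% keep]
  truth <- cag_assignment(membership, params = list(source = "synthetic-truth"))
  list(genes = abundance_table(ab, "gene"), truth = truth, metadata = metadata)
}

#' Collapse ground-truth gene blocks into taxon abundances
#'
#' Synthetic analogue of a taxonomic profiler's output: each ground-truth
#' block becomes one taxon whose abundance is the sum of its member genes,
#' renormalized so rows sum to one.
#'
#' @param gene_table gene \code{abund_table}.
#' @param truth ground-truth [cag_assignment()].
#' @return taxon \code{abund_table} with one column per ground-truth block.
#' @export
generate_taxa_abundances <- function(gene_table, truth) {
  stopifnot(inherits(gene_table, "abund_table"))
  groups <- split(names(truth$membership), truth$membership)
  if (length(groups) == 0) stop("truth assignment has no groups")
  taxa <- vapply(groups, function(g) {
    g <- intersect(g, colnames(gene_table))
    rowSums(gene_table[, g, drop = FALSE])
  }, numeric(nrow(gene_table)))
  taxa <- taxa / rowSums(taxa)
  colnames(taxa) <- paste0("tax_", names(groups))
  abundance_table(taxa, "taxon")
}

#' Run the full synthetic generator
#'
#' @param design a [study_design()].
#' @param signal a [signal_spec()].
#' @return list with \code{metadata}, \code{genes}, \code{taxa}, \code{truth}.
#' @export
simulate_study <- function(design, signal) {
  metadata <- generate_metadata(design)
  g <- generate_gene_abundances(design, signal, metadata)
  taxa <- generate_taxa_abundances(g$genes, g$truth)
  list(metadata = metadata, genes = g$genes, taxa = taxa, truth = g$truth)
}
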
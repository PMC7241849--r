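#' Declare a tunable hyperparameter
#'
#' The search operates on an untransformed coordinate axis \code{lo, lo +
#' stride, ..., hi}; \code{transform} maps coordinates to the values handed
#' to the estimator (applied after sequence construction, so monotone
#' transforms preserve grid order). \code{hard_lo}/\code{hard_hi} bound the
#' coordinates the pseudo-gradient stage may ever explore. Alternatively an
#' explicit candidate set may be given via \code{values}, in which case the
#' grid is fixed (no boundary extension, no fine tuning).
#'
#' @param name hyperparameter name as the estimator knows it.
#' @param lo,hi initial grid extrema (coordinate scale).
#' @param stride initial grid step (> 0).
#' @param transform \code{"identity"}, \code{"pow2"} (2^x), \code{"pow10"}
#'   (10^x), or a monotone function.
#' @param hard_lo,hard_hi limits of the explorable coordinate range.
#' @param n_fine number of fine-tuning grid points (>= 2).
#' @param integer round transformed values to integers.
#' @param values optional explicit candidate values (overrides the grid).
#' @export
hyper_spec <- function(name, lo = NA, hi = NA, stride = NA,
                       transform = "identity",
                       hard_lo = -Inf, hard_hi = Inf,
                       n_fine = 5, integer = FALSE, values = NULL) {
  if (is.null(values)) {
    stopifnot(is.finite(lo), is.finite(hi), lo <= hi, stride > 0, n_fine >= 2)
    if (lo < hard_lo || hi > hard_hi) stop("initial grid exceeds hard limits")
  }
  tf <- if (is.function(transform)) transform else switch(
    transform,
    identity = identity,
    pow2 = function(x) 2^x,
    pow10 = function(x) 10^x,
    stop("unknown transform: ", transform))
  structure(list(name = name, lo = lo, hi = hi, stride = stride,
                 transform = tf, hard_lo = hard_lo, hard_hi = hard_hi,
                 n_fine = n_fine, integer = integer, values = values),
            class = "hyper_spec")
}

spec_coords <- function(spec) {
  if (!is.null(spec$values)) return(seq_along(spec$values))
  seq(spec$lo, spec$hi, by = spec$stride)
}

spec_value <- function(spec, coord) {
  if (!is.null(spec$values)) return(spec$values[[coord]])
  v <- spec$transform(coord)
  if (spec$integer) v <- round(v)
  v
}

#' Build the initial coarse hyperparameter grid
#'
#' Cartesian product of each spec's sequence \code{lo, lo + stride, ..., hi},
#' mapped through its transform.
#'
#' @param specs list of [hyper_spec()]s.
#' @return data.frame of hyper-value combinations (one column per spec).
#' @export
coarse_grid <- function(specs) {
  stopifnot(length(specs) > 0)
  vals <- lapply(specs, function(s) {
    vapply(spec_coords(s), function(cc) spec_value(s, cc), numeric(1))
  })
  names(vals) <- vapply(specs, `[[`, "", "name")
  expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
}

#' Decide whether a candidate may replace the incumbent best
#'
#' A newly best-scoring hyperparameter combination is accepted only if the
#' fitted model can actually produce predictions: any non-finite prediction
#' on the training rows rejects the candidate and the incumbent is kept.
#'
#' @param predictions numeric (or factor) predictions on the training rows.
#' @return \code{"accept"} or \code{"reject"}.
#' @export
guard_predictions <- function(predictions) {
  if (length(predictions) == 0) return("reject")
  if (is.factor(predictions) || is.character(predictions)) {
    if (anyNA(predictions)) "reject" else "accept"
  } else {
    if (all(is.finite(predictions))) "accept" else "reject"
  }
}

coord_key <- function(coords) paste(format(coords, digits = 12), collapse = ",")

# shared evaluation engine for the three tuning stages.
# evaluator(values) -> numeric score (higher better); NA or error = failure.
# guard(values) -> predictions on training rows (optional).
new_tuner_state <- function(specs, evaluator, guard, score_round) {
  nm <- vapply(specs, `[[`, "", "name")
  names(specs) <- nm
  env <- new.env(parent = emptyenv())
  env$specs <- specs
  env$evaluator <- evaluator
  env$guard <- guard
  env$score_round <- score_round
  env$trace <- data.frame(matrix(numeric(0), 0, length(nm),
                                 dimnames = list(NULL, nm)),
                          score = numeric(0), stage = character(0),
                          status = character(0))
  env$best_score <- -Inf
  env$best_coords <- NULL
  env$eff_lo <- stats::setNames(vapply(specs, `[[`, 0, "hard_lo"), nm)
  env$eff_hi <- stats::setNames(vapply(specs, `[[`, 0, "hard_hi"), nm)
  env
}

tuner_eval <- function(st, coords, stage) {
  key <- coord_key(coords)
  if (key %in% rownames(st$trace)) return(invisible(NULL))
  values <- mapply(function(s, cc) spec_value(s, cc), st$specs, coords,
                   SIMPLIFY = FALSE)
  score <- tryCatch(st$evaluator(values), error = function(e) NA_real_)
  status <- if (!is.finite(score)) "failed" else "ok"
  if (status == "ok" && !is.null(st$guard) &&
      round(score, st$score_round) > round(st$best_score, st$score_round)) {
    pred <- tryCatch(st$guard(values), error = function(e) NA_real_)
    if (guard_predictions(pred) == "reject") status <- "guard_rejected"
  }
  if (status == "ok" && score > st$best_score) {
    st$best_score <- score
    st$best_coords <- coords
  }
  row <- as.data.frame(as.list(coords))
  names(row) <- names(st$specs)
  row$score <- if (is.finite(score)) score else NA_real_
  row$stage <- stage
  row$status <- status
  st$trace <- rbind(st$trace, `rownames<-`(row, key))
  invisible(status)
}

best_tied_rows <- function(st) {
  ok <- st$trace[st$trace$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0) return(ok)
  top <- round(max(ok$score), st$score_round)
  ok[round(ok$score, st$score_round) == top, , drop = FALSE]
}

#' Pseudo-gradient exploration of hyperparameter space
#'
#' Evaluates the coarse grid, then repeatedly extends the explored range of
#' any hyperparameter whose best value sits on the boundary of that range
#' (one stride at a time, in the boundary's direction), re-evaluating at the
#' other hyperparameters' values drawn from the combinations tied for the
#' best score. The loop ends when every hyperparameter's best value is
#' interior to its explored range or pinned at an explorable limit.
#' Evaluation failures shrink the explorable limit of the extended
#' hyperparameter to the last successful value, and the failure is recorded.
#'
#' @param specs list of [hyper_spec()]s.
#' @param evaluator function(named list of hyper values) -> score (higher is
#'   better); throw or return NA to signal failure.
#' @param guard optional function(values) -> training-row predictions, used
#'   by [guard_predictions()] before a candidate may replace the incumbent.
#' @param score_round decimals at which scores are considered tied.
#' @param max_iter cap on extension sweeps.
#' @return a \code{tuner_trace}: list with \code{trace} (evaluated
#'   combinations, scores, stages, statuses), \code{best_coords},
#'   \code{best_score}, \code{eff_lo}/\code{eff_hi} (possibly shrunk limits),
#'   and \code{specs}.
#' @export
pseudo_gradient_descent <- function(specs, evaluator, guard = NULL,
                                    score_round = 6, max_iter = 50) {
  st <- new_tuner_state(specs, evaluator, guard, score_round)
  grid <- expand.grid(lapply(st$specs, spec_coords), KEEP.OUT.ATTRS = FALSE)
  for (i in seq_len(nrow(grid))) {
    tuner_eval(st, unlist(grid[i, , drop = FALSE]), "coarse")
  }
  if (all(st$trace$status != "ok")) {
    stop(structure(class = c("tuner_all_failed", "error", "condition"),
                   list(message = "every hyperparameter combination failed",
                        call = sys.call(), trace = st$trace)))
  }
  nm <- names(st$specs)
  for (iter in seq_len(max_iter)) {
    best <- best_tied_rows(st)
    new_combos <- list()
    shrink_info <- list()
    for (h in nm) {
      sp <- st$specs[[h]]
      if (!is.null(sp$values)) next
      explored <- sort(unique(st$trace[[h]]))
      for (dir in c(1, -1)) {
        bound <- if (dir > 0) max(explored) else min(explored)
        if (!any(abs(best[[h]] - bound) < 1e-12)) next
        cand <- bound + dir * sp$stride
        lim_ok <- if (dir > 0) cand <= st$eff_hi[[h]] + 1e-12 else cand >= st$eff_lo[[h]] - 1e-12
        if (!lim_ok) next
        others <- unique(best[best[[h]] == bound |
                                abs(best[[h]] - bound) < 1e-12,
                              setdiff(nm, h), drop = FALSE])
        for (r in seq_len(max(nrow(others), 1))) {
          coords <- stats::setNames(numeric(length(nm)), nm)
          coords[h] <- cand
          if (nrow(others) > 0) {
            for (o in setdiff(nm, h)) coords[o] <- others[r, o]
          }
          new_combos[[length(new_combos) + 1L]] <- coords
          shrink_info[[length(shrink_info) + 1L]] <-
            list(h = h, dir = dir, cand = cand)
        }
      }
    }
    if (length(new_combos) == 0) break
    for (i in seq_along(new_combos)) {
      status <- tuner_eval(st, new_combos[[i]], "pseudo_gradient")
      if (identical(status, "failed")) {
        si <- shrink_info[[i]]
        if (si$dir > 0) {
          st$eff_hi[[si$h]] <- min(st$eff_hi[[si$h]], si$cand - st$specs[[si$h]]$stride)
        } else {
          st$eff_lo[[si$h]] <- max(st$eff_lo[[si$h]], si$cand + st$specs[[si$h]]$stride)
        }
      }
    }
  }
  structure(list(trace = st$trace, best_coords = st$best_coords,
                 best_score = st$best_score,
                 eff_lo = st$eff_lo, eff_hi = st$eff_hi,
                 specs = st$specs, score_round = score_round,
                 state = st),
            class = "tuner_trace")
}

#' Fine-tune hyperparameters around the pseudo-gradient optimum
#'
#' Per hyperparameter: if several values tied for the best score, the fine
#' grid spans the extrema of the tied values; otherwise it spans from the
#' best value toward the second-best value on one side and half a stride on
#' the other side. \code{n_fine} points are explored per hyperparameter
#' (Cartesian product across hyperparameters), and the best evaluated
#' combination over all stages is returned.
#'
#' @param trace a \code{tuner_trace} from [pseudo_gradient_descent()].
#' @return list with \code{best_values} (named list on the estimator scale),
#'   \code{best_coords}, \code{best_score}, and the updated \code{trace}.
#' @export
fine_tune <- function(trace) {
  st <- trace$state
  nm <- names(st$specs)
  best <- best_tied_rows(st)
  grids <- list()
  for (h in nm) {
    sp <- st$specs[[h]]
    if (!is.null(sp$values)) {
      grids[[h]] <- st$best_coords[[h]]
      next
    }
    tied <- sort(unique(best[[h]]))
    if (length(tied) > 1) {
      rng <- range(tied)
    } else {
      b <- tied
      ok <- st$trace[st$trace$status == "ok" & abs(st$trace[[h]] - b) > 1e-12, , drop = FALSE]
      if (nrow(ok) == 0) { grids[[h]] <- b; next }
      sb <- ok[[h]][which.max(ok$score)]
      rng <- if (sb > b) c(b - sp$stride / 2, sb) else c(sb, b + sp$stride / 2)
    }
    rng[1] <- max(rng[1], st$eff_lo[[h]])
    rng[2] <- min(rng[2], st$eff_hi[[h]])
    g <- seq(rng[1], rng[2], length.out = sp$n_fine)
    grids[[h]] <- unique(g)
  }
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  for (i in seq_len(nrow(combos))) {
    tuner_eval(st, unlist(combos[i, , drop = FALSE]), "fine")
  }
  best_values <- mapply(function(s, cc) spec_value(s, cc),
                        st$specs, st$best_coords, SIMPLIFY = FALSE)
  list(best_values = best_values, best_coords = st$best_coords,
       best_score = st$best_score,
       trace = structure(list(trace = st$trace, best_coords = st$best_coords,
                              best_score = st$best_score,
                              eff_lo = st$eff_lo, eff_hi = st$eff_hi,
                              specs = st$specs,
                              score_round = trace$score_round, state = st),
                         class = "tuner_trace"))
}

#' Run the complete three-stage hyperparameter search
#'
#' Coarse grid, pseudo-gradient boundary extension, then fine tuning.
#'
#' @inheritParams pseudo_gradient_descent
#' @return as [fine_tune()].
#' @export
tune_hypers <- function(specs, evaluator, guard = NULL, score_round = 6,
                        max_iter = 50) {
  if (length(specs) == 0) {
    return(list(best_values = list(), best_coords = NULL, best_score = NA_real_,
                trace = NULL))
  }
  tr <- pseudo_gradient_descent(specs, evaluator, guard = guard,
                                score_round = score_round, max_iter = max_iter)
  fine_tune(tr)
}
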
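test_that("coarse grid builds transformed arithmetic sequences and products", {
  g1 <- coarse_grid(list(hyper_spec("h", 0, 4, 2)))
  expect_equal(g1$h, c(0, 2, 4))
  g2 <- coarse_grid(list(hyper_spec("h", 0, 3, 1, transform = "pow2")))
  expect_equal(g2$h, c(1, 2, 4, 8))
  g3 <- coarse_grid(list(hyper_spec("a", 0, 2, 1), hyper_spec("b", 0, 3, 1)))
  expect_equal(nrow(g3), 12)
})

test_that("pseudo-gradient extends through a boundary optimum and stops at it", {
  f <- function(v) -(v$h - 7)^2
  tr <- pseudo_gradient_descent(list(hyper_spec("h", 0, 4, 1, hard_lo = -20,
                                                hard_hi = 20)), f)
  explored <- sort(tr$trace$h)
  expect_true(all(5:8 %in% explored))   # walked 5, 6, 7 and past to 8
  expect_equal(tr$best_coords[["h"]], 7)
  # interior optimum: no extension beyond the initial grid
  f2 <- function(v) -(v$h - 2)^2
  tr2 <- pseudo_gradient_descent(list(hyper_spec("h", 0, 4, 1)), f2)
  expect_equal(sort(unique(tr2$trace$h)), 0:4)
  expect_equal(tr2$best_coords[["h"]], 2)
})

test_that("evaluation failures shrink the explorable limit", {
  f <- function(v) { if (v$h >= 6) stop("oom"); -(v$h - 7)^2 }
  tr <- pseudo_gradient_descent(list(hyper_spec("h", 0, 4, 1, hard_lo = -20,
                                                hard_hi = 20)), f)
  expect_equal(tr$best_coords[["h"]], 5)
  expect_equal(unname(tr$eff_hi["h"]), 5)
  expect_true(any(tr$trace$status == "failed"))
  # everything failing raises an error carrying the trace
  err <- tryCatch(pseudo_gradient_descent(list(hyper_spec("h", 0, 2, 1)),
                                          function(v) stop("no")),
                  error = function(e) e)
  expect_s3_class(err, "tuner_all_failed")
  expect_true(nrow(err$trace) > 0)
})

test_that("fine tuning spans ties, or best-to-second-best plus half a stride", {
  # plateau: h in {2, 4} tie for best -> fine grid spans [2, 4]
  f <- function(v) -abs(min(max(v$h, 2), 4) - v$h)
  tr <- pseudo_gradient_descent(list(hyper_spec("h", 0, 6, 2, n_fine = 5)), f)
  ft <- fine_tune(tr)
  fine <- ft$trace$trace[ft$trace$trace$stage == "fine", "h"]
  expect_gte(min(fine), 2)
  expect_lte(max(fine), 4)

  # unique best 7, second best 8, stride 1 -> fine grid spans (6.5, 8)
  f2 <- function(v) -(v$h - 7.2)^2
  tr2 <- pseudo_gradient_descent(list(hyper_spec("h", 0, 4, 1, hard_lo = -20,
                                                 hard_hi = 20, n_fine = 5)), f2)
  expect_equal(tr2$best_coords[["h"]], 7)
  ft2 <- fine_tune(tr2)
  fine2 <- ft2$trace$trace[ft2$trace$trace$stage == "fine", "h"]
  expect_gte(min(fine2), 6.5)
  expect_lte(max(fine2), 8)
  expect_equal(ft2$best_coords[["h"]], 7.25, tolerance = 0.2)
})

test_that("trace is complete and the reported best is reproducible from it", {
  f <- function(v) -(v$h - 3)^2 - (v$g - 1)^2
  res <- tune_hypers(list(hyper_spec("h", 0, 4, 1, hard_lo = -10, hard_hi = 10),
                          hyper_spec("g", 0, 2, 1, hard_lo = -10, hard_hi = 10)), f)
  tr <- res$trace$trace
  keys <- paste(tr$h, tr$g)
  expect_false(any(duplicated(keys)))      # every combination exactly once
  ok <- tr[tr$status == "ok", ]
  expect_equal(max(ok$score), res$best_score)
  best_row <- ok[which.max(ok$score), ]
  expect_equal(unname(unlist(best_row[c("h", "g")])),
               unname(unlist(res$best_coords)))
})

test_that("the prediction guard protects the incumbent", {
  expect_equal(guard_predictions(c(1, 2, NaN)), "reject")
  expect_equal(guard_predictions(c(1.5, 2.5)), "accept")
  expect_equal(guard_predictions(factor(c("a", NA))), "reject")
  expect_equal(guard_predictions(numeric(0)), "reject")

  # a better-scoring combination with NaN training predictions never becomes best
  f <- function(v) -(v$h - 4)^2
  g <- function(v) if (v$h == 4) NaN else 1
  res <- tune_hypers(list(hyper_spec("h", 0, 6, 1)), f, guard = g)
  expect_false(res$best_coords[["h"]] == 4)
  tr <- res$trace$trace
  expect_true(any(tr$status == "guard_rejected"))
})

test_that("tuner attains the exhaustive optimum within one fine-grid step (1-D and 2-D)", {
  set.seed(99)
  for (rep in 1:30) {
    ctr <- runif(1, -12, 12)
    f <- function(v) -(v$h - ctr)^2
    sp <- hyper_spec("h", 0, 4, 1, hard_lo = -15, hard_hi = 15, n_fine = 5)
    res <- tune_hypers(list(sp), f)
    fine_step <- sp$stride / (sp$n_fine - 1)
    exhaustive <- seq(-15, 15, by = fine_step)
    best_ex <- exhaustive[which.min((exhaustive - ctr)^2)]
    tol <- max(abs((exhaustive + fine_step - ctr)^2 - (exhaustive - ctr)^2))
    expect_lte((res$best_coords[["h"]] - ctr)^2, (best_ex - ctr)^2 + tol)
  }
  for (rep in 1:20) {
    cx <- runif(1, -8, 8); cy <- runif(1, -8, 8)
    f <- function(v) -(v$h - cx)^2 - 2 * (v$g - cy)^2
    sps <- list(hyper_spec("h", 0, 4, 1, hard_lo = -10, hard_hi = 10, n_fine = 4),
                hyper_spec("g", 0, 4, 1, hard_lo = -10, hard_hi = 10, n_fine = 4))
    res <- tune_hypers(sps, f)
    loss <- function(h, g) (h - cx)^2 + 2 * (g - cy)^2
    fs <- 1 / 3
    ex <- expand.grid(h = seq(-10, 10, fs), g = seq(-10, 10, fs))
    best_ex <- min(loss(ex$h, ex$g))
    tol <- 2 * (2 * fs * (abs(cx) + abs(cy) + 20) + 3 * fs^2)
    expect_lte(loss(res$best_coords[["h"]], res$best_coords[["g"]]),
               best_ex + tol)
  }
})
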
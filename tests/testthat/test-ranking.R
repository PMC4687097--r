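test_that("column scaling and quantile normalization match hand-derived cases", {
  expect_equal(as.vector(minmax_scale(matrix(c(2, 4, 6), 3, 1))),
               c(0, 0.5, 1))
  q <- quantile_normalize(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(q, matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))
})

test_that("quantile normalization is idempotent and matches limma", {
  skip_if_not_installed("limma")
  set.seed(10)
  m <- matrix(stats::rlnorm(9 * 5), 9, 5)
  q1 <- quantile_normalize(m)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  expect_equal(q1, unname(limma::normalizeQuantiles(m)), tolerance = 1e-10)
})

test_that("scaled columns span [0, 1] with both extremes attained", {
  set.seed(11)
  m <- matrix(stats::rgamma(9 * 6, 2, 0.1), 9, 6)
  s <- minmax_scale(m)
  expect_equal(unname(apply(s, 2, min)), rep(0, 6))
  expect_equal(unname(apply(s, 2, max)), rep(1, 6))
})

test_that("complete matrices normalize in one pass; imputation converges", {
  set.seed(12)
  m <- matrix(stats::rgamma(9 * 6, 2, 0.1), 9, 6,
              dimnames = list(paste0("E", 1:9), paste0("S", 1:6)))
  full <- normalize_enzyme_matrix(m)
  expect_equal(full$iterations, 1L)
  expect_equal(nrow(full$imputed), 0L)
  mm <- m; mm[sample(length(m), 12)] <- NA
  r <- normalize_enzyme_matrix(mm, tol = 0.001)
  expect_true(all(r$matrix >= 0 & r$matrix <= 1))
  expect_equal(nrow(r$imputed), 12L)
})

test_that("imputed normalized values stay close to the unmasked run", {
  set.seed(13)
  # strong row structure so row means are informative
  base <- stats::rgamma(9, 3, 0.05)
  m <- outer(base, stats::runif(6, 0.8, 1.2)) * matrix(stats::rlnorm(54, 0, 0.1), 9)
  dimnames(m) <- list(paste0("E", 1:9), paste0("S", 1:6))
  full <- normalize_enzyme_matrix(m)$matrix
  mm <- m; idx <- sample(length(m), 14); mm[idx] <- NA   # ~26% masked
  masked <- normalize_enzyme_matrix(mm)$matrix
  expect_lt(mean(abs(masked[idx] - full[idx])), 0.15)
})

test_that("summaries sum-normalize to one and absorb column scaling", {
  set.seed(14)
  m <- matrix(stats::rgamma(9 * 6, 2, 0.1), 9, 6,
              dimnames = list(paste0("E", 1:9), NULL))
  n1 <- normalize_enzyme_matrix(m)$matrix
  st <- summarize_enzyme_stats(n1, n1)
  expect_equal(sum(st$activity_avg), 1, tolerance = 1e-12)
  expect_equal(sum(st$abundance_avg), 1, tolerance = 1e-12)
  m2 <- m; m2[, 4] <- m2[, 4] * 11.7
  st2 <- summarize_enzyme_stats(normalize_enzyme_matrix(m2)$matrix, n1)
  expect_equal(st2$activity_avg, st$activity_avg, tolerance = 1e-12)
})

test_that("rows without observations are dropped with a warning", {
  m <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), NULL))
  m[2, ] <- NA
  expect_warning(r <- normalize_enzyme_matrix(m), "B")
  expect_equal(rownames(r$matrix), c("A", "C"))
})

test_that("packaged CYP averages match the published normalization", {
  st <- load_enzyme_stats()
  expect_equal(st$enzyme, c("1A2", "2A6", "2B6", "2C8", "2C9", "2C19",
                            "2D6", "2E1", "3A4"))
  r <- st[st$enzyme == "1A2", ]
  expect_equal(r$activity_avg, 0.0414)
  expect_equal(r$abundance_avg, 0.0895)
  expect_lt(abs(sum(st$activity_avg) - 1), 5e-4)
  expect_lt(abs(sum(st$abundance_avg) - 1), 5e-4)
})

test_that("scores sum activity x abundance over enzymes with data", {
  st <- load_enzyme_stats()
  s <- score_enzymes(c("1A1", "1A2", "1B1", "3A4"), st)
  expect_equal(s$score_reported, 0.0395)
  expect_equal(sort(s$missing), c("1A1", "1B1"))
  expect_equal(score_enzymes("2E1", st)$score_reported, 0.0317)
  expect_equal(score_enzymes(character(0), st)$score, 0)
  expect_equal(score_enzymes(c("1A1", "1B1"), st)$score, 0)
})

test_that("ranks are ordinal, descending, and stable within ties", {
  st <- load_enzyme_stats()
  rk <- rank_predictions(data.frame(id = c("a", "b", "c"),
                                    enzymes = c("2E1", "3A4", "2E1")), st)
  expect_equal(rk$rank, 1:3)
  # 2E1-only entries tie; input order a before c is preserved
  expect_equal(rk$id[rk$score == 0.0317], c("a", "c"))
  single <- rank_predictions(data.frame(id = "x", enzymes = "3A4"), st)
  expect_equal(single$rank, 1L)
})
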
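test_that("precision score matches closed forms", {
  # constant offset of 1 N above the target line
  tr <- force_trace(rep(6 + 1, 1200), rate = 100, target = 0.1, mvc = 60)
  s <- compute_precision_score(tr)
  expect_equal(s$rmse, 1)
  expect_equal(s$score, 0)
  # constant offset e
  s2 <- compute_precision_score(rep(6 + exp(1), 1200), target_level = 6)
  expect_equal(s2$score, -1)
  # sinusoid of amplitude A around the target: rms = A / sqrt(2)
  A <- 0.7
  t <- seq(0, 120, by = 0.01)[-1]
  s3 <- compute_precision_score(6 + A * sin(2 * pi * 2 * t), target_level = 6)
  expect_equal(s3$rmse, A / sqrt(2), tolerance = 1e-3)
})

test_that("degenerate traces are rejected", {
  expect_error(compute_precision_score(numeric(0), target_level = 6),
               "empty")
  expect_error(compute_precision_score(rep(6, 10), target_level = 6),
               "degenerate")
  expect_error(force_trace(1:10, rate = 100, target = 1.5), "target")
})

test_that("score is strictly decreasing in rmse", {
  rmses <- c(0.2, 0.5, 1, 2, 5)
  scores <- vapply(rmses, function(r)
    compute_precision_score(c(6 + r, 6 - r), target_level = 6)$score,
    numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("one-way ANOVA and Holm-adjusted pairwise tests match a direct
          sum-of-squares oracle", {
  scores <- c(2, 3, 4, 5, 6, 7)
  groups <- rep(c("a", "b", "c"), each = 2)
  st <- group_statistics(scores, groups)
  # oracle: classic between/within sums of squares
  gm <- mean(scores)
  means <- tapply(scores, groups, mean)
  ssb <- sum(2 * (means - gm)^2)
  ssw <- sum((scores - means[groups])^2)
  F_oracle <- (ssb / 2) / (ssw / 3)
  expect_equal(unname(st$F), F_oracle)
  expect_equal(unname(st$df), c(2, 3))
  # pairwise pooled t-tests oracle
  t_oracle <- function(a, b) {
    sp <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  }
  praw <- c(
    2 * pt(-abs(t_oracle(c(2, 3), c(4, 5))), 2),
    2 * pt(-abs(t_oracle(c(2, 3), c(6, 7))), 2),
    2 * pt(-abs(t_oracle(c(4, 5), c(6, 7))), 2)
  )
  expect_equal(st$pairwise$p, praw, tolerance = 1e-12)
  expect_equal(st$pairwise$p_holm, p.adjust(praw, "holm"))
})

test_that("equal group means give F = 0 and label permutation leaves F
          invariant", {
  scores <- rep(c(1, 2, 3), 4)
  groups <- rep(c("g1", "g2", "g3", "g4"), each = 3)
  st <- group_statistics(scores, groups)
  expect_equal(unname(st$F), 0)

  set.seed(1)
  sc <- rnorm(24)
  gr <- rep(letters[1:4], each = 6)
  F1 <- group_statistics(sc, gr)$F
  relabel <- c(a = "c", b = "d", c = "a", d = "b")
  F2 <- group_statistics(sc, unname(relabel[gr]))$F
  expect_equal(F1, F2)
})

test_that("Holm-adjusted p-values are monotone in rank and dominate raw ones", {
  set.seed(7)
  for (rep in 1:5) {
    sc <- rnorm(20, mean = rep(runif(4, 0, 2), each = 5))
    st <- group_statistics(sc, rep(paste0("g", 1:4), each = 5))
    pw <- st$pairwise[order(st$pairwise$p), ]
    expect_true(all(pw$p_holm >= pw$p))
    expect_true(all(diff(pw$p_holm) >= -1e-15))
  }
})

test_that("groups with fewer than two members are rejected", {
  expect_error(group_statistics(1:4, c("a", "a", "b", "c")), "at least two")
})

test_that("force CSV round-trips through scoring", {
  path <- tempfile(fileext = ".csv")
  t <- seq(0, 10, by = 0.01)[-1]
  write.csv(data.frame(time = t, force = 6 + sin(t)), path, row.names = FALSE)
  tr <- read_force_csv(path, target = 0.1, mvc = 60)
  expect_equal(tr$rate, 100, tolerance = 1e-6)
  expect_equal(compute_precision_score(tr)$rmse, sqrt(mean(sin(t)^2)))
  unlink(path)
})
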
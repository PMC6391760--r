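test_that("coefficients equal the closed form on a toy set", {
  x <- matrix(c(1, 2, 3, 5, 6, 7,
                1.2, 1.9, 3.1, 4.8, 6.2, 7.1), ncol = 2)
  g <- rep(c("a", "b"), each = 3)
  fit <- dfa(x, g)
  # oracle: explicit pooled covariance and direct matrix inversion
  xa <- x[1:3, ]; xb <- x[4:6, ]
  S <- (cov(xa) * 2 + cov(xb) * 2) / 4
  w_oracle <- solve(S) %*% (colMeans(xa) - colMeans(xb))
  expect_equal(unname(coef(fit)), drop(w_oracle), tolerance = 1e-10)
})

test_that("the discriminant aligns with the separating axis", {
  d <- two_group_data(n1 = 60, n2 = 60, p = 2, shift = 4, seed = 2)
  fit <- dfa(d[c("f1", "f2")], d$group)
  expect_gt(abs(coef(fit)[1]), 5 * abs(coef(fit)[2]))
})

test_that("swapping group labels flips the discriminant sign only", {
  d <- two_group_data(seed = 3)
  f1 <- dfa(d[1:3], factor(d$group, levels = c("a", "b")))
  f2 <- dfa(d[1:3], factor(d$group, levels = c("b", "a")))
  expect_equal(coef(f1), -coef(f2))
  p1 <- predict(f1, d[1:3])$class
  p2 <- predict(f2, d[1:3])$class
  expect_identical(as.character(p1), as.character(p2))
})

test_that("predictions agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  d <- two_group_data(n1 = 50, n2 = 30, p = 3, shift = 1.5, seed = 4)
  fit <- dfa(d[1:3], d$group)
  ref <- MASS::lda(d[1:3], grouping = d$group, prior = c(0.5, 0.5))
  expect_identical(as.character(predict(fit, d[1:3])$class),
                   as.character(predict(ref, d[1:3])$class))
})

test_that("classification summaries behave on separable data", {
  d <- two_group_data(shift = 20, seed = 5)
  fit <- dfa(d[1:3], d$group)
  res <- classify(fit, d)
  expect_equal(res$percent_correct, 100)
  expect_equal(unname(rowSums(res$confusion)), as.numeric(table(d$group)))
  expect_true(all(res$wilks_partial > 0 & res$wilks_partial <= 1))
  # the informative feature carries the separation
  expect_lt(res$wilks_partial[["f1"]], min(res$wilks_partial[c("f2", "f3")]))
})

test_that("attribution is invariant to affine feature rescaling", {
  d <- two_group_data(shift = 2, seed = 6)
  base <- classify(dfa(d[1:3], d$group), d)
  d2 <- d
  d2$f1 <- d2$f1 * 1000 + 5  # seconds to milliseconds plus an offset
  scaled <- classify(dfa(d2[1:3], d2$group), d2)
  expect_equal(base$percent_correct, scaled$percent_correct)
  expect_equal(base$confusion, scaled$confusion)
})

test_that("degenerate inputs are caught", {
  d <- two_group_data(seed = 7)
  expect_error(dfa(d[1:3], rep("a", nrow(d))), "two groups")
  expect_error(predict(dfa(d[1:3], d$group), d[1:2]), "feature")
  dup <- d
  dup$f2 <- dup$f1  # perfectly collinear features
  expect_warning(dfa(dup[1:3], dup$group), "ridge")
})
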
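test_that("overall and relative value follow their definitions", {
  expect_equal(overall_value(c(8, 4, 4, 4)), 5)
  expect_equal(overall_value(c(0, 0, 0, 0)), 0)
  expect_equal(overall_value(c(10, 10, 10, 10)), 10)
  expect_equal(relative_value(c(8, 4, 4, 4), "selection"), 4)
  expect_equal(relative_value(c(2, 6, 6, 6), "removal"), 4)
  expect_equal(relative_value(c(5, 5, 5, 5), "selection"), 0)
  expect_equal(relative_value(c(5, 5, 5, 5), "removal"), 0)
  expect_error(overall_value(c(1, 2, 3)), "exactly 4")
  expect_error(overall_value(c(1, 2, 3, 11)), "\\[0, 10\\]")
})

test_that("relative value ignores permutation of the non-extreme options", {
  set.seed(1)
  ok <- vapply(1:50, function(i) {
    v <- sort(runif(4, 0, 10), decreasing = TRUE)
    perm <- c(1, sample(2:4))
    w <- sort(v) # worst first
    permw <- c(1, sample(2:4))
    isTRUE(all.equal(relative_value(v[perm], "selection"),
                     relative_value(v, "selection"))) &&
      isTRUE(all.equal(relative_value(w[permw], "removal"),
                       relative_value(w, "removal")))
  }, logical(1))
  expect_true(all(ok))
})

test_that("reward rate is chosen value per second and scales with value", {
  expect_equal(reward_rate(6, 2), 3)
  expect_equal(reward_rate(0, 1.5), 0)
  expect_equal(reward_rate(7, 2), 3.5)
  expect_error(reward_rate(5, 0), "positive")
  expect_error(reward_rate(5, -1), "positive")
  set.seed(2)
  v <- runif(20, 0, 5); rt <- runif(20, 0.5, 5); s <- 1.7
  expect_equal(reward_rate(s * v, rt), s * reward_rate(v, rt))
})

test_that("accuracy tracks the framing-relevant extreme, ties accurate", {
  expect_true(is_accurate(1, c(8, 4, 4, 4), "selection"))
  expect_false(is_accurate(2, c(8, 4, 4, 4), "selection"))
  expect_true(is_accurate(1, c(5, 5, 2, 1), "selection"))
  expect_true(is_accurate(2, c(5, 5, 2, 1), "selection"))
  expect_false(is_accurate(3, c(5, 5, 2, 1), "selection"))
  expect_true(is_accurate(4, c(5, 5, 2, 1), "removal"))
  expect_false(is_accurate(1, c(5, 5, 2, 1), "removal"))
  expect_error(is_accurate(5, c(1, 2, 3, 4)), "1..4")
})

test_that("successive-differences contrast recovers grand mean and gap", {
  cc <- condition_contrast(c("inclusive", "exclusive"))
  expect_equal(unname(cc[c("exclusive", "inclusive")]), c(-0.5, 0.5))
  expect_error(condition_contrast(c("a", "b", "c")), "2 levels")

  # balanced two-group mean model: intercept = unweighted grand mean,
  # slope = between-group difference (closed-form least squares)
  g <- rep(c("exclusive", "inclusive"), each = 30)
  x <- unname(cc[g])
  y <- ifelse(g == "exclusive", 2, 4)
  fit <- lm(y ~ x)
  expect_equal(unname(coef(fit)[1]), 3, tolerance = 1e-10)
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 1e-10)
  y2 <- rep(5, 60)
  expect_equal(unname(coef(lm(y2 ~ x))[2]), 0, tolerance = 1e-10)

  # with noise and balance the intercept still equals the unweighted mean
  # of the two condition means
  set.seed(3)
  y3 <- ifelse(g == "exclusive", 2, 4) + rnorm(60)
  m_e <- mean(y3[g == "exclusive"]); m_i <- mean(y3[g == "inclusive"])
  expect_equal(unname(coef(lm(y3 ~ x))[1]), (m_e + m_i) / 2,
               tolerance = 1e-10)
})

test_that("orthogonal polynomials match a Gram-Schmidt construction", {
  x <- 1:10
  p <- orthogonal_poly(x)
  expect_lt(abs(sum(p$lin * p$quad)), 1e-10)
  expect_lt(abs(sum(p$lin)), 1e-10)
  expect_lt(abs(sum(p$quad)), 1e-10)
  expect_equal(sum(p$lin^2), 1)
  expect_equal(sum(p$quad^2), 1)

  # independent Gram-Schmidt of (x, x^2) against the constant column
  l <- x - mean(x)
  l <- l / sqrt(sum(l^2))
  q <- x^2 - mean(x^2) - sum((x^2) * l) * l
  q <- q / sqrt(sum(q^2))
  expect_equal(abs(sum(p$lin * l)), 1, tolerance = 1e-10)
  expect_equal(abs(sum(p$quad * q)), 1, tolerance = 1e-10)

  # symmetric x: quadratic column symmetric, linear antisymmetric
  xs <- c(-3, -1, 0, 1, 3)
  ps <- orthogonal_poly(xs)
  expect_equal(ps$lin, -rev(ps$lin))
  expect_equal(ps$quad, rev(ps$quad))

  expect_error(orthogonal_poly(rep(2, 10)), "distinct")
})

test_that("add_value_summaries computes per-row OV and RV by framing", {
  tr <- tibble::tibble(v1 = c(8, 2), v2 = c(4, 6), v3 = c(4, 6),
                       v4 = c(4, 6), framing = c("selection", "removal"))
  out <- add_value_summaries(tr)
  expect_equal(out$ov, c(5, 5))
  expect_equal(out$rv, c(4, 4))
  expect_error(add_value_summaries(tr[, 1:3]), "v4")
})
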
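test_that("parameter construction enforces ranges and resolution", {
  expect_s3_class(lca_params(), "lca_params")
  expect_error(lca_params(k = -1), "k must be")
  expect_error(lca_params(g = 0), "g must be")
  expect_error(lca_params(a = -2), "a must be")
  expect_error(lca_params(dt = 0.5, t_max = 10), "100 integration steps")
})

test_that("boundary level collapses exponentially from a", {
  expect_equal(boundary_level(c(0, 1, 7), a = 2, beta = 0), rep(2, 3))
  expect_equal(boundary_level(0, a = 2, beta = 3), 2)
  expect_equal(boundary_level(log(2), a = 1, beta = 1), 0.5)
  t <- seq(0, 5, by = 0.1)
  b <- boundary_level(t, a = 2, beta = 0.3)
  expect_true(all(diff(b) < 0) && all(b > 0))
  bl <- boundary_level(t, a = 2, beta = 1, collapse = "linear")
  expect_true(all(diff(bl) <= 0) && all(bl > 0))
})

test_that("noise-free race with a unique best input always picks it", {
  p <- fast_params(c = 0, m = 0, beta = 0.3)
  sets <- tibble::tibble(v1 = 10, v2 = 1, v3 = 1, v4 = 1,
                         framing = "selection")
  b <- simulate_batch(p, sets, n_iter = 20)
  expect_true(all(b$choice == 1))
  expect_true(all(b$accuracy))
  expect_true(all(!b$omitted))
})

test_that("noise-free RT matches the closed-form crossing and a fine-dt run", {
  p <- lca_params(k = 0.5, m = 0, g = 2, c = 0, a = 2, beta = 0.1,
                  dt = 0.001)
  vals <- c(10, 4, 3, 2)
  tr <- simulate_trial(p, vals)
  f <- function(t) p$g * vals[1] * (1 - exp(-p$k * t)) / p$k -
    p$a * exp(-p$beta * t)
  t_star <- uniroot(f, c(1e-6, p$t_max))$root
  expect_lt(abs(tr$rt - t_star), p$dt)
  fine <- simulate_trial(lca_params(k = 0.5, m = 0, g = 2, c = 0, a = 2,
                                    beta = 0.1, dt = 0.0001), vals)
  expect_lt(abs(tr$rt - fine$rt), p$dt)
  expect_equal(tr$choice, 1L)
})

test_that("batches have the promised shape and are seed-deterministic", {
  p <- fast_params()
  sets <- task_sets(10, seed = 4)
  b1 <- simulate_batch(p, sets, n_iter = 25, seed = 99)
  expect_equal(nrow(b1), 250)
  expect_equal(tabulate(b1$set_id, 10), rep(25L, 10))
  b2 <- simulate_batch(p, sets, n_iter = 25, seed = 99)
  expect_identical(b1$rt, b2$rt)
  expect_identical(b1$choice, b2$choice)
  b3 <- simulate_batch(p, sets, n_iter = 25, seed = 100)
  expect_false(identical(b1$rt, b3$rt))
  expect_equal(nrow(simulate_batch(p, sets[0, ], n_iter = 5)), 0)
  expect_error(simulate_batch(p, sets[, c("v1", "v2")], n_iter = 2), "v3")
})

test_that("permuting option values permutes choice shares", {
  p <- fast_params()
  s1 <- tibble::tibble(v1 = 7, v2 = 5, v3 = 4, v4 = 3)
  s2 <- tibble::tibble(v1 = 3, v2 = 4, v3 = 5, v4 = 7) # reversed
  b1 <- simulate_batch(p, s1, n_iter = 1500, seed = 5)
  b2 <- simulate_batch(p, s2, n_iter = 1500, seed = 6)
  p1 <- tabulate(b1$choice, 4) / sum(!b1$omitted)
  p2 <- tabulate(b2$choice, 4) / sum(!b2$omitted)
  expect_lt(max(abs(p1 - rev(p2))), 0.05)
})

test_that("raising a fixed boundary does not speed responses", {
  sets <- task_sets(15, seed = 7)
  rts <- sapply(c(1, 1.5, 2), function(a) {
    p <- fast_params(a = a, beta = 0, g = 0.4)
    mean(simulate_batch(p, sets, n_iter = 80, seed = 8)$rt, na.rm = TRUE)
  })
  expect_true(all(diff(rts) >= 0))
})

test_that("lowering mutual inhibition does not slow responses", {
  sets <- task_sets(15, seed = 17)
  p_hi <- fast_params()
  p_lo <- fast_params(m = 0.3)
  rt_hi <- simulate_batch(p_hi, sets, n_iter = 150, seed = 18)$rt
  rt_lo <- simulate_batch(p_lo, sets, n_iter = 150, seed = 18)$rt
  tt <- t.test(rt_lo, rt_hi, alternative = "less")
  expect_lt(tt$p.value, 0.01)
})

test_that("with no inhibition an accumulator ignores its rivals (race)", {
  p <- lca_params(m = 0, dt = 0.001)
  n_steps <- ceiling(p$t_max / p$dt)
  set.seed(9)
  noise <- matrix(rnorm(n_steps * 4), n_steps, 4)
  t1 <- simulate_trial(p, c(7, 2, 2, 2), noise = noise,
                       keep_trajectory = TRUE)
  t2 <- simulate_trial(p, c(7, 9, 5, 1), noise = noise,
                       keep_trajectory = TRUE)
  n <- min(nrow(t1$trajectory), nrow(t2$trajectory))
  expect_identical(t1$trajectory[1:n, 1], t2$trajectory[1:n, 1])
})

test_that("simultaneous deterministic ties are broken uniformly at random", {
  p <- fast_params(c = 0, m = 0, beta = 0.3)
  sets <- tibble::tibble(v1 = 5, v2 = 5, v3 = 5, v4 = 5)
  b <- simulate_batch(p, sets, n_iter = 200, seed = 10)
  expect_true(all(!b$omitted))
  expect_setequal(unique(b$choice), 1:4)
})

test_that("trials with no crossing before the horizon are omissions", {
  p <- fast_params(g = 0.01, c = 0, t_max = 2, dt = 0.01)
  b <- simulate_batch(p, tibble::tibble(v1 = 1, v2 = 1, v3 = 1, v4 = 1),
                      n_iter = 5)
  expect_true(all(b$omitted))
  expect_true(all(is.na(b$rt)))
  expect_true(all(is.na(b$choice)))
})
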
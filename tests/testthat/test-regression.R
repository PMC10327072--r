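test_that("RT model recovers planted fixed effects", {
  set.seed(20)
  d <- lmm_rt_data(n_part = 16, n_per_cond = 40)
  ct <- fit_rt_model(d, random_slopes = c("cond", "ov"))
  expect_s3_class(ct, "coef_table")
  expect_true(ci_covers(ct, "ov", -0.3))
  expect_true(ci_covers(ct, "rv", -0.19))
  expect_true(ci_covers(ct, "cond", -0.3))
  expect_true(ci_covers(ct, "cond:rv", 0)) # null interaction recovered
  expect_true(all(ct$conf.low <= ct$estimate & ct$estimate <= ct$conf.high,
                  na.rm = TRUE))
  g <- glance(ct)
  expect_equal(g$n_groups, 16)
  expect_true(g$random_structure %in% c("full", "uncorrelated", "intercept"))
})

test_that("swapping condition labels flips condition terms only", {
  set.seed(21)
  d <- lmm_rt_data(n_part = 10, n_per_cond = 25)
  ct1 <- fit_rt_model(d, ladder = FALSE)
  d2 <- d
  d2$condition <- ifelse(d$condition == "exclusive", "inclusive",
                         "exclusive")
  ct2 <- fit_rt_model(d2, ladder = FALSE)
  for (tm in c("cond", "cond:ov", "cond:rv")) {
    expect_equal(ct1$estimate[ct1$term == tm],
                 -ct2$estimate[ct2$term == tm], tolerance = 1e-8)
  }
  for (tm in c("(Intercept)", "ov", "rv", "trial_z")) {
    expect_equal(ct1$estimate[ct1$term == tm],
                 ct2$estimate[ct2$term == tm], tolerance = 1e-8)
  }
})

test_that("log transform symmetrises lognormal RT residuals", {
  set.seed(22)
  d <- lmm_rt_data(n_part = 10, n_per_cond = 30, log_normal = TRUE)
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  res_raw <- residuals(stats::lm(rt ~ cond * ov + cond * rv + trial_z,
                                 data = with_contrast(d)))
  res_log <- residuals(stats::lm(log(rt) ~ cond * ov + cond * rv + trial_z,
                                 data = with_contrast(d)))
  expect_lt(abs(skew(res_log)), abs(skew(res_raw)))
  ct <- fit_rt_model(d, log_transform = TRUE, ladder = FALSE)
  expect_s3_class(ct, "coef_table")
})

test_that("accuracy model recovers log-odds and handles degeneracy", {
  set.seed(23)
  d <- glmm_acc_data(n_part = 16, n_per_cond = 40)
  ct <- fit_accuracy_model(d, random_slopes = character(0))
  expect_true(ci_covers(ct, "rv", 0.68))
  expect_true(ci_covers(ct, "ov", 0.05))

  d_all <- d
  d_all$accuracy <- TRUE
  ct_deg <- fit_accuracy_model(d_all)
  expect_match(glance(ct_deg)$notes, "degenerate")

  # equal-value sets: RV constant, term reported inestimable
  d_flat <- d
  d_flat$rv <- 0
  ct_flat <- fit_accuracy_model(d_flat, random_slopes = character(0))
  expect_true(is.na(ct_flat$estimate[ct_flat$term == "rv"]))
  expect_match(glance(ct_flat)$notes, "inestimable")
})

test_that("conflict model recovers the planted quadratic and interactions", {
  set.seed(24)
  cd <- conflict_data(n_part = 16, n_per_cond = 40)
  ct <- fit_conflict_model(cd$trials, random_slopes = c("ov_lin", "rv"))
  expect_gt(ct$conf.low[ct$term == "ov_quad"], 0)
  expect_true(ci_covers(ct, "ov_quad", unname(cd$implied["ov_quad"])))
  expect_true(ci_covers(ct, "rv", unname(cd$implied["rv"])))
  # flat generator: all value terms cover zero
  set.seed(25)
  cf <- conflict_data(n_part = 10, n_per_cond = 30,
                      b = c(b0 = 3, b1 = 0, b2 = 0, b3 = 0, b4 = 0,
                            b5 = 0))
  ct0 <- fit_conflict_model(cf$trials, ladder = FALSE)
  for (tm in c("ov_lin", "ov_quad", "rv", "cond")) {
    expect_true(ci_covers(ct0, tm, 0))
  }
})

test_that("conflict covariates restrict rows to completed trials", {
  set.seed(26)
  cd <- conflict_data(n_part = 8, n_per_cond = 20)
  tr <- cd$trials
  tr$rt <- 2.5 + runif(nrow(tr))
  tr$accuracy <- runif(nrow(tr)) < 0.5
  tr$omitted[1:5] <- TRUE
  ct <- fit_conflict_model(tr, covariates = TRUE, ladder = FALSE)
  expect_true(all(c("rt", "accuracy") %in% ct$term))
  expect_equal(glance(ct)$n_obs, nrow(tr) - 5)
})

test_that("voluntary keep model finds the global-mean indifference point", {
  set.seed(27)
  kd <- keep_data(n_part = 12, n_trials = 50, temperature = 0.8)
  fits <- fit_voluntary_models(kd$trials, kd$ratings)
  expect_named(fits, c("n_actions", "n_kept", "keep_prob", "suboptimal"))
  kp <- fits$keep_prob
  expect_true(ci_covers(kp, "vdiff", 1 / 0.8))
  expect_true(ci_covers(kp, "ov", 0))
  # indifference point: fitted keep probability crosses 0.5 where the
  # product value equals the global mean rating (vdiff = 0)
  b0 <- kp$estimate[kp$term == "(Intercept)"]
  b1 <- kp$estimate[kp$term == "vdiff"]
  b_ov <- kp$estimate[kp$term == "ov"]
  crossing <- -(b0 + b_ov * 5) / b1 # vdiff at p = 0.5, at the mean OV
  expect_lt(abs(crossing), 0.2)
})

test_that("keep-count models detect a planted conflict effect", {
  set.seed(28)
  kd <- keep_data(n_part = 12, n_trials = 40)
  tr <- kd$trials
  # couple the number kept to the conflict rating, then refit (b)
  tr$conflict <- sample(1:5, nrow(tr), replace = TRUE)
  km <- do.call(rbind, lapply(strsplit(tr$kept_mask, ""), as.integer))
  extra <- runif(nrow(tr)) < 0.2 * (tr$conflict - 3)
  flip <- which(extra & rowSums(km) < 4)
  for (i in flip) km[i, which(km[i, ] == 0)[1]] <- 1L
  tr$kept_mask <- apply(km, 1, paste, collapse = "")
  fits <- fit_voluntary_models(tr, kd$ratings, include_conflict = TRUE,
                               random_slopes = character(0))
  nk <- fits$n_kept
  expect_gt(nk$estimate[nk$term == "conflict"], 0)
  expect_lt(nk$p.value[nk$term == "conflict"], 0.05)
})

test_that("degenerate voluntary inputs are flagged, empty input errors", {
  set.seed(29)
  kd <- keep_data(n_part = 6, n_trials = 20)
  tr <- kd$trials
  tr$kept_mask <- "1111"
  fits <- fit_voluntary_models(tr, kd$ratings, random_slopes = character(0))
  expect_match(glance(fits$n_kept)$notes, "degenerate")
  tr_none <- kd$trials
  tr_none$condition <- "exclusive"
  expect_error(fit_voluntary_models(tr_none, kd$ratings), "no inclusive")
})

test_that("condition means use per-trial reward rate and sane intervals", {
  tr <- tibble::tibble(
    participant = rep(c("a", "b"), each = 4),
    trial = rep(1:4, 2),
    condition = rep(c("exclusive", "inclusive"), 4),
    framing = "selection",
    v1 = 8, v2 = 4, v3 = 4, v4 = 2,
    rt = c(2, 4, 2, 4, 1, 2, 1, 2),
    choice = c(1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L),
    accuracy = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    omitted = FALSE)
  sm <- summarize_condition_means(tr, n_boot = 100, seed = 30)
  rr_excl <- sm$mean[sm$condition == "exclusive" & sm$measure == "rrate"]
  # mean of per-trial value/RT, not ratio of means
  expect_equal(rr_excl, mean(c(8 / 2, 8 / 2, 8 / 1, 8 / 1)))
  expect_true(all(sm$conf.low <= sm$mean + 1e-9 &
                    sm$mean <= sm$conf.high + 1e-9))
  one <- summarize_condition_means(tr[tr$trial == 1 &
                                        tr$participant == "a", ],
                                   n_boot = 50, seed = 1)
  expect_equal(one$mean[one$measure == "rt"], 2)
})
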
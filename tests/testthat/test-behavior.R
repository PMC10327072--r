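test_that("design defaults flip the conflict interaction with framing", {
  ds <- design_spec()
  dr <- design_spec(framing = "removal")
  expect_lt(ds$conflict_coefs["b5"], 0)
  expect_gt(dr$conflict_coefs["b5"], 0)
  custom <- design_spec(conflict_coefs = c(b5 = 2))
  expect_equal(unname(custom$conflict_coefs["b5"]), 2)
  expect_error(design_spec(bad_participants = "nope"), "unknown bad")
})

test_that("the keep rule becomes a hard threshold at low temperature", {
  set.seed(13)
  kept <- generate_subsequent_choices(c(9, 8, 2, 1), first_choice = 1,
                                      framing = "selection",
                                      global_mean = 5,
                                      temperature = 1e-6)
  expect_equal(kept, c(TRUE, TRUE, FALSE, FALSE))
  # removal framing forces the first-removed option out
  kept_r <- generate_subsequent_choices(c(9, 8, 2, 1), first_choice = 4,
                                        framing = "removal",
                                        global_mean = 5,
                                        temperature = 1e-6)
  expect_equal(kept_r, c(TRUE, TRUE, FALSE, FALSE))
  # at the indifference point each voluntary option is a coin flip
  hits <- replicate(800, generate_subsequent_choices(
    rep(5, 4), first_choice = 1, framing = "selection", global_mean = 5,
    temperature = 0.5)[2])
  expect_equal(mean(hits), 0.5, tolerance = 0.06)
})

test_that("more valuable sets lead to keeping more options", {
  set.seed(14)
  n <- 1000
  ov <- runif(n, 0, 10)
  n_kept <- vapply(ov, function(o) {
    v <- pmin(pmax(o + rnorm(4, 0, 1.5), 0), 10)
    sum(generate_subsequent_choices(v, first_choice = which.max(v),
                                    framing = "selection", global_mean = 5,
                                    temperature = 0.8))
  }, numeric(1))
  ct <- cor.test(ov, n_kept, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0.3)
  expect_lt(ct$p.value, 1e-6)
})

test_that("conflict model is U-shaped in OV and decreasing in RV", {
  set.seed(15)
  des <- design_spec(n_participants = 1, trials_per_condition = 40,
                     conflict_sd = 0)
  cat <- generate_catalog(200)
  sess <- generate_session(des, cat)
  cf <- choicelca:::generate_conflict(des, sess)
  # interior minimum in OV (quadratic with b2 > 0)
  lo <- mean(cf[sess$ov < 2]); mi <- mean(cf[sess$ov > 4 & sess$ov < 6])
  hi <- mean(cf[sess$ov > 8])
  expect_lt(mi, lo)
  expect_lt(mi, hi)
  # holding OV, higher RV lowers conflict (b3 < 0)
  band <- sess$ov > 3 & sess$ov < 7
  expect_lt(cor(sess$rv[band], cf[band]), 0)
})

test_that("planted non-compliant participants fire their exclusion rules", {
  des <- design_spec(n_participants = 2, trials_per_condition = 15,
                     bad_participants = c("constant_ratings",
                                          "sloppy_chooser",
                                          "flat_conflict"))
  st <- generate_study(des, seed = 16)
  excl <- apply_exclusions(st$trials, st$ratings)
  rep <- excl$report
  get <- function(pat) rep[grepl(pat, rep$participant), ]
  expect_true(get("constant_ratings")$excluded)
  expect_match(get("constant_ratings")$criteria, "sd_value")
  expect_true(get("sloppy_chooser")$excluded)
  expect_match(get("sloppy_chooser")$criteria, "easy_accuracy")
  expect_true(get("flat_conflict")$excluded)
  expect_match(get("flat_conflict")$criteria, "sd_conflict")
  expect_true(all(!rep$excluded[grepl("^s\\d", rep$participant)]))

  # idempotence: filtering a filtered table changes nothing
  again <- apply_exclusions(excl$trials, st$ratings)
  expect_identical(excl$trials, again$trials)
  expect_setequal(excl$kept, again$kept)
})

test_that("urgency omission exclusions fire only on high-urgency designs", {
  des <- design_spec(n_participants = 2, trials_per_condition = 15,
                     conditions = c("low_urgency", "high_urgency"),
                     bad_participants = "high_omitter")
  st <- generate_study(des, params_by_condition = list(
    low_urgency = fast_params(), high_urgency = fast_params(a = 1.8)),
    seed = 17)
  excl <- apply_exclusions(st$trials, st$ratings)
  bad <- excl$report[grepl("high_omitter", excl$report$participant), ]
  expect_true(bad$excluded)
  expect_match(bad$criteria, "urgency_omission")
})

test_that("study tables are reproducible from the top-level seed", {
  des <- design_spec(n_participants = 2, trials_per_condition = 10)
  s1 <- generate_study(des, seed = 18)
  s2 <- generate_study(des, seed = 18)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$ratings, s2$ratings)
  s3 <- generate_study(des, seed = 19)
  expect_false(identical(s1$trials$rt, s3$trials$rt))
})

test_that("exclusion filters demand the schema they need", {
  expect_error(apply_exclusions(tibble::tibble(participant = "a"),
                                tibble::tibble(participant = "a",
                                               rating = 1)),
               "rv")
})
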
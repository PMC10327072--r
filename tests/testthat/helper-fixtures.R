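# Shared fixtures: coarse-dt parameter sets for speed, task-distributed
# choice sets, and direct mixed-model data generators used for
# coefficient-recovery checks (these generate from the fitted model's own
# form, so nominal CI coverage is well defined).

fast_params <- function(..., dt = 0.01) lca_params(..., dt = dt)

withr_like_tempdir <- function() {
  d <- tempfile("choicelca_test_")
  dir.create(d)
  d
}

task_sets <- function(n = 100, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- dplyr::bind_rows(lapply(seq_len(n), function(i) generate_choice_set()))
  s$set_id <- seq_len(n)
  s$framing <- "selection"
  s
}

# design skeleton: per participant, 2 x n_per_cond interleaved trials with
# task-distributed ov/rv
design_skeleton <- function(n_part, n_per_cond) {
  purrr::map_dfr(seq_len(n_part), function(p) {
    n <- 2 * n_per_cond
    sets <- dplyr::bind_rows(lapply(seq_len(n),
                                    function(i) generate_choice_set()))
    rv <- sets$v1 - rowMeans(cbind(sets$v2, sets$v3, sets$v4))
    tibble::tibble(
      participant = sprintf("s%02d", p), trial = seq_len(n),
      condition = sample(rep(c("exclusive", "inclusive"), n_per_cond)),
      framing = "selection", ov = sets$ov_target, rv = rv, omitted = FALSE)
  })
}

with_contrast <- function(d) {
  d$cond <- ifelse(d$condition == "inclusive", 0.5, -0.5)
  d |>
    dplyr::group_by(participant) |>
    dplyr::mutate(trial_z = as.numeric(scale(trial))) |>
    dplyr::ungroup()
}

# linear mixed data for the RT model, planted on the fitted scale
lmm_rt_data <- function(n_part = 20, n_per_cond = 30,
                        beta = c(cond = -0.3, ov = -0.3, rv = -0.19,
                                 cond_ov = -0.14, cond_rv = 0,
                                 trial = 0.02),
                        b0 = 4.5, sd_int = 0.3, sd_cond = 0.1,
                        sd_ov = 0.05, sigma = 0.5, log_normal = FALSE) {
  d <- with_contrast(design_skeleton(n_part, n_per_cond))
  re <- d |>
    dplyr::distinct(participant) |>
    dplyr::mutate(b_i = stats::rnorm(dplyr::n(), 0, sd_int),
                  bc_i = stats::rnorm(dplyr::n(), 0, sd_cond),
                  bov_i = stats::rnorm(dplyr::n(), 0, sd_ov))
  d <- dplyr::left_join(d, re, by = "participant")
  mu <- b0 + (beta["cond"] + d$bc_i) * d$cond +
    (beta["ov"] + d$bov_i) * d$ov + beta["rv"] * d$rv +
    beta["cond_ov"] * d$cond * d$ov + beta["cond_rv"] * d$cond * d$rv +
    beta["trial"] * d$trial_z + d$b_i
  d$rt <- if (log_normal) exp(mu / 4 + stats::rnorm(nrow(d), 0, sigma))
          else mu + stats::rnorm(nrow(d), 0, sigma)
  d
}

# logistic mixed data for the accuracy model
glmm_acc_data <- function(n_part = 20, n_per_cond = 30,
                          beta = c(cond = -0.2, ov = 0.05, rv = 0.68,
                                   cond_ov = 0, cond_rv = 0, trial = 0),
                          b0 = -1.2, sd_int = 0.3) {
  d <- with_contrast(design_skeleton(n_part, n_per_cond))
  re <- d |>
    dplyr::distinct(participant) |>
    dplyr::mutate(b_i = stats::rnorm(dplyr::n(), 0, sd_int))
  d <- dplyr::left_join(d, re, by = "participant")
  eta <- b0 + beta["cond"] * d$cond + beta["ov"] * d$ov +
    beta["rv"] * d$rv + beta["cond_ov"] * d$cond * d$ov +
    beta["cond_rv"] * d$cond * d$rv + beta["trial"] * d$trial_z + d$b_i
  d$accuracy <- stats::runif(nrow(d)) < stats::plogis(eta)
  d$rt <- 2.5
  d
}

# conflict data from the generative conflict model (continuous mean,
# Gaussian noise, rounded and clamped to 1..5); returns both the table and
# the implied coefficients on the orthogonal-polynomial design actually
# fitted by fit_conflict_model
conflict_data <- function(n_part = 20, n_per_cond = 30,
                          b = c(b0 = 2.8, b1 = 0.3, b2 = 0.8, b3 = -0.12,
                                b4 = -0.3, b5 = -0.5),
                          sd_int = 0.2, sigma = 0.6) {
  d <- with_contrast(design_skeleton(n_part, n_per_cond))
  re <- d |>
    dplyr::distinct(participant) |>
    dplyr::mutate(b_i = stats::rnorm(dplyr::n(), 0, sd_int))
  d <- dplyr::left_join(d, re, by = "participant")
  s <- (d$ov - 5) / 5
  mu <- b["b0"] + b["b1"] * s + b["b2"] * (s^2 - 1 / 3) + b["b3"] * d$rv +
    b["b4"] * d$cond + b["b5"] * d$cond * s
  d$conflict <- pmin(pmax(round(mu + d$b_i +
                                  stats::rnorm(nrow(d), 0, sigma)), 1), 5)
  po <- stats::poly(d$ov, 2)
  dd <- d
  dd$ov_lin <- po[, 1]
  dd$ov_quad <- po[, 2]
  implied <- stats::coef(stats::lm(
    mu ~ cond + ov_lin + ov_quad + rv + cond:ov_lin + cond:ov_quad +
      cond:rv + trial_z, data = dd))
  list(trials = d, implied = implied)
}

# inclusive-trial data under the sigmoid keep rule for the voluntary models
keep_data <- function(n_part = 15, n_trials = 60, temperature = 0.8,
                      sd_int = 0.3, global_mean = 5) {
  trials <- purrr::map_dfr(seq_len(n_part), function(p) {
    b_i <- stats::rnorm(1, 0, sd_int)
    purrr::map_dfr(seq_len(n_trials), function(t) {
      v <- stats::runif(4, 0, 10)
      first <- which.max(v)
      eta <- (v - global_mean) / temperature + b_i
      kept <- stats::runif(4) < stats::plogis(eta)
      kept[first] <- TRUE
      tibble::tibble(
        participant = sprintf("s%02d", p), trial = t,
        condition = "inclusive", framing = "selection",
        v1 = v[1], v2 = v[2], v3 = v[3], v4 = v[4],
        rt = 2.5 + stats::runif(1), choice = first,
        accuracy = TRUE, omitted = FALSE,
        kept_mask = paste(as.integer(kept), collapse = ""))
    })
  })
  ratings <- tibble::tibble(
    participant = rep(sprintf("s%02d", seq_len(n_part)), each = 2),
    product = rep(1:2, n_part),
    rating = rep(c(global_mean - 1, global_mean + 1), n_part))
  list(trials = trials, ratings = ratings)
}

ci_covers <- function(ct, term, value) {
  row <- ct[ct$term == term, ]
  nrow(row) == 1 && !is.na(row$conf.low) &&
    row$conf.low <= value && value <= row$conf.high
}

# binomial three-sigma band around nominal 95% coverage, with the number
# of replicates (not replicate x term checks) as the effective n
coverage_band <- function(n_rep) {
  half <- 3 * sqrt(0.95 * 0.05 / n_rep)
  c(max(0, 0.95 - half), 1)
}
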
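#' Regression summary of one simulated batch
#'
#' The simulate-regress-compare machinery describes a batch of simulated
#' trials by the same regressions applied to empirical data, fitted without
#' random effects since simulated trials are exchangeable: a linear model
#' of RT on overall and relative value and a logistic model of accuracy on
#' the same predictors, plus the batch mean RT and accuracy.
#'
#' @param batch Output of [simulate_batch] (needs `rt`, `omitted`,
#'   `accuracy`, `ov`, `rv`).
#' @return A tibble with columns `metric`, `estimate`, `std.error` and the
#'   batch `omission_rate` as an attribute. Metrics: `rt_ov`, `rt_rv`,
#'   `acc_ov`, `acc_rv` (log-odds), `mean_rt`, `mean_acc`.
#' @export
sim_regressions <- function(batch) {
  d <- dplyr::filter(batch, !.data$omitted)
  omit_rate <- 1 - nrow(d) / nrow(batch)
  out <- tibble::tibble(
    metric = c("rt_ov", "rt_rv", "acc_ov", "acc_rv", "mean_rt", "mean_acc"),
    estimate = NA_real_, std.error = NA_real_)
  if (nrow(d) < 10) {
    attr(out, "omission_rate") <- omit_rate
    return(out)
  }
  lfit <- stats::lm(rt ~ ov + rv, data = d)
  ls <- summary(lfit)$coefficients
  acc <- as.numeric(d$accuracy)
  if (stats::var(acc) > 1e-12) {
    gfit <- suppressWarnings(stats::glm(acc ~ ov + rv, data = d,
                                        family = stats::binomial()))
    gs <- summary(gfit)$coefficients
  } else {
    gs <- ls[0, , drop = FALSE]
  }
  pick <- function(tab, term, col) {
    # rank-deficient fits (e.g. a constant predictor) drop the row
    if (term %in% rownames(tab)) tab[term, col] else NA_real_
  }
  fill <- function(metric, est, se) {
    out[out$metric == metric, c("estimate", "std.error")] <<-
      list(est, se)
  }
  fill("rt_ov", pick(ls, "ov", 1), pick(ls, "ov", 2))
  fill("rt_rv", pick(ls, "rv", 1), pick(ls, "rv", 2))
  fill("acc_ov", pick(gs, "ov", 1), pick(gs, "ov", 2))
  fill("acc_rv", pick(gs, "rv", 1), pick(gs, "rv", 2))
  fill("mean_rt", mean(d$rt), stats::sd(d$rt) / sqrt(nrow(d)))
  fill("mean_acc", mean(acc), stats::sd(acc) / sqrt(nrow(d)))
  attr(out, "omission_rate") <- omit_rate
  out
}

#' Qualitative signature of a single-parameter manipulation
#'
#' Simulates choice behavior at each level of one manipulated LCA
#' parameter, refits the RT and accuracy regressions at each level, and
#' classifies how each key quantity changes from the first to the last
#' level: `increase`, `decrease`, `~unchanged`, or `mixed` (non-monotone
#' across levels). A change counts as real only when it is both
#' distinguishable from Monte-Carlo error (first-vs-last difference at
#' least `z_threshold` standard errors) *and* material (relative change of
#' at least `rel_threshold` of the larger absolute estimate); otherwise
#' the quantity is classified `~unchanged`. A `magnitude` column
#' classifies the change in absolute size the same way, which is the
#' natural reading of "attenuated" for signed slopes.
#'
#' @param base Baseline [lca_params].
#' @param manipulate Name of the manipulated parameter
#'   (`"k"`, `"m"`, `"g"`, `"c"`, `"a"` or `"beta"`).
#' @param levels Numeric values of the manipulated parameter, in
#'   manipulation order (directions are read from first to last level).
#' @param choice_sets Evaluation sets; defaults to [eval_choice_sets()].
#' @param n_iter Simulated trials per choice set per level.
#' @param z_threshold Monte-Carlo z threshold below which a change is
#'   classified as unchanged.
#' @param rel_threshold Relative-magnitude threshold below which a change
#'   is classified as unchanged.
#' @param seed Optional seed.
#' @return An `lca_signature` object: list with `coefficients` (per level
#'   and metric) and `profile` (per metric classification).
#' @export
signature_scan <- function(base, manipulate, levels,
                           choice_sets = eval_choice_sets(), n_iter = 100,
                           z_threshold = 3, rel_threshold = 0.1,
                           seed = NULL) {
  stopifnot(inherits(base, "lca_params"),
            manipulate %in% c("k", "m", "g", "c", "a", "beta"),
            length(levels) >= 2, n_iter >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  coefs <- purrr::map2_dfr(levels, seq_along(levels), function(lv, i) {
    params <- do.call(update_params,
                      c(list(base), stats::setNames(list(lv), manipulate)))
    batch <- simulate_batch(params, choice_sets, n_iter = n_iter)
    reg <- sim_regressions(batch)
    omr <- attr(reg, "omission_rate")
    reg$level <- lv
    reg$level_index <- i
    reg$omission_rate <- omr
    reg
  })
  profile <- coefs |>
    dplyr::group_by(.data$metric) |>
    dplyr::arrange(.data$level_index, .by_group = TRUE) |>
    dplyr::summarise(
      first = dplyr::first(.data$estimate),
      last = dplyr::last(.data$estimate),
      delta = .data$last - .data$first,
      se_delta = sqrt(dplyr::first(.data$std.error)^2 +
                        dplyr::last(.data$std.error)^2),
      z = .data$delta / .data$se_delta,
      monotone = all(diff(.data$estimate) >= 0) ||
        all(diff(.data$estimate) <= 0),
      delta_abs = abs(.data$last) - abs(.data$first),
      z_abs = .data$delta_abs / .data$se_delta,
      .groups = "drop") |>
    dplyr::mutate(
      scale = pmax(abs(.data$first), abs(.data$last)),
      rel_change = abs(.data$delta) / .data$scale,
      direction = dplyr::case_when(
        is.na(.data$z) ~ "undefined",
        abs(.data$z) < z_threshold ~ "~unchanged",
        .data$rel_change < rel_threshold ~ "~unchanged",
        !.data$monotone ~ "mixed",
        .data$delta > 0 ~ "increase",
        TRUE ~ "decrease"),
      magnitude = dplyr::case_when(
        is.na(.data$z_abs) ~ "undefined",
        abs(.data$z_abs) < z_threshold ~ "~unchanged",
        abs(.data$delta_abs) / .data$scale < rel_threshold ~ "~unchanged",
        .data$delta_abs > 0 ~ "increase",
        TRUE ~ "decrease"))
  flagged <- unique(coefs$level[coefs$omission_rate > 0.5])
  structure(list(manipulate = manipulate, levels = levels,
                 coefficients = coefs, profile = profile,
                 uninformative_levels = flagged),
            class = "lca_signature")
}

#' @export
print.lca_signature <- function(x, ...) {
  cat("<lca_signature> manipulating", x$manipulate, "over",
      paste(x$levels, collapse = " -> "), "\n")
  print(x$profile[, c("metric", "first", "last", "direction", "magnitude")])
  if (length(x$uninformative_levels)) {
    cat("uninformative levels (omission rate > 50%):",
        paste(x$uninformative_levels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.lca_signature <- function(x, ...) x$profile

#' Build a parameter grid
#'
#' Expands named value vectors into a grid tibble. Condition-specific
#' parameters use suffixed names (`m_exclusive`, `m_inclusive`,
#' `a_high_urgency`, ...); bare names are shared across conditions.
#'
#' @param ... Named numeric vectors of candidate values.
#' @return A tibble with one row per parameter combination.
#' @export
param_grid <- function(...) {
  tidyr::expand_grid(...)
}

# Assemble condition-specific lca_params from one grid row.
grid_row_params <- function(row, condition, base) {
  fields <- c("k", "m", "g", "c", "a", "beta", "dt", "t_max")
  overrides <- list()
  for (f in fields) {
    specific <- paste0(f, "_", condition)
    if (specific %in% names(row)) overrides[[f]] <- row[[specific]]
    else if (f %in% names(row)) overrides[[f]] <- row[[f]]
  }
  do.call(update_params, c(list(base), overrides))
}

# Simulate every grid row for every condition and return the long
# coefficient table (one row per grid row, condition, metric).
evaluate_grid <- function(grid, conditions, base, choice_sets, n_iter) {
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    purrr::map_dfr(conditions, function(cond) {
      params <- grid_row_params(grid[i, ], cond, base)
      reg <- sim_regressions(simulate_batch(params, choice_sets,
                                            n_iter = n_iter))
      reg$grid_row <- i
      reg$condition <- cond
      reg
    })
  })
}

#' Grid-search fit of LCA parameters to target regression coefficients
#'
#' For every grid point, simulates choice behavior in each condition,
#' refits the RT and accuracy regressions, and scores the point by the sum
#' of squared differences between simulated and target coefficients after
#' z-standardising each coefficient across grid points (so quantities on
#' different scales contribute comparably). Returns the best point, the
#' full loss table, and the five best alternates.
#'
#' @param targets Target coefficients: tibble with `condition`, `metric`,
#'   `estimate` (e.g. from [simulate_targets] or from empirical fits).
#' @param grid A [param_grid] tibble.
#' @param base Baseline [lca_params] supplying unsearched parameters.
#' @param choice_sets Evaluation sets; defaults to [eval_choice_sets()].
#' @param n_iter Simulated trials per set per grid point and condition.
#' @param seed Optional seed.
#' @return An `lca_grid_fit` object: list with `best` (grid row), `loss`
#'   (per-row loss table), `top5`, `coefficients` (simulated coefficient
#'   long table) and the inputs.
#' @export
fit_grid <- function(targets, grid, base = lca_params(),
                     choice_sets = eval_choice_sets(), n_iter = 100,
                     seed = NULL) {
  stopifnot(nrow(grid) >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  conditions <- unique(targets$condition)
  sims <- evaluate_grid(grid, conditions, base, choice_sets, n_iter)
  if (all(is.na(sims$estimate))) {
    stop("simulation produced no usable regression estimates on any grid ",
         "point", call. = FALSE)
  }
  loss_tbl <- grid_loss(sims, targets)
  best_i <- loss_tbl$grid_row[which.min(loss_tbl$loss)]
  structure(list(
    best = dplyr::bind_cols(grid[best_i, ],
                            loss = min(loss_tbl$loss, na.rm = TRUE)),
    best_row = best_i,
    loss = dplyr::bind_cols(grid[loss_tbl$grid_row, ], loss_tbl["loss"]),
    top5 = utils::head(dplyr::arrange(
      dplyr::bind_cols(grid[loss_tbl$grid_row, ], loss_tbl["loss"]),
      .data$loss), 5),
    coefficients = sims, targets = targets, grid = grid),
    class = "lca_grid_fit")
}

# z-standardise each (condition, metric) across grid rows, score targets on
# the same scale, and aggregate squared differences per row. Coefficients
# that do not vary across the grid (sd ~ 0) are compared unstandardised on
# a unit scale so a 1-point grid still yields a finite loss.
grid_loss <- function(sims, targets) {
  scaled <- sims |>
    dplyr::group_by(.data$condition, .data$metric) |>
    dplyr::mutate(mu = mean(.data$estimate, na.rm = TRUE),
                  sigma = stats::sd(.data$estimate, na.rm = TRUE),
                  sigma = ifelse(is.na(.data$sigma) | .data$sigma < 1e-12,
                                 1, .data$sigma),
                  z_sim = (.data$estimate - .data$mu) / .data$sigma) |>
    dplyr::ungroup() |>
    dplyr::inner_join(targets[, c("condition", "metric", "estimate")] |>
                        dplyr::rename(target = "estimate"),
                      by = c("condition", "metric")) |>
    dplyr::mutate(z_target = (.data$target - .data$mu) / .data$sigma)
  scaled |>
    dplyr::group_by(.data$grid_row) |>
    dplyr::summarise(loss = sum((.data$z_sim - .data$z_target)^2,
                                na.rm = TRUE),
                     .groups = "drop")
}

#' @export
print.lca_grid_fit <- function(x, ...) {
  cat("<lca_grid_fit> ", nrow(x$grid), " grid points, best loss ",
      signif(x$best$loss, 4), "\n", sep = "")
  print(x$best)
  invisible(x)
}

#' @export
tidy.lca_grid_fit <- function(x, ...) tibble::as_tibble(x$loss)

#' @export
glance.lca_grid_fit <- function(x, ...) {
  tibble::tibble(n_grid = nrow(x$grid), best_loss = x$best$loss,
                 best_row = x$best_row)
}

#' Simulate target coefficients from known condition parameters
#'
#' Convenience wrapper for recovery and discrimination experiments:
#' simulates each condition at its known parameters and returns the
#' regression coefficients in the shape [fit_grid] expects.
#'
#' @param params_by_condition Named list of [lca_params].
#' @param choice_sets,n_iter,seed As in [fit_grid].
#' @return A tibble with `condition`, `metric`, `estimate`, `std.error`.
#' @export
simulate_targets <- function(params_by_condition,
                             choice_sets = eval_choice_sets(),
                             n_iter = 1000, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  purrr::imap_dfr(params_by_condition, function(params, cond) {
    reg <- sim_regressions(simulate_batch(params, choice_sets,
                                          n_iter = n_iter))
    reg$condition <- cond
    reg
  })
}

#' Compare the mutual-inhibition and boundary mechanism families
#'
#' Scores two rival explanations of a two-condition difference in choice
#' behavior: a family in which mutual inhibition `m` differs between
#' conditions (with shared boundary), and a family in which the boundary
#' parameters (`a` and/or `beta`) differ (with shared `m`). Both grids are
#' simulated, coefficients are z-standardised jointly across the union of
#' grid points so losses are directly comparable, and the family attaining
#' the lower best loss is reported.
#'
#' @param targets Target coefficients (tibble with `condition`, `metric`,
#'   `estimate`).
#' @param m_grid Grid over the inhibition family (condition-specific `m`).
#' @param boundary_grid Grid over the boundary family (condition-specific
#'   `a` and/or `beta`).
#' @param base Baseline [lca_params] for unsearched parameters.
#' @param choice_sets,n_iter,seed As in [fit_grid].
#' @return An `lca_mechanism_comparison`: list with the winning `family`,
#'   per-family best losses and grid rows, and per-coefficient residuals of
#'   each family's best fit.
#' @export
compare_mechanisms <- function(targets, m_grid, boundary_grid,
                               base = lca_params(),
                               choice_sets = eval_choice_sets(),
                               n_iter = 100, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  conditions <- unique(targets$condition)
  sims_m <- evaluate_grid(m_grid, conditions, base, choice_sets, n_iter)
  sims_b <- evaluate_grid(boundary_grid, conditions, base, choice_sets,
                          n_iter)
  sims_m$family <- "inhibition"
  sims_b$family <- "boundary"
  sims_b$grid_row <- sims_b$grid_row + nrow(m_grid)
  pooled <- dplyr::bind_rows(sims_m, sims_b)
  losses <- grid_loss(pooled, targets)
  fam <- tibble::tibble(grid_row = seq_len(nrow(m_grid) + nrow(boundary_grid)),
                        family = rep(c("inhibition", "boundary"),
                                     c(nrow(m_grid), nrow(boundary_grid))))
  losses <- dplyr::left_join(losses, fam, by = "grid_row")
  best <- losses |>
    dplyr::group_by(.data$family) |>
    dplyr::slice_min(.data$loss, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  winner <- best$family[which.min(best$loss)]
  resid <- pooled |>
    dplyr::filter(.data$grid_row %in% best$grid_row) |>
    dplyr::inner_join(targets[, c("condition", "metric", "estimate")] |>
                        dplyr::rename(target = "estimate"),
                      by = c("condition", "metric")) |>
    dplyr::mutate(residual = .data$estimate - .data$target) |>
    dplyr::select(dplyr::all_of(c("family", "condition", "metric",
                                  "estimate", "target", "residual")))
  structure(list(family = winner, best = best, losses = losses,
                 residuals = resid, m_grid = m_grid,
                 boundary_grid = boundary_grid),
            class = "lca_mechanism_comparison")
}

#' @export
print.lca_mechanism_comparison <- function(x, ...) {
  cat("<lca_mechanism_comparison> winner:", x$family, "\n")
  print(x$best)
  invisible(x)
}

#' @export
glance.lca_mechanism_comparison <- function(x, ...) {
  tibble::tibble(family = x$family,
                 loss_inhibition =
                   x$best$loss[x$best$family == "inhibition"],
                 loss_boundary = x$best$loss[x$best$family == "boundary"])
}
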
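#' Coefficient tables
#'
#' All model-fitting functions return a `coef_table`: a tibble with one row
#' per fixed-effect term (`term`, `estimate`, `std.error`, `conf.low`,
#' `conf.high`, `p.value`) and fit metadata in attributes. Intervals are
#' Wald-type 95% intervals and p-values are two-sided Wald z tests.
#'
#' @param x A fitted `merMod` (or `lm`/`glm`) object.
#' @param random_structure Label of the random-effect structure actually
#'   used (`"full"`, `"uncorrelated"`, `"intercept"`, `"none"`).
#' @param dropped Terms dropped as inestimable (near-constant predictors).
#' @param notes Free-text fit notes (e.g. separation handling).
#' @return A `coef_table` tibble.
#' @keywords internal
new_coef_table <- function(x, random_structure = "none",
                           dropped = character(0), notes = character(0)) {
  if (inherits(x, "merMod")) {
    cf <- lme4::fixef(x)
    se <- sqrt(diag(as.matrix(stats::vcov(x))))
    n_obs <- stats::nobs(x)
    n_groups <- lme4::ngrps(x)[[1]]
    converged <- length(x@optinfo$conv$lme4$messages) == 0
    singular <- lme4::isSingular(x)
  } else {
    sm <- summary(x)$coefficients
    cf <- sm[, 1]
    se <- sm[, 2]
    n_obs <- stats::nobs(x)
    n_groups <- NA_integer_
    converged <- TRUE
    singular <- FALSE
  }
  z <- cf / se
  out <- tibble::tibble(
    term = names(cf),
    estimate = unname(cf),
    std.error = unname(se),
    conf.low = unname(cf - stats::qnorm(0.975) * se),
    conf.high = unname(cf + stats::qnorm(0.975) * se),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
  if (length(dropped)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = dropped, estimate = NA_real_, std.error = NA_real_,
      conf.low = NA_real_, conf.high = NA_real_, p.value = NA_real_))
    notes <- c(notes, paste("inestimable term(s):",
                            paste(dropped, collapse = ", ")))
  }
  structure(out,
            class = c("coef_table", class(out)),
            random_structure = random_structure,
            converged = converged, singular = singular,
            n_obs = n_obs, n_groups = n_groups,
            notes = notes)
}

#' @export
print.coef_table <- function(x, ...) {
  cat("Coefficient table (", attr(x, "n_obs"), " obs",
      if (!is.na(attr(x, "n_groups")))
        paste0(", ", attr(x, "n_groups"), " participants, random: ",
               attr(x, "random_structure")),
      ")\n", sep = "")
  if (length(attr(x, "notes"))) {
    cat("note:", paste(attr(x, "notes"), collapse = "; "), "\n")
  }
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.coef_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.coef_table <- function(x, ...) {
  tibble::tibble(
    n_obs = attr(x, "n_obs"),
    n_groups = attr(x, "n_groups"),
    random_structure = attr(x, "random_structure"),
    converged = attr(x, "converged"),
    singular = attr(x, "singular"),
    notes = paste(attr(x, "notes"), collapse = "; ")
  )
}

# ---- shared data preparation ------------------------------------------------

# Adds the numeric condition contrast and a within-participant standardised
# trial-order column; validates the two-level design.
prepare_trials <- function(trials, require = character(0)) {
  trials <- tibble::as_tibble(trials)
  need <- unique(c("participant", "condition", require))
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("ov", "rv") %in% names(trials))) {
    trials <- add_value_summaries(trials)
  }
  if (length(unique(trials$condition)) == 2) {
    cc <- condition_contrast(unique(trials$condition))
    trials$cond <- unname(cc[as.character(trials$condition)])
  } else {
    trials$cond <- 0 # single-condition table: contrast is inestimable
  }
  if ("trial" %in% names(trials)) {
    trials <- trials |>
      dplyr::group_by(.data$participant) |>
      dplyr::mutate(trial_z = if (dplyr::n() > 1 &&
                                  stats::sd(.data$trial) > 0)
        as.numeric(scale(.data$trial)) else 0) |>
      dplyr::ungroup()
  } else {
    trials$trial_z <- 0
  }
  trials
}

# Predictors with (near-)zero variance cannot be estimated; they are
# dropped from the formula and reported as inestimable.
split_estimable <- function(data, terms) {
  base <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  bad_base <- base[vapply(base, function(v) {
    x <- data[[v]]
    !is.numeric(x) || stats::sd(x, na.rm = TRUE) < 1e-10
  }, logical(1))]
  dropped <- terms[vapply(terms, function(tm) {
    any(strsplit(tm, ":", fixed = TRUE)[[1]] %in% bad_base)
  }, logical(1))]
  list(keep = setdiff(terms, dropped), dropped = dropped)
}

# Convergence fallback ladder: correlated random slopes -> uncorrelated
# slopes -> random intercept only. A rung is accepted when the fit neither
# errors, fails to converge, nor is singular; if every rung is rejected the
# intercept-only fit is returned with a note.
fit_ladder <- function(response, fixed_terms, random_terms, data,
                       family = NULL, ladder = TRUE) {
  group <- "participant"
  rhs <- paste(fixed_terms, collapse = " + ")
  forms <- list(
    full = paste0(response, " ~ ", rhs, " + (1 + ",
                  paste(random_terms, collapse = " + "), " | ", group, ")"),
    uncorrelated = paste0(response, " ~ ", rhs, " + (1 + ",
                          paste(random_terms, collapse = " + "), " || ",
                          group, ")"),
    intercept = paste0(response, " ~ ", rhs, " + (1 | ", group, ")")
  )
  if (!length(random_terms)) forms <- forms["intercept"]
  if (!ladder) forms <- forms["intercept"]
  last <- NULL
  for (rung in names(forms)) {
    fit <- try(suppressMessages(suppressWarnings(
      if (is.null(family)) {
        lme4::lmer(stats::as.formula(forms[[rung]]), data = data,
                   REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE))
      } else {
        lme4::glmer(stats::as.formula(forms[[rung]]), data = data,
                    family = family, nAGQ = 0L,
                    control = lme4::glmerControl(calc.derivs = FALSE))
      })), silent = TRUE)
    if (inherits(fit, "try-error")) next
    last <- list(fit = fit, rung = rung)
    ok <- length(fit@optinfo$conv$lme4$messages) == 0 &&
      !isTRUE(lme4::isSingular(fit))
    if (ok) return(last)
  }
  if (is.null(last)) {
    stop("mixed-model fitting failed at every random-effect structure",
         call. = FALSE)
  }
  last$note <- "no non-singular converged fit; reporting last rung"
  last
}

# ---- model fits -------------------------------------------------------------

#' Mixed-effects model of first-choice reaction time
#'
#' Linear mixed model of (optionally log-transformed) RT on the condition
#' contrast, overall value, relative value, their interactions with
#' condition, and trial order, with participant-specific random intercepts
#' and slopes. Omitted trials are dropped. When the full random structure
#' is singular or fails to converge, the fit steps down a ladder
#' (correlated slopes, uncorrelated slopes, intercept only) and records
#' which rung was used.
#'
#' @param trials Trial table with `participant`, `condition`, `rt`,
#'   `omitted`, option values (`v1..v4` or precomputed `ov`/`rv`) and
#'   optionally `trial`.
#' @param log_transform Model `log(rt)` instead of raw RT (used when RTs
#'   are long-tailed, e.g. without a response deadline).
#' @param random_slopes Character vector of predictors given random slopes;
#'   `NULL` (default) uses every fixed main effect.
#' @param ladder Use the convergence fallback ladder? `FALSE` fits the
#'   random-intercept model directly.
#' @return A [coef_table][new_coef_table].
#' @export
fit_rt_model <- function(trials, log_transform = FALSE, random_slopes = NULL,
                         ladder = TRUE) {
  d <- prepare_trials(trials, require = c("rt", "omitted"))
  d <- dplyr::filter(d, !.data$omitted, is.finite(.data$rt))
  if (length(unique(d$participant)) < 2) {
    stop("mixed models require at least 2 participants", call. = FALSE)
  }
  d$resp <- if (log_transform) log(d$rt) else d$rt
  terms <- c("cond", "ov", "rv", "cond:ov", "cond:rv", "trial_z")
  est <- split_estimable(d, terms)
  rs <- if (is.null(random_slopes)) {
    intersect(c("cond", "ov", "rv", "trial_z"), est$keep)
  } else {
    random_slopes
  }
  res <- fit_ladder("resp", est$keep, rs, d, ladder = ladder)
  new_coef_table(res$fit, random_structure = res$rung,
                 dropped = est$dropped, notes = res$note %||% character(0))
}

#' Mixed-effects logistic model of first-choice accuracy
#'
#' Generalized linear mixed model (logit link) of whether the
#' framing-relevant extreme option was acted on first, with the same fixed
#' and random structure as [fit_rt_model]. Degenerate responses (all
#' accurate or all inaccurate) cannot identify the coefficients; the fit is
#' then replaced by a weakly regularised logistic fit (two pseudo-trials at
#' the design mean, one per outcome) and flagged.
#'
#' @inheritParams fit_rt_model
#' @return A [coef_table][new_coef_table] of log-odds coefficients.
#' @export
fit_accuracy_model <- function(trials, random_slopes = NULL, ladder = TRUE) {
  d <- prepare_trials(trials, require = c("accuracy", "omitted"))
  d <- dplyr::filter(d, !.data$omitted, !is.na(.data$accuracy))
  if (length(unique(d$participant)) < 2) {
    stop("mixed models require at least 2 participants", call. = FALSE)
  }
  d$acc <- as.numeric(d$accuracy)
  terms <- c("cond", "ov", "rv", "cond:ov", "cond:rv", "trial_z")
  est <- split_estimable(d, terms)
  if (stats::var(d$acc) < 1e-12) {
    # complete separation: regularise with one pseudo-trial per outcome at
    # the predictor means, fit a plain logistic model, and flag it
    aug <- d[1:2, ]
    for (v in c("cond", "ov", "rv", "trial_z")) aug[[v]] <- mean(d[[v]])
    aug$acc <- c(0, 1)
    fit <- suppressWarnings(stats::glm(
      stats::as.formula(paste("acc ~", paste(est$keep, collapse = " + "))),
      data = dplyr::bind_rows(d, aug), family = stats::binomial()))
    return(new_coef_table(fit, random_structure = "none",
                          dropped = est$dropped,
                          notes = "degenerate response; penalized fallback"))
  }
  rs <- if (is.null(random_slopes)) {
    intersect(c("cond", "ov", "rv", "trial_z"), est$keep)
  } else {
    random_slopes
  }
  res <- fit_ladder("acc", est$keep, rs, d, family = stats::binomial(),
                    ladder = ladder)
  new_coef_table(res$fit, random_structure = res$rung,
                 dropped = est$dropped, notes = res$note %||% character(0))
}

#' Mixed-effects model of retrospective choice conflict
#'
#' Linear mixed model of the 1--5 conflict rating on the condition
#' contrast, linear and quadratic overall value (orthogonal polynomials
#' computed on the analysed sample), relative value, the condition
#' interactions with each value term, and trial order. Optional covariates
#' add first-choice RT and accuracy.
#'
#' @inheritParams fit_rt_model
#' @param covariates Control for first-choice RT and accuracy?
#' @return A [coef_table][new_coef_table]; the OV terms appear as `ov_lin`
#'   and `ov_quad`.
#' @export
fit_conflict_model <- function(trials, covariates = FALSE,
                               random_slopes = NULL, ladder = TRUE) {
  d <- prepare_trials(trials, require = "conflict")
  d <- dplyr::filter(d, !is.na(.data$conflict))
  if (covariates) {
    d <- dplyr::filter(d, !.data$omitted, is.finite(.data$rt),
                       !is.na(.data$accuracy))
    d$accuracy <- as.numeric(d$accuracy)
  }
  po <- orthogonal_poly(d$ov)
  d$ov_lin <- po$lin
  d$ov_quad <- po$quad
  terms <- c("cond", "ov_lin", "ov_quad", "rv", "cond:ov_lin",
             "cond:ov_quad", "cond:rv", "trial_z")
  if (covariates) terms <- c(terms, "rt", "accuracy")
  est <- split_estimable(d, terms)
  rs <- if (is.null(random_slopes)) {
    intersect(setdiff(terms, grep(":", terms, value = TRUE)), est$keep)
  } else {
    random_slopes
  }
  res <- fit_ladder("conflict", est$keep, rs, d, ladder = ladder)
  new_coef_table(res$fit, random_structure = res$rung,
                 dropped = est$dropped, notes = res$note %||% character(0))
}

#' Models of voluntary subsequent choices on inclusive trials
#'
#' Fits the four analyses of what happens after the first choice on
#' inclusive trials: (a) a linear mixed model of the number of voluntary
#' selections/removals per trial, (b) of the number of products kept,
#' (c) a logistic mixed model of per-product keep probability on overall
#' value and the product's value relative to the participant's global mean
#' rating (the option acted on first is forced by the framing and is
#' excluded), and (d) a linear mixed model of the proportion of kept products
#' that are suboptimal (rated below the participant's global mean). Models
#' (a), (b) and (d) control for linear and quadratic overall value,
#' relative value, initial-choice RT and accuracy, and trial order;
#' `include_conflict` adds the trial's conflict rating as a predictor.
#'
#' @param trials Trial table including `kept_mask` strings for inclusive
#'   trials.
#' @param ratings Ratings table used to compute each participant's global
#'   mean rating.
#' @param include_conflict Add the conflict rating to models (a), (b), (d)?
#' @inheritParams fit_rt_model
#' @return Named list of [coef_table][new_coef_table]s: `n_actions`,
#'   `n_kept`, `keep_prob`, `suboptimal`.
#' @export
fit_voluntary_models <- function(trials, ratings, include_conflict = FALSE,
                                 random_slopes = NULL, ladder = TRUE) {
  d <- prepare_trials(trials, require = c("kept_mask", "rt", "accuracy",
                                          "omitted", "framing"))
  d <- dplyr::filter(d, .data$condition == "inclusive", !.data$omitted,
                     !is.na(.data$kept_mask))
  if (nrow(d) == 0) {
    stop("no inclusive trials with subsequent-choice records", call. = FALSE)
  }
  gm <- ratings |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(global_mean = mean(.data$rating), .groups = "drop")
  d <- dplyr::left_join(d, gm, by = "participant")
  km <- do.call(rbind, lapply(strsplit(d$kept_mask, ""), as.integer))
  vmat <- as.matrix(d[, paste0("v", 1:4)])
  d$n_kept <- rowSums(km)
  d$n_actions <- ifelse(d$framing == "selection", d$n_kept, 4 - d$n_kept)
  sub_kept <- rowSums(km * (vmat < d$global_mean))
  d$suboptimal <- ifelse(d$n_kept > 0, sub_kept / d$n_kept, 0)
  po <- orthogonal_poly(d$ov)
  d$ov_lin <- po$lin
  d$ov_quad <- po$quad
  d$accuracy <- as.numeric(d$accuracy)

  terms <- c("ov_lin", "ov_quad", "rv", "rt", "accuracy", "trial_z")
  if (include_conflict && "conflict" %in% names(d)) {
    terms <- c(terms, "conflict")
  }
  degenerate_table <- function(keep_terms, data, note) {
    structure(tibble::tibble(
      term = c("(Intercept)", keep_terms), estimate = NA_real_,
      std.error = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
      p.value = NA_real_),
      class = c("coef_table", "tbl_df", "tbl", "data.frame"),
      random_structure = "none", converged = FALSE, singular = FALSE,
      n_obs = nrow(data), n_groups = length(unique(data$participant)),
      notes = note)
  }
  fit_count <- function(resp) {
    est <- split_estimable(d, terms)
    if (stats::var(d[[resp]]) < 1e-12) {
      return(degenerate_table(est$keep, d,
                              "degenerate response (constant count)"))
    }
    rs <- if (is.null(random_slopes)) est$keep else random_slopes
    res <- fit_ladder(resp, est$keep, rs, d, ladder = ladder)
    new_coef_table(res$fit, random_structure = res$rung,
                   dropped = est$dropped, notes = res$note %||% character(0))
  }

  # per-product long table for the keep-probability model; the option acted
  # on first is forced (kept under selection, dropped under removal), so
  # only the three voluntary options enter
  long <- tidyr::pivot_longer(
    dplyr::mutate(d, row = dplyr::row_number()),
    cols = dplyr::all_of(paste0("v", 1:4)),
    names_to = "slot", values_to = "value")
  long$kept <- as.vector(t(km))
  long$slot_index <- as.integer(sub("v", "", long$slot))
  long <- dplyr::filter(long, .data$slot_index != rep(d$choice, each = 4))
  long$vdiff <- long$value - long$global_mean
  est_c <- split_estimable(long, c("ov", "vdiff"))
  keep_prob <- if (stats::var(long$kept) < 1e-12) {
    degenerate_table(est_c$keep, long,
                     "degenerate response (constant keep flag)")
  } else {
    rs_c <- if (is.null(random_slopes)) est_c$keep else random_slopes
    res_c <- fit_ladder("kept", est_c$keep, rs_c, long,
                        family = stats::binomial(), ladder = ladder)
    new_coef_table(res_c$fit, random_structure = res_c$rung,
                   dropped = est_c$dropped,
                   notes = res_c$note %||% character(0))
  }

  list(
    n_actions = fit_count("n_actions"),
    n_kept = fit_count("n_kept"),
    keep_prob = keep_prob,
    suboptimal = fit_count("suboptimal")
  )
}

#' Condition-wise behavioral summaries
#'
#' Per-condition means of reaction time, accuracy, reward rate (chosen
#' value divided by RT, averaged over trials) and, when present, conflict,
#' with cluster-bootstrap 95% intervals resampling participants.
#'
#' @inheritParams fit_rt_model
#' @param n_boot Bootstrap resamples.
#' @param seed Optional seed for the bootstrap.
#' @return A tibble with one row per condition and measure: `mean`,
#'   `conf.low`, `conf.high`, `n_trials`.
#' @export
summarize_condition_means <- function(trials, n_boot = 1000, seed = NULL) {
  d <- prepare_trials(trials, require = c("rt", "choice", "omitted"))
  vmat <- as.matrix(d[, paste0("v", 1:4)])
  d$chosen_value <- ifelse(d$omitted, NA_real_,
                           vmat[cbind(seq_len(nrow(d)),
                                      ifelse(is.na(d$choice), 1, d$choice))])
  d$rrate <- ifelse(d$omitted, NA_real_, d$chosen_value / d$rt)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  measures <- c("rt", "accuracy", "rrate",
                if ("conflict" %in% names(d)) "conflict")
  measures <- intersect(measures, names(d))
  parts <- unique(d$participant)
  split_d <- split(d, d$participant)

  stat_fun <- function(dat) {
    dat |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(measures),
                                     ~ mean(as.numeric(.x), na.rm = TRUE)),
                       .groups = "drop")
  }
  pt <- stat_fun(d)
  boots <- purrr::map(seq_len(n_boot), function(i) {
    take <- sample(parts, length(parts), replace = TRUE)
    stat_fun(dplyr::bind_rows(split_d[take]))
  })
  boot_long <- dplyr::bind_rows(boots) |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure") |>
    dplyr::group_by(.data$condition, .data$measure) |>
    dplyr::summarise(conf.low = stats::quantile(.data$value, 0.025,
                                                na.rm = TRUE),
                     conf.high = stats::quantile(.data$value, 0.975,
                                                 na.rm = TRUE),
                     .groups = "drop")
  n_tr <- d |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_trials = dplyr::n(), .groups = "drop")
  pt |>
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "mean") |>
    dplyr::left_join(boot_long, by = c("condition", "measure")) |>
    dplyr::left_join(n_tr, by = "condition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
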
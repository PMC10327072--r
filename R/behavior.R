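#' Design specification for a synthetic study
#'
#' Collects the study-level settings the generator needs: sample size,
#' trial counts, framing (selection of wanted products vs removal of
#' unwanted ones), condition labels, the generative conflict model, and the
#' softness of the keep rule for voluntary subsequent choices.
#'
#' The conflict model produces, per trial,
#' `conflict = b0 + b1 s + b2 (s^2 - 1/3) + b3 rv + b4 cond + b5 cond * s + noise`
#' where `s = (ov - 5) / 5` is overall value rescaled to \[-1, 1\] and
#' `cond` is the +/-0.5 condition contrast, then rounds and clamps to the
#' 1--5 rating scale. A positive `b2` gives the characteristic U-shape in
#' overall value; a negative `b3` makes easy (high relative value) choices
#' feel less conflicting. The default condition-by-OV interaction `b5` is
#' negative under a selection framing (inclusivity relieves conflict most
#' for high-value sets) and positive under a removal framing (most relief
#' for low-value sets).
#'
#' @param n_participants Number of simulated participants.
#' @param trials_per_condition Trials per condition per participant.
#' @param framing `"selection"` or `"removal"`.
#' @param conditions Exactly two condition labels.
#' @param n_products Catalog size per participant.
#' @param conflict_coefs Named vector `b0..b5` (see above); `b5` defaults by
#'   framing when `NULL`.
#' @param conflict_sd SD of the Gaussian noise added before discretising
#'   conflict to the 1--5 scale.
#' @param keep_temperature Temperature of the sigmoid keep rule for
#'   voluntary subsequent choices; as it approaches 0 the rule becomes a
#'   hard threshold at the participant's global mean rating.
#' @param bad_participants Character vector of planted non-compliant
#'   participant types (any of `"constant_ratings"`, `"sloppy_chooser"`,
#'   `"flat_conflict"`, `"high_omitter"`), appended after the regular
#'   sample for exclusion-filter testing.
#' @return A `design_spec` object.
#' @export
design_spec <- function(n_participants = 20, trials_per_condition = 60,
                        framing = c("selection", "removal"),
                        conditions = c("exclusive", "inclusive"),
                        n_products = 200,
                        conflict_coefs = NULL,
                        conflict_sd = 0.6,
                        keep_temperature = 0.8,
                        bad_participants = character(0)) {
  framing <- match.arg(framing)
  stopifnot(length(conditions) == 2, n_participants >= 1,
            trials_per_condition >= 1, conflict_sd >= 0,
            keep_temperature > 0)
  default_b5 <- if (framing == "selection") -0.8 else 0.5
  coefs <- c(b0 = 2.4, b1 = 0.3, b2 = 1.2, b3 = -0.12, b4 = -0.45,
             b5 = default_b5)
  if (!is.null(conflict_coefs)) {
    coefs[names(conflict_coefs)] <- conflict_coefs
  }
  bad_types <- c("constant_ratings", "sloppy_chooser", "flat_conflict",
                 "high_omitter")
  if (!all(bad_participants %in% bad_types)) {
    stop("unknown bad participant type; use one of: ",
         paste(bad_types, collapse = ", "), call. = FALSE)
  }
  structure(
    list(n_participants = n_participants,
         trials_per_condition = trials_per_condition, framing = framing,
         conditions = level_order(conditions), n_products = n_products,
         conflict_coefs = coefs, conflict_sd = conflict_sd,
         keep_temperature = keep_temperature,
         bad_participants = bad_participants),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec> ", x$n_participants, " participants x ",
      2 * x$trials_per_condition, " trials (", x$framing, "; ",
      paste(x$conditions, collapse = " vs "), ")\n", sep = "")
  invisible(x)
}

#' Simulate choices, RTs and conflict ratings for one session
#'
#' Drives the LCA per condition over a generated session, then adds the
#' generative conflict rating and, on inclusive trials, voluntary
#' subsequent (de)selections under the sigmoid keep rule. RTs are reported
#' in seconds (simulation time units are calibrated so typical first
#' choices take 2--3 s).
#'
#' @param design A [design_spec].
#' @param params_by_condition Named list of [lca_params], one per condition
#'   label in the design.
#' @param session A session from [generate_session].
#' @param global_mean The participant's mean rating over the full catalog
#'   (the indifference point of the keep rule).
#' @return The session tibble with `rt`, `choice`, `omitted`, `accuracy`,
#'   `conflict` and `kept_mask` columns appended. `kept_mask` is a 4-char
#'   string of 0/1 flags (`NA` on exclusive trials).
#' @export
generate_behavior <- function(design, params_by_condition, session,
                              global_mean) {
  stopifnot(inherits(design, "design_spec"))
  miss <- setdiff(design$conditions, names(params_by_condition))
  if (length(miss)) {
    stop("missing LCA parameters for condition(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  session$rt <- NA_real_
  session$choice <- NA_integer_
  session$omitted <- TRUE
  for (cond in design$conditions) {
    rows <- which(session$condition == cond)
    sim <- simulate_batch(params_by_condition[[cond]],
                          session[rows, paste0("v", 1:4)], n_iter = 1)
    session$rt[rows] <- sim$rt
    session$choice[rows] <- sim$choice
    session$omitted[rows] <- sim$omitted
  }
  vmat <- as.matrix(session[, paste0("v", 1:4)])
  session$accuracy <- vapply(seq_len(nrow(session)), function(i) {
    if (session$omitted[i]) return(NA)
    is_accurate(session$choice[i], vmat[i, ], session$framing[i])
  }, logical(1))

  session$conflict <- generate_conflict(design, session)

  inclusive <- which(session$condition == "inclusive" & !session$omitted)
  session$kept_mask <- NA_character_
  for (i in inclusive) {
    kept <- generate_subsequent_choices(
      values = vmat[i, ], first_choice = session$choice[i],
      framing = session$framing[i], global_mean = global_mean,
      temperature = design$keep_temperature)
    session$kept_mask[i] <- paste(as.integer(kept), collapse = "")
  }
  session
}

# Continuous conflict from the generative model, discretised to 1..5.
generate_conflict <- function(design, session) {
  b <- design$conflict_coefs
  cc <- condition_contrast(design$conditions)
  cond <- unname(cc[session$condition])
  s <- (session$ov - 5) / 5
  mu <- b["b0"] + b["b1"] * s + b["b2"] * (s^2 - 1 / 3) +
    b["b3"] * session$rv + b["b4"] * cond + b["b5"] * cond * s
  raw <- mu + stats::rnorm(nrow(session), 0, design$conflict_sd)
  pmin(pmax(round(raw), 1), 5)
}

#' Voluntary keep decisions for an inclusive trial
#'
#' Each option is kept with probability
#' `plogis((value - global_mean) / temperature)`: the keep rule's
#' indifference point is the participant's global mean rating, and as
#' `temperature` approaches 0 it becomes the hard threshold rule (keep
#' exactly the options rated above the global mean). The option acted on
#' first is forced: kept under a selection framing, dropped under removal.
#'
#' @param values Four option ratings.
#' @param first_choice Index of the initially selected/removed option.
#' @param framing `"selection"` or `"removal"`.
#' @param global_mean Participant's mean rating of all rated products.
#' @param temperature Softness of the keep rule (> 0).
#' @return Logical vector of length 4: which options end up kept.
#' @export
generate_subsequent_choices <- function(values, first_choice,
                                        framing = c("selection", "removal"),
                                        global_mean, temperature = 0.8) {
  framing <- match.arg(framing)
  check_choice_values(values)
  stopifnot(temperature > 0)
  p_keep <- stats::plogis((values - global_mean) / temperature)
  kept <- stats::runif(4) < p_keep
  if (framing == "selection") kept[first_choice] <- TRUE
  else kept[first_choice] <- FALSE
  kept
}

#' Generate a complete synthetic study
#'
#' End-to-end generator: per participant, a rating catalog, a constrained
#' session, LCA-driven choices and RTs, conflict ratings, and voluntary
#' subsequent choices; optionally appends planted non-compliant
#' participants so the exclusion filters can be exercised. A single
#' top-level seed makes the whole study reproducible.
#'
#' @param design A [design_spec].
#' @param params_by_condition Named list of [lca_params] per condition;
#'   defaults to [default_condition_params()].
#' @param seed Optional integer seed.
#' @return A list with tibbles `ratings` (participant, product, rating),
#'   `trials` (one row per trial with values, behavior, conflict and
#'   kept_mask) and `meta` (seed and design settings).
#' @export
generate_study <- function(design, params_by_condition = NULL, seed = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (is.null(params_by_condition)) {
    params_by_condition <- default_condition_params()
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  ids <- sprintf("s%02d", seq_len(design$n_participants))
  bad <- design$bad_participants
  bad_ids <- if (length(bad)) sprintf("bad_%s_%d", bad, seq_along(bad))
             else character(0)

  ratings <- list()
  trials <- list()
  for (i in seq_along(c(ids, bad_ids))) {
    pid <- c(ids, bad_ids)[i]
    type <- if (i > length(ids)) bad[i - length(ids)] else "regular"
    part <- generate_participant(design, params_by_condition, pid, type)
    ratings[[i]] <- part$ratings
    trials[[i]] <- part$trials
  }
  list(ratings = dplyr::bind_rows(ratings),
       trials = dplyr::bind_rows(trials),
       meta = tibble::tibble(seed = if (is.null(seed)) NA_integer_ else seed,
                             framing = design$framing,
                             n_participants = design$n_participants,
                             trials_per_condition =
                               design$trials_per_condition))
}

generate_participant <- function(design, params_by_condition, pid, type) {
  catalog <- generate_catalog(design$n_products)
  if (type == "constant_ratings") catalog$rating <- rep(5, nrow(catalog))
  session <- generate_session(design, catalog)
  session <- generate_behavior(design, params_by_condition, session,
                               global_mean = mean(catalog$rating))
  vmat <- as.matrix(session[, paste0("v", 1:4)])
  if (type == "sloppy_chooser") {
    # picks a non-extreme option 80% of the time: easy-trial accuracy ~ 0.2
    for (i in which(!session$omitted)) {
      if (stats::runif(1) < 0.8) {
        worst <- if (session$framing[i] == "selection") which.min(vmat[i, ])
                 else which.max(vmat[i, ])
        session$choice[i] <- worst
      } else {
        best <- if (session$framing[i] == "selection") which.max(vmat[i, ])
                else which.min(vmat[i, ])
        session$choice[i] <- best
      }
      session$accuracy[i] <- is_accurate(session$choice[i], vmat[i, ],
                                         session$framing[i])
    }
  }
  if (type == "flat_conflict") session$conflict <- rep(3L, nrow(session))
  if (type == "high_omitter") {
    target <- if ("high_urgency" %in% design$conditions) "high_urgency"
              else design$conditions[2]
    hit <- session$condition == target & stats::runif(nrow(session)) < 0.5
    session$omitted[hit] <- TRUE
    session$rt[hit] <- NA_real_
    session$choice[hit] <- NA_integer_
    session$accuracy[hit] <- NA
  }
  session$participant <- pid
  catalog$participant <- pid
  list(ratings = catalog[, c("participant", "product", "rating")],
       trials = session[, c("participant", "trial", "condition", "framing",
                            paste0("v", 1:4), "ov", "rv", "rt", "choice",
                            "accuracy", "omitted", "conflict", "kept_mask")])
}

#' Apply the participant-level exclusion criteria
#'
#' A participant is excluded when any criterion fires: (1) rating
#' variability out of range (`SD < 1` or `SD > 5` over their product
#' ratings); (2) mean accuracy below 25% on easy trials (trials whose
#' relative value exceeds the participant's median); (3) conflict-rating
#' variability too low (`SD < 0.5`); (4) when a high-urgency condition is
#' present, an omission rate of 40% or more on high-urgency trials.
#' Filtering is idempotent and criteria are evaluated independently, so
#' their order is irrelevant.
#'
#' @param trials Trial table (needs `participant`, `rv`, `accuracy`,
#'   `omitted`, `condition`; `conflict` enables criterion 3).
#' @param ratings Ratings table (`participant`, `rating`).
#' @return A list: `trials` (rows of retained participants), `kept`
#'   (participant ids), `report` (per-participant criterion values, which
#'   criteria fired, and the exclusion flag).
#' @export
apply_exclusions <- function(trials, ratings) {
  need <- c("participant", "rv", "accuracy", "omitted", "condition")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("participant", "rating") %in% names(ratings))) {
    stop("ratings table needs columns participant, rating", call. = FALSE)
  }
  sd_val <- ratings |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(sd_value = stats::sd(.data$rating), .groups = "drop")

  per <- trials |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      easy_accuracy = mean(
        .data$accuracy[.data$rv > stats::median(.data$rv)], na.rm = TRUE),
      sd_conflict = if ("conflict" %in% names(trials))
        stats::sd(.data$conflict) else NA_real_,
      urgency_omission = if (any(.data$condition == "high_urgency"))
        mean(.data$omitted[.data$condition == "high_urgency"]) else NA_real_,
      .groups = "drop") |>
    dplyr::left_join(sd_val, by = "participant")

  per <- per |>
    dplyr::mutate(
      fire_sd_value = !is.na(.data$sd_value) &
        (.data$sd_value < 1 | .data$sd_value > 5),
      fire_easy_accuracy = !is.na(.data$easy_accuracy) &
        .data$easy_accuracy < 0.25,
      fire_sd_conflict = !is.na(.data$sd_conflict) & .data$sd_conflict < 0.5,
      fire_urgency_omission = !is.na(.data$urgency_omission) &
        .data$urgency_omission >= 0.4,
      excluded = .data$fire_sd_value | .data$fire_easy_accuracy |
        .data$fire_sd_conflict | .data$fire_urgency_omission,
      criteria = purrr::pmap_chr(
        list(.data$fire_sd_value, .data$fire_easy_accuracy,
             .data$fire_sd_conflict, .data$fire_urgency_omission),
        function(a, b, c, d) {
          paste(c("sd_value", "easy_accuracy", "sd_conflict",
                  "urgency_omission")[c(a, b, c, d)], collapse = ",")
        }))

  kept <- per$participant[!per$excluded]
  list(trials = dplyr::filter(trials, .data$participant %in% kept),
       kept = kept, report = per)
}
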
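#' Generate a product catalog of liking ratings
#'
#' Emulates the rating phase of the task: a participant rates a pool of
#' consumer products on an analog 0--10 liking scale. Ratings are drawn
#' uniformly on \[0, 10\] (SD about 2.9, comfortably inside the
#' rating-variability inclusion window).
#'
#' @param n_products Pool size; must support the session constraints
#'   (each product appears at most 3 times).
#' @return A tibble with columns `product` and `rating`.
#' @export
generate_catalog <- function(n_products = 200) {
  tibble::tibble(product = seq_len(n_products),
                 rating = stats::runif(n_products, 0, 10))
}

#' Sample one constrained choice set of target values
#'
#' Overall value is drawn uniformly on \[0, 10\]; the best option's value is
#' then drawn uniformly on `[OV, min(10, 4 OV)]`; the remaining three values
#' are constructed to have mean `(4 OV - best) / 3`, each within
#' `[0, best]`: two are sampled uniformly on `[0, best]` and the third is
#' fixed by the mean constraint, resampling whenever it falls outside the
#' interval. The realised set mean therefore equals the sampled OV exactly
#' (to floating-point precision).
#'
#' @param max_tries Resampling cap for the remainder construction.
#' @return A tibble row: `ov_target`, `v1..v4` (v1 is the best option).
#' @export
generate_choice_set <- function(max_tries = 1000) {
  ov <- stats::runif(1, 0, 10)
  best <- stats::runif(1, ov, min(10, 4 * ov))
  rest_mean <- (4 * ov - best) / 3
  rest <- NULL
  for (i in seq_len(max_tries)) {
    v23 <- stats::runif(2, 0, best)
    v4 <- 3 * rest_mean - sum(v23)
    if (v4 >= 0 && v4 <= best) {
      rest <- c(v23, v4)
      break
    }
  }
  if (is.null(rest)) {
    # only reachable for degenerate rest_mean at the interval ends
    rest <- rep(rest_mean, 3)
  }
  tibble::tibble(ov_target = ov, v1 = best, v2 = rest[1], v3 = rest[2],
                 v4 = rest[3])
}

#' Generate a constrained session of choice sets from a catalog
#'
#' Builds a full session of four-product trials that respects the task's
#' design constraints: every product appears at most 3 times, no product
#' appears on two consecutive trials, and no two trials show the same set
#' of four products. Overall- and relative-value distributions are matched
#' between the two conditions by sampling target value sets in pairs and
#' realising each member of a pair (with different products) in a different
#' condition; condition order is randomly interleaved under balance.
#'
#' Target values are mapped to concrete products by picking, for each
#' target, the admissible product whose rating is nearest; the trial's
#' recorded option values are the selected products' actual ratings.
#'
#' @param design A [design_spec] (supplies trial counts, framing and
#'   condition labels).
#' @param catalog A product catalog from [generate_catalog].
#' @param max_tries Retry cap for constraint satisfaction.
#' @return A tibble with one row per trial: `trial`, `condition`, `framing`,
#'   `pair_id`, `p1..p4` (product ids), `v1..v4` (their ratings),
#'   `ov_target`, `ov`, `rv`.
#' @export
generate_session <- function(design, catalog, max_tries = 50) {
  stopifnot(inherits(design, "design_spec"))
  n_cond <- length(design$conditions)
  stopifnot(n_cond == 2)
  n_pairs <- design$trials_per_condition
  n_trials <- n_pairs * n_cond
  if (nrow(catalog) < ceiling(4 * n_trials / 3)) {
    stop("catalog too small: need at least ", ceiling(4 * n_trials / 3),
         " products for ", n_trials, " trials", call. = FALSE)
  }

  # target value sets, one per pair, shared by both conditions
  targets <- dplyr::bind_rows(lapply(seq_len(n_pairs),
                                     function(i) generate_choice_set()))

  # balanced random interleaving of conditions; pairs appear once per
  # condition, in random order within condition
  ord <- data.frame(
    pair_id = c(sample(n_pairs), sample(n_pairs)),
    condition = rep(design$conditions, each = n_pairs)
  )
  ord <- ord[sample(n_trials), ]

  for (attempt in seq_len(max_tries)) {
    sess <- realize_session(targets, ord, catalog)
    if (!is.null(sess)) {
      sess$trial <- seq_len(n_trials)
      sess$framing <- design$framing
      sess <- add_value_summaries(sess)
      check_session_constraints(sess, error = TRUE)
      return(sess[, c("trial", "condition", "framing", "pair_id",
                      paste0("p", 1:4), paste0("v", 1:4), "ov_target",
                      "ov", "rv")])
    }
    # reshuffle the interleaving and try again
    ord <- ord[sample(n_trials), ]
  }
  stop("session generation failed to satisfy design constraints after ",
       max_tries, " attempts; enlarge the catalog", call. = FALSE)
}

# Greedy product assignment under the three session constraints; returns
# NULL when a trial cannot be completed so the caller can reshuffle.
realize_session <- function(targets, ord, catalog) {
  n_trials <- nrow(ord)
  use_count <- integer(nrow(catalog))
  seen_sets <- character(0)
  prev <- integer(0)
  rows <- vector("list", n_trials)
  ratings <- catalog$rating
  for (t in seq_len(n_trials)) {
    tgt <- as.numeric(targets[ord$pair_id[t], paste0("v", 1:4)])
    chosen <- integer(0)
    for (v in tgt) {
      ok <- which(use_count < 3L)
      ok <- setdiff(ok, c(prev, chosen))
      if (!length(ok)) return(NULL)
      pick <- ok[which.min(abs(ratings[ok] - v))]
      chosen <- c(chosen, pick)
    }
    key <- paste(sort(chosen), collapse = "-")
    if (key %in% seen_sets) {
      # swap the last slot for the next-nearest admissible product
      ok <- setdiff(which(use_count < 3L), c(prev, chosen))
      if (!length(ok)) return(NULL)
      alt <- ok[order(abs(ratings[ok] - tgt[4]))]
      done <- FALSE
      for (p in alt) {
        cand <- c(chosen[1:3], p)
        k2 <- paste(sort(cand), collapse = "-")
        if (!k2 %in% seen_sets) {
          chosen <- cand
          key <- k2
          done <- TRUE
          break
        }
      }
      if (!done) return(NULL)
    }
    seen_sets <- c(seen_sets, key)
    use_count[chosen] <- use_count[chosen] + 1L
    prev <- chosen
    row <- as.list(c(chosen, ratings[chosen]))
    names(row) <- c(paste0("p", 1:4), paste0("v", 1:4))
    row$pair_id <- ord$pair_id[t]
    row$condition <- ord$condition[t]
    row$ov_target <- targets$ov_target[ord$pair_id[t]]
    rows[[t]] <- tibble::as_tibble(row)
  }
  dplyr::bind_rows(rows)
}

#' Verify the session design constraints
#'
#' Checks that (1) no product appears more than 3 times, (2) no product
#' appears on two consecutive trials, and (3) no two trials display the
#' same four products.
#'
#' @param session A session tibble from [generate_session] (needs `p1..p4`
#'   in trial order).
#' @param error Throw on violation instead of returning `FALSE`?
#' @return `TRUE` invisibly when all constraints hold, otherwise `FALSE`
#'   (or an error), with a `violations` attribute naming the failures.
#' @export
check_session_constraints <- function(session, error = FALSE) {
  pm <- as.matrix(session[, paste0("p", 1:4)])
  viol <- character(0)
  if (max(table(as.vector(pm))) > 3) {
    viol <- c(viol, "a product appears more than 3 times")
  }
  if (nrow(pm) > 1) {
    overlap <- vapply(seq_len(nrow(pm) - 1), function(i) {
      length(intersect(pm[i, ], pm[i + 1, ])) > 0
    }, logical(1))
    if (any(overlap)) {
      viol <- c(viol, "a product appears on two consecutive trials")
    }
  }
  keys <- apply(pm, 1, function(r) paste(sort(r), collapse = "-"))
  if (anyDuplicated(keys)) viol <- c(viol, "duplicate four-product set")
  ok <- length(viol) == 0
  if (!ok && error) {
    stop("session constraint violation: ", paste(viol, collapse = "; "),
         call. = FALSE)
  }
  structure(invisible(ok), violations = viol)
}

#' Fixed evaluation grid of choice sets for model identification
#'
#' Deterministic sets spanning overall and relative value: each set has a
#' single best option at `ov + 0.75 rv` and three equal remaining options at
#' `ov - 0.25 rv`, so the set mean is exactly `ov` and the selection-framing
#' relative value exactly `rv`.
#'
#' @param ov,rv Grid values; all implied ratings must stay in \[0, 10\].
#' @return A tibble of choice sets with `set_id`, `v1..v4`, `ov`, `rv`,
#'   `framing = "selection"`.
#' @export
eval_choice_sets <- function(ov = c(2, 4, 6, 8), rv = c(0.5, 1.5, 2.5)) {
  grid <- tidyr::expand_grid(ov = ov, rv = rv)
  best <- grid$ov + 0.75 * grid$rv
  rest <- grid$ov - 0.25 * grid$rv
  if (any(best > 10) || any(rest < 0)) {
    stop("ov/rv grid implies ratings outside [0, 10]", call. = FALSE)
  }
  tibble::tibble(set_id = seq_len(nrow(grid)), v1 = best, v2 = rest,
                 v3 = rest, v4 = rest, ov = grid$ov, rv = grid$rv,
                 framing = "selection")
}
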
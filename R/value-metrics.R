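#' Scalar value metrics for four-option choice sets
#'
#' A choice set is four product ratings on a 0--10 liking scale. Its
#' *overall value* (OV) is the mean rating; its *relative value* (RV) is a
#' framing-dependent difficulty index: under a selection framing, the gap
#' between the best option and the mean of the other three; under a removal
#' framing, the absolute gap between the worst option and the mean of the
#' other three. Higher RV means an easier choice in both framings.
#'
#' @param values Numeric vector of exactly four ratings, each in \[0, 10\].
#' @param framing Either `"selection"` or `"removal"`.
#' @return A single number: the mean rating for `overall_value()`, the
#'   framing-relevant value gap (always non-negative) for `relative_value()`.
#' @examples
#' overall_value(c(8, 4, 4, 4))           # 5
#' relative_value(c(8, 4, 4, 4))          # 4, selection framing
#' relative_value(c(2, 6, 6, 6), "removal") # 4
#' @export
overall_value <- function(values) {
  check_choice_values(values)
  mean(values)
}

#' @rdname overall_value
#' @export
relative_value <- function(values, framing = c("selection", "removal")) {
  check_choice_values(values)
  framing <- match.arg(framing)
  if (framing == "selection") {
    i <- which.max(values)
    values[i] - mean(values[-i])
  } else {
    i <- which.min(values)
    abs(values[i] - mean(values[-i]))
  }
}

check_choice_values <- function(values) {
  if (!is.numeric(values) || length(values) != 4L) {
    stop("a choice set must contain exactly 4 numeric ratings, got ",
         length(values), call. = FALSE)
  }
  if (anyNA(values) || any(values < 0 | values > 10)) {
    stop("choice-set ratings must lie in [0, 10]", call. = FALSE)
  }
  invisible(values)
}

#' Reward rate of a single response
#'
#' The value of the chosen item divided by the time taken to choose it, a
#' per-second measure of how productive the deliberation was.
#'
#' @param chosen_value Rating of the chosen item (0--10 scale).
#' @param rt Response time in seconds; must be strictly positive.
#' @return `chosen_value / rt`, in rating units per second.
#' @examples
#' reward_rate(6, 2) # 3
#' @export
reward_rate <- function(chosen_value, rt) {
  if (any(!is.finite(rt)) || any(rt <= 0)) {
    stop("reward rate requires a strictly positive response time",
         call. = FALSE)
  }
  chosen_value / rt
}

#' Accuracy of a first choice
#'
#' A selection is accurate when the highest-rated option was picked; a
#' removal is accurate when the lowest-rated option was dropped. If several
#' options tie at the framing-relevant extreme, picking any of them counts
#' as accurate.
#'
#' @param choice_index Index (1--4) of the option acted on.
#' @inheritParams overall_value
#' @return Logical flag.
#' @export
is_accurate <- function(choice_index, values,
                        framing = c("selection", "removal")) {
  check_choice_values(values)
  framing <- match.arg(framing)
  if (length(choice_index) != 1L || is.na(choice_index) ||
      !choice_index %in% 1:4) {
    stop("choice_index must be a single integer in 1..4", call. = FALSE)
  }
  extreme <- if (framing == "selection") max(values) else min(values)
  values[choice_index] == extreme
}

#' Successive-differences contrast for a two-level factor
#'
#' Codes two condition labels as -0.5 and +0.5 so that, in a balanced
#' design, the model intercept estimates the grand mean (the unweighted
#' average of the two condition means) and the slope estimates the
#' between-condition difference.
#'
#' Levels are ordered by `level_order()` conventions: `exclusive` before
#' `inclusive` and `low_urgency` before `high_urgency`, otherwise
#' alphabetically; the second level gets +0.5.
#'
#' @param levels Character vector of exactly two condition labels.
#' @return Named numeric vector of contrast codes.
#' @examples
#' condition_contrast(c("exclusive", "inclusive"))
#' @export
condition_contrast <- function(levels) {
  levels <- unique(as.character(levels))
  if (length(levels) != 2L) {
    stop("successive-differences contrast supports exactly 2 levels, got ",
         length(levels), call. = FALSE)
  }
  ord <- level_order(levels)
  stats::setNames(c(-0.5, 0.5), ord)
}

# Canonical ordering of condition labels: the baseline (exclusive /
# low-urgency) level first so the contrast's + pole is the manipulated one.
level_order <- function(levels) {
  canonical <- c("exclusive", "inclusive", "low_urgency", "high_urgency")
  known <- intersect(canonical, levels)
  c(known, sort(setdiff(levels, canonical)))
}

#' Orthogonal polynomial design columns for overall value
#'
#' Builds degree-1 and degree-2 polynomial columns of `x` that are mutually
#' orthogonal, orthogonal to the constant column, and normalised to unit
#' length, so linear and quadratic (U-shape) effects can be estimated
#' without collinearity. Columns are computed on the analysed sample, as is
#' standard for `stats::poly()`.
#'
#' @param x Numeric vector with at least 3 distinct values.
#' @param degree Polynomial degree; only 2 is supported.
#' @return A tibble with columns `lin` and `quad`.
#' @export
orthogonal_poly <- function(x, degree = 2) {
  if (degree != 2) stop("only degree = 2 is supported", call. = FALSE)
  if (length(unique(x)) < 3L) {
    stop("orthogonal polynomials need at least 3 distinct values; ",
         "predictor is (near-)constant", call. = FALSE)
  }
  p <- stats::poly(x, degree = 2)
  tibble::tibble(lin = p[, 1], quad = p[, 2])
}

#' Add value summaries to a trial table
#'
#' Convenience verb that appends `ov` (overall value) and `rv` (relative
#' value, using each row's `framing`) columns to a trial table holding
#' option ratings in `v1..v4`.
#'
#' @param trials A data frame with columns `v1`, `v2`, `v3`, `v4` and
#'   optionally `framing` (defaults to selection).
#' @return The input as a tibble with `ov` and `rv` columns added.
#' @export
add_value_summaries <- function(trials) {
  trials <- tibble::as_tibble(trials)
  need <- paste0("v", 1:4)
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(trials[, need])
  framing <- if ("framing" %in% names(trials)) {
    as.character(trials$framing)
  } else {
    rep("selection", nrow(trials))
  }
  trials$ov <- rowMeans(vals)
  trials$rv <- vapply(seq_len(nrow(vals)), function(i) {
    relative_value(vals[i, ], framing[i])
  }, numeric(1))
  trials
}
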
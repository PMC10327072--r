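#' Parameters of the collapsing-bound Leaky Competing Accumulator
#'
#' The model integrates four option-specific accumulators by
#' Euler--Maruyama:
#' \deqn{dy_i = (-k y_i - k m \sum_{j \ne i} y_j + g V_i)\,dt + c\sqrt{dt}\,\epsilon_i}
#' with per-step rectification at zero, starting from \eqn{y(0) = 0}. A
#' response is emitted the first time any accumulator reaches the decision
#' boundary, which starts at `a` and collapses exponentially at rate `beta`
#' (`a * exp(-beta * t)`); `beta = 0` recovers a fixed bound. Time is in
#' arbitrary simulation units (defaults put typical first-passage times in
#' the 2--3 range, so they read naturally as seconds).
#'
#' @param k Leak (decay) rate, per unit time; `>= 0`.
#' @param m Mutual inhibition expressed as a ratio to the leak; `>= 0`.
#'   Lowering `m` is the model's operationalisation of choice inclusivity.
#' @param g Input gain applied to the option ratings; `> 0`.
#' @param c Noise scale: increments are `c * sqrt(dt)`-scaled standard
#'   normals; `>= 0`.
#' @param a Initial boundary height; `> 0`. Urgency manipulations lower `a`
#'   and/or raise `beta`.
#' @param beta Boundary collapse rate, per unit time; `>= 0`.
#' @param dt Integration step; must allow at least 100 steps before `t_max`.
#' @param t_max Simulation horizon; trials with no crossing by `t_max` are
#'   recorded as omissions.
#' @param collapse `"exponential"` (default) or `"linear"`
#'   (`max(a - beta t, 0)`), selectable for sensitivity checks.
#' @return An object of class `lca_params`.
#' @examples
#' lca_params(m = 0.4)
#' @export
lca_params <- function(k = 1, m = 0.8, g = 0.25, c = 0.8, a = 3, beta = 0.25,
                       dt = 0.001, t_max = 10,
                       collapse = c("exponential", "linear")) {
  collapse <- match.arg(collapse)
  stopifnot(
    "k must be >= 0" = is.numeric(k) && length(k) == 1 && k >= 0,
    "m must be >= 0" = is.numeric(m) && length(m) == 1 && m >= 0,
    "g must be > 0" = is.numeric(g) && length(g) == 1 && g > 0,
    "c must be >= 0" = is.numeric(c) && length(c) == 1 && c >= 0,
    "a must be > 0" = is.numeric(a) && length(a) == 1 && a > 0,
    "beta must be >= 0" = is.numeric(beta) && length(beta) == 1 && beta >= 0,
    "dt must be > 0" = is.numeric(dt) && length(dt) == 1 && dt > 0,
    "t_max must be > 0" = is.numeric(t_max) && length(t_max) == 1 && t_max > 0
  )
  if (t_max / dt < 100) {
    stop("dt is too coarse: fewer than 100 integration steps before t_max",
         call. = FALSE)
  }
  structure(
    list(k = k, m = m, g = g, c = c, a = a, beta = beta, dt = dt,
         t_max = t_max, collapse = collapse),
    class = "lca_params"
  )
}

#' @export
print.lca_params <- function(x, ...) {
  cat("<lca_params> k=", x$k, " m=", x$m, " g=", x$g, " c=", x$c,
      " a=", x$a, " beta=", x$beta, " (", x$collapse, " collapse), dt=",
      x$dt, ", t_max=", x$t_max, "\n", sep = "")
  invisible(x)
}

# Modify a subset of fields, revalidating.
update_params <- function(params, ...) {
  new <- utils::modifyList(unclass(params), list(...))
  do.call(lca_params, new)
}

#' Decision boundary level at time t
#'
#' @param t Time(s), `>= 0`.
#' @param a Initial boundary height.
#' @param beta Collapse rate.
#' @param collapse `"exponential"` for `a * exp(-beta t)` or `"linear"` for
#'   `max(a - beta t, ~0)`.
#' @return Boundary level(s); strictly positive and non-increasing in `t`.
#' @export
boundary_level <- function(t, a, beta, collapse = c("exponential", "linear")) {
  collapse <- match.arg(collapse)
  stopifnot(all(t >= 0))
  if (collapse == "exponential") a * exp(-beta * t) else pmax(a - beta * t, 1e-12)
}

#' Simulate a single LCA trial
#'
#' Integrates one trial and (optionally) returns the full activation
#' trajectory. The noise matrix may be supplied explicitly, one column of
#' standard normal deviates per accumulator; with `m = 0` accumulator `i`
#' then depends only on its own column, so trajectories are bitwise
#' reproducible under common random numbers.
#'
#' @param params An [lca_params] object.
#' @param values Four option ratings in \[0, 10\].
#' @param noise Optional numeric matrix (`>= t_max/dt` rows, 4 columns) of
#'   standard normal deviates; drawn from the current RNG when `NULL`.
#' @param keep_trajectory Return the activation path?
#' @return A list with `rt`, `choice`, `omitted` and, if requested,
#'   `trajectory` (time step by accumulator matrix, row 1 = t of 0).
#' @export
simulate_trial <- function(params, values, noise = NULL,
                           keep_trajectory = FALSE) {
  stopifnot(inherits(params, "lca_params"))
  check_choice_values(values)
  n_steps <- ceiling(params$t_max / params$dt - 1e-9)
  if (is.null(noise)) {
    noise <- matrix(stats::rnorm(n_steps * 4), n_steps, 4)
  }
  out <- lca_run_trial_traj(values, params$k, params$m, params$g, params$c,
                            params$a, params$beta, params$dt, params$t_max,
                            params$collapse == "linear", noise)
  if (!keep_trajectory) out$trajectory <- NULL
  out
}

#' Simulate a batch of LCA trials over choice sets
#'
#' Runs `n_iter` independent trials of every choice set and returns one row
#' per (set, iteration). With the same `seed` and the same set order the
#' output is identical.
#'
#' @param params An [lca_params] object.
#' @param choice_sets Data frame with option ratings in `v1..v4`; optional
#'   `set_id`, `condition` and `framing` columns are carried through
#'   (`framing` additionally yields an `accuracy` column).
#' @param n_iter Iterations per choice set.
#' @param seed Optional integer seed; when supplied the RNG state is set
#'   locally and restored afterwards.
#' @return A tibble with columns `set_id`, `iter`, `v1..v4`, `ov`, `rv`
#'   (when framing is known), `rt`, `choice`, `omitted` and possibly
#'   `accuracy`. `rt` is in simulation time units.
#' @export
simulate_batch <- function(params, choice_sets, n_iter = 100, seed = NULL) {
  stopifnot(inherits(params, "lca_params"), n_iter >= 1)
  choice_sets <- tibble::as_tibble(choice_sets)
  if (nrow(choice_sets) == 0) {
    return(tibble::tibble(set_id = integer(), iter = integer(),
                          rt = double(), choice = integer(),
                          omitted = logical()))
  }
  need <- paste0("v", 1:4)
  miss <- setdiff(need, names(choice_sets))
  if (length(miss)) {
    stop("choice_sets is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"set_id" %in% names(choice_sets)) {
    choice_sets$set_id <- seq_len(nrow(choice_sets))
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  idx <- rep(seq_len(nrow(choice_sets)), each = n_iter)
  vals <- as.matrix(choice_sets[idx, need])
  res <- lca_run_batch(vals, params$k, params$m, params$g, params$c,
                       params$a, params$beta, params$dt, params$t_max,
                       params$collapse == "linear")
  out <- choice_sets[idx, intersect(c("set_id", "condition", "framing", need),
                                    names(choice_sets))]
  out$iter <- rep(seq_len(n_iter), times = nrow(choice_sets))
  out$rt <- res$rt
  out$choice <- res$choice
  out$omitted <- res$omitted
  out <- add_value_summaries(out)
  if ("framing" %in% names(out)) {
    vmat <- as.matrix(out[, need])
    out$accuracy <- vapply(seq_len(nrow(out)), function(i) {
      if (out$omitted[i]) return(NA)
      is_accurate(out$choice[i], vmat[i, ], out$framing[i])
    }, logical(1))
  }
  attr(out, "n_tie") <- res$n_tie
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Default condition-to-parameter mapping
#'
#' Encodes the model-based interpretation of the task manipulations:
#' inclusive choice lowers mutual inhibition `m` relative to exclusive
#' choice, while high urgency lowers the initial bound `a` and raises the
#' collapse rate `beta`, leaving `m` untouched.
#'
#' @param base An [lca_params] object used for the exclusive / low-urgency
#'   baseline.
#' @param m_inclusive Mutual-inhibition ratio in the inclusive condition.
#' @param a_urgent,beta_urgent Boundary parameters in the high-urgency
#'   condition.
#' @return Named list of `lca_params`, one per condition label.
#' @export
default_condition_params <- function(base = lca_params(),
                                     m_inclusive = 0.3,
                                     a_urgent = 1.8, beta_urgent = 0.55) {
  list(
    exclusive    = base,
    inclusive    = update_params(base, m = m_inclusive),
    low_urgency  = base,
    high_urgency = update_params(base, a = a_urgent, beta = beta_urgent)
  )
}
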
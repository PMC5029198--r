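# Transformed up-down staircase in integer signal-element units.
# 3-down/1-up with step halving at reversals tracks the level where
# p^3 = 1/2, i.e. p ~ 0.7937 correct.

#' Staircase configuration
#'
#' Levels and steps are expressed in whole signal elements (coherence is
#' derived as `100 * level / total_elements`). The staircase starts at
#' ceiling (all elements signal) with an initial step equal to the total
#' element count; the step halves (integer halving, floor
#' `step_floor_elements`) at every reversal; the run terminates when
#' `required_reversals_at_floor` reversals have occurred at the floor step
#' size.
#'
#' @param total_elements Total element count (200 dots or 50 bars).
#' @param n_down Consecutive correct responses required to lower the level.
#' @param n_up Consecutive errors required to raise the level.
#' @param initial_level_elements Starting level; defaults to
#'   `total_elements` (100% coherence), guaranteeing early correct
#'   responses and a defined first descent.
#' @param initial_step_elements Starting step size; defaults to
#'   `total_elements`.
#' @param step_floor_elements Smallest step size (1 element).
#' @param required_reversals_at_floor Floor-step reversals needed to
#'   terminate (6).
#' @param max_trials Non-termination guard; [run_staircase()] aborts with a
#'   diagnostic beyond this many trials.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(total_elements = 200L, n_down = 3L, n_up = 1L,
                             initial_level_elements = total_elements,
                             initial_step_elements = total_elements,
                             step_floor_elements = 1L,
                             required_reversals_at_floor = 6L,
                             max_trials = 10000L) {
  total_elements <- as.integer(total_elements)
  if (total_elements <= 0L) stop("total_elements must be positive",
                                 call. = FALSE)
  if (n_down < 1L || n_up < 1L) stop("n_down and n_up must be >= 1",
                                     call. = FALSE)
  if (initial_step_elements > total_elements) {
    stop("initial step cannot exceed the total element count",
         call. = FALSE)
  }
  if (step_floor_elements < 1L) stop("step floor must be >= 1",
                                     call. = FALSE)
  if (initial_level_elements < 0L ||
      initial_level_elements > total_elements) {
    stop("initial level must lie in [0, total_elements]", call. = FALSE)
  }
  structure(
    list(total_elements = total_elements,
         n_down = as.integer(n_down), n_up = as.integer(n_up),
         initial_level_elements = as.integer(initial_level_elements),
         initial_step_elements = as.integer(initial_step_elements),
         step_floor_elements = as.integer(step_floor_elements),
         required_reversals_at_floor =
           as.integer(required_reversals_at_floor),
         max_trials = as.integer(max_trials)),
    class = "staircase_config")
}

#' Create a fresh staircase state
#'
#' @param config A [staircase_config()].
#' @return An object of class `staircase_state`. Fields: current `level`
#'   and `step` (elements), run counters, `last_move` (+1/-1/0 = none),
#'   `reversal_levels` and `reversal_steps` (step size in force when each
#'   reversal occurred), the trial log (`trial_levels`, `trial_steps`,
#'   `trial_correct`) and the `terminated` flag.
#' @export
new_staircase <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(
    list(level = config$initial_level_elements,
         step = config$initial_step_elements,
         n_correct = 0L, n_incorrect = 0L, last_move = 0L,
         reversal_levels = integer(0), reversal_steps = integer(0),
         trial_levels = integer(0), trial_steps = integer(0),
         trial_correct = logical(0), terminated = FALSE),
    class = "staircase_state")
}

#' Advance a staircase by one trial
#'
#' Applies the transformed up-down rule: any completed run of `n_up` errors
#' raises the level by the current step; a completed run of `n_down`
#' consecutive correct responses lowers it. A movement whose direction is
#' opposite to the previous movement records a reversal at the pre-move
#' level and halves the step (`max(floor, step %/% 2)`); the move itself is
#' then taken with the halved step. Levels are clamped to
#' `[0, total_elements]`; a clamped move only counts as a reversal if its
#' intended direction actually changed sign. Termination is checked after
#' each reversal.
#'
#' @param state A non-terminated [new_staircase()] state.
#' @param config The matching [staircase_config()].
#' @param correct Logical response for the current trial.
#' @return The updated `staircase_state`.
#' @export
update_staircase <- function(state, config, correct) {
  stopifnot(inherits(state, "staircase_state"),
            inherits(config, "staircase_config"))
  if (state$terminated) {
    stop("staircase already terminated", call. = FALSE)
  }
  state$trial_levels <- c(state$trial_levels, state$level)
  state$trial_steps <- c(state$trial_steps, state$step)
  state$trial_correct <- c(state$trial_correct, isTRUE(correct))
  move <- 0L
  if (isTRUE(correct)) {
    state$n_correct <- state$n_correct + 1L
    state$n_incorrect <- 0L
    if (state$n_correct >= config$n_down) {
      move <- -1L
      state$n_correct <- 0L
    }
  } else {
    state$n_incorrect <- state$n_incorrect + 1L
    state$n_correct <- 0L
    if (state$n_incorrect >= config$n_up) {
      move <- 1L
      state$n_incorrect <- 0L
    }
  }
  if (move != 0L) {
    if (state$last_move != 0L && move != state$last_move) {
      state$reversal_levels <- c(state$reversal_levels, state$level)
      state$reversal_steps <- c(state$reversal_steps, state$step)
      state$step <- max(config$step_floor_elements, state$step %/% 2L)
      if (sum(state$reversal_steps <= config$step_floor_elements) >=
          config$required_reversals_at_floor) {
        state$terminated <- TRUE
      }
    }
    state$last_move <- move
    if (!state$terminated) {
      state$level <- clamp(state$level + move * state$step, 0L,
                           config$total_elements)
    }
  }
  state
}

#' Threshold estimate from a terminated staircase
#'
#' The arithmetic mean of the last `n_reversals` reversal levels, expressed
#' as a coherence percentage. Under the default termination rule every
#' late reversal occurs at the floor step size, so the "last six overall"
#' and "the six floor-step reversals" readings coincide; `use = "floor"`
#' restricts explicitly to floor-step reversals for configurations where
#' they could differ.
#'
#' @param state A terminated `staircase_state`.
#' @param config The matching [staircase_config()].
#' @param use `"last"` (last reversals overall, default) or `"floor"`
#'   (reversals recorded at the floor step only).
#' @param n_reversals Number of reversals averaged (6).
#' @return Coherence threshold percentage.
#' @export
estimate_threshold <- function(state, config, use = c("last", "floor"),
                               n_reversals = 6L) {
  stopifnot(inherits(state, "staircase_state"))
  use <- match.arg(use)
  if (!state$terminated) {
    stop("threshold requested before staircase termination", call. = FALSE)
  }
  levels <- state$reversal_levels
  if (use == "floor") {
    levels <- levels[state$reversal_steps <= config$step_floor_elements]
  }
  levels <- utils::tail(levels, n_reversals)
  100 * mean(levels) / config$total_elements
}

#' Run one adaptive staircase to termination
#'
#' The observer can be a [psychometric_observer()] (responses are Bernoulli
#' draws at the coherence implied by the current level), a
#' [stimulus_observer()] (a full stimulus is generated on every trial with
#' a random signal direction and the decision is scored against it), or a
#' plain function `f(coherence_pct) -> logical` for deterministic testing.
#'
#' @param observer Response model (see Details).
#' @param config A [staircase_config()].
#' @param seed Optional integer seed.
#' @param geometry,elements Stimulus parameters, used only with a
#'   [stimulus_observer()]. Defaults follow the observer's task kind
#'   (200 dots, or 50 bars for `bar_motion`).
#' @return A terminated `staircase_state`.
#' @export
run_staircase <- function(observer, config, seed = NULL,
                          geometry = display_geometry(), elements = NULL) {
  stopifnot(inherits(config, "staircase_config"))
  with_seed(seed, {
    state <- new_staircase(config)
    respond <- make_responder(observer, config, geometry, elements)
    trials <- 0L
    while (!state$terminated) {
      trials <- trials + 1L
      if (trials > config$max_trials) {
        stop("staircase failed to terminate within ", config$max_trials,
             " trials (level ", state$level, ", ",
             length(state$reversal_levels), " reversals)", call. = FALSE)
      }
      coherence <- 100 * state$level / config$total_elements
      state <- update_staircase(state, config, respond(coherence))
    }
    state
  })
}

make_responder <- function(observer, config, geometry, elements) {
  if (inherits(observer, "psychometric_observer")) {
    function(coherence) {
      stats::runif(1) < prob_correct(observer, coherence)
    }
  } else if (inherits(observer, "stimulus_observer")) {
    task <- observer$task_kind
    if (is.null(elements)) {
      elements <- if (task == "bar_motion") element_spec("bar")
                  else element_spec("dot")
    }
    alternatives <- if (task %in% c("rdk_motion", "bar_motion")) {
      c("up", "down")
    } else {
      c("vertical", "horizontal")
    }
    generator <- switch(task,
                        rdk_motion = generate_rdk_sequence,
                        bar_motion = generate_bar_sequence,
                        static_form = collapse_to_static_form,
                        temporal_form = generate_temporal_form_sequence)
    function(coherence) {
      direction <- sample(alternatives, 1)
      spec <- coherence_spec(coherence, direction)
      stim <- generator(geometry, elements, spec)
      identical(stimulus_decision(observer, stim), direction)
    }
  } else if (is.function(observer)) {
    function(coherence) isTRUE(observer(coherence))
  } else {
    stop("unsupported observer type", call. = FALSE)
  }
}

#' Run a session of independent staircases
#'
#' The session threshold is the arithmetic mean of the per-staircase
#' estimates; at least four staircases are required.
#'
#' @inheritParams run_staircase
#' @param n_staircases Number of independent staircases (>= 4).
#' @param keep_states Keep the full per-staircase states in the result.
#' @param ... Passed on to [run_staircase()].
#' @return An object of class `session_result` with
#'   `staircase_thresholds`, `session_threshold_pct` and `n_staircases`.
#' @export
run_session <- function(observer, config, n_staircases = 4L, seed = NULL,
                        keep_states = FALSE, ...) {
  if (n_staircases < 4L) {
    stop("a session requires at least four staircases", call. = FALSE)
  }
  seeds <- if (is.null(seed)) vector("list", n_staircases)
           else as.list(spawn_seeds(seed, n_staircases))
  states <- lapply(seeds, function(s) run_staircase(observer, config,
                                                    seed = s, ...))
  thresholds <- vapply(states, estimate_threshold, numeric(1),
                       config = config)
  structure(
    list(staircase_thresholds = thresholds,
         session_threshold_pct = mean(thresholds),
         n_staircases = as.integer(n_staircases),
         states = if (keep_states) states else NULL),
    class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat("<session_result> ", x$n_staircases, " staircases; threshold ",
      format(x$session_threshold_pct, digits = 4), "% (per staircase: ",
      paste(format(x$staircase_thresholds, digits = 3), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Plot a staircase trajectory
#'
#' Trial level against trial number, with reversal levels marked.
#'
#' @param x A `staircase_state`.
#' @param ... Further arguments passed to [plot()].
#' @export
plot.staircase_state <- function(x, ...) {
  plot(seq_along(x$trial_levels), x$trial_levels, type = "s",
       xlab = "trial", ylab = "level (signal elements)", ...)
  rev_trials <- which(c(FALSE, diff(sign(diff(x$trial_levels))) != 0))
  points(rev_trials, x$trial_levels[rev_trials], pch = 1, col = 2)
  invisible(x)
}
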
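# Simulated decision-makers. Two kinds:
#  * psychometric_observer -- a Weibull-type psychometric function of
#    coherence, parameterised directly at the performance level the
#    staircase tracks (79.3% correct by default);
#  * stimulus_observer -- decides from the generated frame sequence itself
#    after adding positional internal noise, validating that the stimuli
#    carry the intended signal.

#' Psychometric observer
#'
#' Probability-correct model
#' \deqn{P(c) = \gamma + (1-\gamma-\lambda)\,(1 - e^{-(c/\alpha)^\beta})}
#' with guess rate \eqn{\gamma}, lapse rate \eqn{\lambda} and slope
#' \eqn{\beta}. The scale \eqn{\alpha} is solved so that
#' `P(threshold_pct)` equals `performance_level` exactly, i.e. the
#' threshold parameter is *at* the tracked performance level rather than at
#' the conventional Weibull alpha, so staircase recovery targets it
#' directly.
#'
#' @param threshold_pct Coherence (%) at which the observer performs at
#'   `performance_level`.
#' @param slope Weibull shape parameter (> 0). Unitless; thresholds are
#'   reported in the source literature but slopes are not, so this is a
#'   free parameter of the simulation. The default of 2 is in the shallow
#'   range typical of coherence-based direction/orientation judgements;
#'   much steeper functions make the staircase's trial-level accuracy sit
#'   visibly below the nominal tracked level (see the vignette).
#' @param guess_rate Chance performance (0.5 for two-alternative tasks).
#' @param lapse_rate Stimulus-independent error rate in \[0, 0.05\]. The
#'   non-zero default keeps ceiling behaviour realistic for near-ceiling
#'   tasks.
#' @param performance_level Probability correct defined as "threshold";
#'   0.793 matches the level tracked by the 3-down/1-up staircase.
#' @return An object of class `psychometric_observer`.
#' @examples
#' obs <- psychometric_observer(20)
#' prob_correct(obs, 20)   # 0.793 by construction
#' @export
psychometric_observer <- function(threshold_pct, slope = 2,
                                  guess_rate = 0.5, lapse_rate = 0.01,
                                  performance_level = 0.793) {
  if (threshold_pct <= 0 || threshold_pct > 100) {
    stop("threshold_pct must lie in (0, 100]", call. = FALSE)
  }
  if (slope <= 0) stop("slope must be positive", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate > 0.05) {
    stop("lapse_rate must lie in [0, 0.05]", call. = FALSE)
  }
  if (guess_rate < 0 || guess_rate >= 1) {
    stop("guess_rate must lie in [0, 1)", call. = FALSE)
  }
  q <- (performance_level - guess_rate) / (1 - guess_rate - lapse_rate)
  if (is.na(q) || q <= 0 || q >= 1) {
    stop("performance_level is not attainable with these guess/lapse rates",
         call. = FALSE)
  }
  alpha <- threshold_pct / (-log(1 - q))^(1 / slope)
  structure(
    list(threshold_pct = threshold_pct, slope = slope,
         guess_rate = guess_rate, lapse_rate = lapse_rate,
         performance_level = performance_level, alpha = alpha),
    class = "psychometric_observer")
}

#' @export
print.psychometric_observer <- function(x, ...) {
  cat("<psychometric_observer> threshold ", x$threshold_pct, "% at P = ",
      x$performance_level, ", slope ", x$slope, ", guess ", x$guess_rate,
      ", lapse ", x$lapse_rate, "\n", sep = "")
  invisible(x)
}

#' Probability of a correct response at a given coherence
#'
#' @param observer A [psychometric_observer()].
#' @param coherence_pct Coherence percentage(s) in \[0, 100\].
#' @return Probability (vectorised over `coherence_pct`).
#' @export
prob_correct <- function(observer, coherence_pct) {
  stopifnot(inherits(observer, "psychometric_observer"))
  if (any(is.na(coherence_pct)) || any(coherence_pct < 0) ||
      any(coherence_pct > 100)) {
    stop("coherence_pct must lie in [0, 100]", call. = FALSE)
  }
  g <- observer$guess_rate
  l <- observer$lapse_rate
  g + (1 - g - l) *
    (1 - exp(-(coherence_pct / observer$alpha)^observer$slope))
}

#' Simulate a single Bernoulli response
#'
#' @inheritParams prob_correct
#' @param seed Optional integer seed.
#' @return Logical: `TRUE` for a correct response.
#' @export
simulate_response <- function(observer, coherence_pct, seed = NULL) {
  p <- prob_correct(observer, coherence_pct)
  with_seed(seed, stats::runif(length(p)) < p)
}

#' Stimulus-driven observer
#'
#' Decides directly from a frame sequence after perturbing every element
#' position in every frame with isotropic Gaussian internal noise. Decision
#' rules: motion tasks take the sign of the summed (minimum-image) vertical
#' displacement; the static form task picks the axis with the greater
#' summed squared trail projection; the temporal form task picks the
#' midline split that maximises the across-halves difference in per-update
#' jitter-event counts.
#'
#' @param task_kind One of `"rdk_motion"`, `"bar_motion"`,
#'   `"static_form"`, `"temporal_form"`.
#' @param internal_noise_sd Positional noise SD in degrees.
#' @return An object of class `stimulus_observer`.
#' @export
stimulus_observer <- function(task_kind = c("rdk_motion", "bar_motion",
                                            "static_form", "temporal_form"),
                              internal_noise_sd = 0) {
  task_kind <- match.arg(task_kind)
  if (internal_noise_sd < 0) {
    stop("internal_noise_sd must be non-negative", call. = FALSE)
  }
  structure(list(task_kind = task_kind,
                 internal_noise_sd = internal_noise_sd),
            class = "stimulus_observer")
}

perturb_frames <- function(frames, sd) {
  if (sd <= 0) return(frames)
  lapply(frames, function(f) f + matrix(stats::rnorm(length(f), 0, sd),
                                        nrow(f), ncol(f)))
}

frame_displacements <- function(frames, w, h) {
  n_up <- length(frames) - 1L
  dx <- dy <- matrix(0, nrow(frames[[1]]), n_up)
  for (u in seq_len(n_up)) {
    dx[, u] <- unwrap_displacement(frames[[u + 1L]][, 1] -
                                     frames[[u]][, 1], w)
    dy[, u] <- unwrap_displacement(frames[[u + 1L]][, 2] -
                                     frames[[u]][, 2], h)
  }
  list(dx = dx, dy = dy)
}

#' Decision of a stimulus-driven observer
#'
#' @param observer A [stimulus_observer()] whose task matches the stimulus.
#' @param stim A `frame_seq` or `static_form_image`.
#' @param seed Optional integer seed for the internal noise (and tie
#'   breaks).
#' @return For motion tasks `"up"`/`"down"`; for form tasks
#'   `"vertical"`/`"horizontal"`.
#' @export
stimulus_decision <- function(observer, stim, seed = NULL) {
  stopifnot(inherits(observer, "stimulus_observer"))
  task <- if (inherits(stim, "static_form_image")) "static_form"
          else stim$task_kind
  if (!identical(task, observer$task_kind)) {
    stop("observer task kind does not match the stimulus", call. = FALSE)
  }
  w <- stim$geometry$window_width_deg
  h <- stim$geometry$window_height_deg
  with_seed(seed, {
    frames <- perturb_frames(stim$frames, observer$internal_noise_sd)
    disp <- frame_displacements(frames, w, h)
    switch(task,
      rdk_motion = ,
      bar_motion = {
        s <- sum(disp$dy)
        if (s == 0) sample(c("up", "down"), 1)
        else if (s > 0) "up" else "down"
      },
      static_form = {
        sv <- sum(disp$dy^2)
        sh <- sum(disp$dx^2)
        if (sv == sh) sample(c("vertical", "horizontal"), 1)
        else if (sv > sh) "vertical" else "horizontal"
      },
      temporal_form = {
        crit <- stim$displacement_deg / 2
        moved <- sqrt(disp$dx^2 + disp$dy^2) > crit
        score <- function(coord, extent) {
          s <- 0
          for (u in seq_len(ncol(moved))) {
            left <- frames[[u]][, coord] < extent / 2
            s <- s + abs(sum(moved[left, u]) - sum(moved[!left, u]))
          }
          s
        }
        sv <- score(1, w)   # vertical boundary splits on x
        sh <- score(2, h)
        if (sv == sh) sample(c("vertical", "horizontal"), 1)
        else if (sv > sh) "vertical" else "horizontal"
      })
  })
}
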
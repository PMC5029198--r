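# Stimulus generators: all four tasks are produced as abstract geometric
# frame sequences (element positions in degrees); no rendering is done.
# Elements leaving the window wrap toroidally, conserving density.

new_frame_seq <- function(frames, roles, task_kind, signal_direction,
                          spec, geometry, elements, extra = list()) {
  out <- c(list(frames = frames, roles = roles, task_kind = task_kind,
                signal_direction = signal_direction,
                coherence_pct = spec$coherence_pct,
                displacement_deg = spec$displacement_deg,
                n_images = spec$n_images,
                geometry = geometry, elements = elements),
           extra)
  class(out) <- "frame_seq"
  out
}

#' @export
print.frame_seq <- function(x, ...) {
  cat("<frame_seq>", x$task_kind, "\n")
  cat("  ", x$elements$count, " elements, ", x$n_images, " images, ",
      "coherence ", x$coherence_pct, "% (", x$signal_direction, ")\n",
      sep = "")
  invisible(x)
}

check_dot <- function(elements) {
  if (elements$kind != "dot") {
    stop("this task requires dot elements", call. = FALSE)
  }
}

motion_direction_vector <- function(direction, d) {
  switch(direction,
         up = c(0, d),
         down = c(0, -d),
         stop("motion tasks need signal_direction 'up' or 'down'",
              call. = FALSE))
}

#' Generate a random-dot kinematogram sequence
#'
#' Builds an `n_images`-frame dot sequence. On each update a fresh random
#' subset of `round(coherence/100 * n)` dots is labelled signal and
#' displaced by `displacement_deg` in the signal direction; the remaining
#' noise dots are displaced by the same magnitude in an independently
#' uniform random direction, so signal and noise dots share a common speed.
#' Signal/noise assignment is re-randomised on every update, limiting any
#' single dot's coherent trajectory in time. Initial positions are uniform
#' in the window and positions wrap toroidally.
#'
#' @param geometry A [display_geometry()].
#' @param elements An [element_spec()] with `kind = "dot"`.
#' @param spec A [coherence_spec()] with an up/down signal direction.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A `frame_seq`: `frames` is a list of n x 2 position matrices
#'   (degrees), `roles` an n x (n_images - 1) matrix of
#'   `"signal"`/`"noise"` labels per update.
#' @examples
#' seq <- generate_rdk_sequence(spec = coherence_spec(50, "up"), seed = 1)
#' empirical_coherence(seq)
#' @export
generate_rdk_sequence <- function(geometry = display_geometry(),
                                  elements = element_spec("dot"),
                                  spec, seed = NULL) {
  check_dot(elements)
  n <- elements$count
  k <- signal_count(spec$coherence_pct, n)
  d <- spec$displacement_deg
  sig_vec <- motion_direction_vector(spec$signal_direction, d)
  w <- geometry$window_width_deg
  h <- geometry$window_height_deg
  with_seed(seed, {
    pos <- cbind(stats::runif(n, 0, w), stats::runif(n, 0, h))
    frames <- vector("list", spec$n_images)
    frames[[1]] <- pos
    roles <- matrix("noise", n, spec$n_images - 1L)
    for (u in seq_len(spec$n_images - 1L)) {
      sig <- if (k > 0L) sample.int(n, k) else integer(0)
      roles[sig, u] <- "signal"
      disp <- matrix(0, n, 2)
      if (length(sig)) disp[sig, ] <- rep(sig_vec, each = length(sig))
      noise <- setdiff(seq_len(n), sig)
      if (length(noise)) {
        theta <- stats::runif(length(noise), 0, 2 * pi)
        disp[noise, ] <- d * cbind(cos(theta), sin(theta))
      }
      pos <- cbind(wrap_position(pos[, 1] + disp[, 1], w),
                   wrap_position(pos[, 2] + disp[, 2], h))
      frames[[u + 1L]] <- pos
    }
    new_frame_seq(frames, roles, "rdk_motion", spec$signal_direction,
                  spec, geometry, elements)
  })
}

#' Generate a spatially one-dimensional bar-motion sequence
#'
#' As [generate_rdk_sequence()] but with full-width horizontal bars whose
#' motion is restricted to the vertical axis: signal bars move in the
#' common direction, noise bars choose up or down with probability 1/2 on
#' each update. All bars therefore share an identical speed.
#'
#' @inheritParams generate_rdk_sequence
#' @param elements An [element_spec()] with `kind = "bar"`.
#' @return A `frame_seq` of task kind `"bar_motion"`. Bar positions are
#'   stored as n x 2 matrices whose x column is the fixed bar centre.
#' @export
generate_bar_sequence <- function(geometry = display_geometry(),
                                  elements = element_spec("bar"),
                                  spec, seed = NULL) {
  if (elements$kind != "bar") {
    stop("this task requires bar elements", call. = FALSE)
  }
  n <- elements$count
  k <- signal_count(spec$coherence_pct, n)
  d <- spec$displacement_deg
  sig_dy <- motion_direction_vector(spec$signal_direction, d)[2]
  w <- geometry$window_width_deg
  h <- geometry$window_height_deg
  with_seed(seed, {
    y <- stats::runif(n, 0, h)
    frames <- vector("list", spec$n_images)
    frames[[1]] <- cbind(rep(w / 2, n), y)
    roles <- matrix("noise", n, spec$n_images - 1L)
    for (u in seq_len(spec$n_images - 1L)) {
      sig <- if (k > 0L) sample.int(n, k) else integer(0)
      roles[sig, u] <- "signal"
      dy <- sample(c(-d, d), n, replace = TRUE)
      dy[sig] <- sig_dy
      y <- wrap_position(y + dy, h)
      frames[[u + 1L]] <- cbind(rep(w / 2, n), y)
    }
    new_frame_seq(frames, roles, "bar_motion", spec$signal_direction,
                  spec, geometry, elements)
  })
}

#' Build a static global-form image by superimposing a frame sequence
#'
#' Generates an `n_images`-frame dot sequence in which signal/noise
#' assignment is fixed for the whole sequence: each signal dot steps
#' consistently along the signal axis (a random sign per dot), producing an
#' `n_images`-dot collinear streak of extent
#' `(n_images - 1) * displacement_deg` once the frames are superimposed,
#' while noise dots trace random walks. The fixed assignment differs from
#' the per-update re-randomisation of the motion tasks and is what yields
#' localised streaks along a common axis.
#'
#' @inheritParams generate_rdk_sequence
#' @param spec A [coherence_spec()] whose `signal_direction` is
#'   `"vertical"` or `"horizontal"` (the streak axis).
#' @return An object of class `static_form_image` with `positions` (an
#'   `n_images * n` x 2 matrix of superimposed dot positions), per-dot
#'   `roles`, `signal_axis`, and the underlying `frames`.
#' @export
collapse_to_static_form <- function(geometry = display_geometry(),
                                    elements = element_spec("dot"),
                                    spec, seed = NULL) {
  check_dot(elements)
  if (!spec$signal_direction %in% c("vertical", "horizontal")) {
    stop("form tasks need signal_direction 'vertical' or 'horizontal'",
         call. = FALSE)
  }
  n <- elements$count
  k <- signal_count(spec$coherence_pct, n)
  d <- spec$displacement_deg
  w <- geometry$window_width_deg
  h <- geometry$window_height_deg
  with_seed(seed, {
    pos <- cbind(stats::runif(n, 0, w), stats::runif(n, 0, h))
    sig <- if (k > 0L) sample.int(n, k) else integer(0)
    roles <- rep("noise", n)
    roles[sig] <- "signal"
    sgn <- sample(c(-1, 1), n, replace = TRUE)  # fixed per-dot streak sign
    frames <- vector("list", spec$n_images)
    frames[[1]] <- pos
    for (u in seq_len(spec$n_images - 1L)) {
      disp <- matrix(0, n, 2)
      theta <- stats::runif(n, 0, 2 * pi)
      disp[, 1] <- d * cos(theta)
      disp[, 2] <- d * sin(theta)
      if (length(sig)) {
        if (spec$signal_direction == "vertical") {
          disp[sig, 1] <- 0
          disp[sig, 2] <- sgn[sig] * d
        } else {
          disp[sig, 1] <- sgn[sig] * d
          disp[sig, 2] <- 0
        }
      }
      pos <- cbind(wrap_position(pos[, 1] + disp[, 1], w),
                   wrap_position(pos[, 2] + disp[, 2], h))
      frames[[u + 1L]] <- pos
    }
    structure(
      list(positions = do.call(rbind, frames), roles = roles,
           signal_axis = spec$signal_direction, frames = frames,
           task_kind = "static_form", coherence_pct = spec$coherence_pct,
           displacement_deg = d, n_images = spec$n_images,
           geometry = geometry, elements = elements),
      class = "static_form_image")
  })
}

#' @export
print.static_form_image <- function(x, ...) {
  cat("<static_form_image> ", nrow(x$positions), " positions (",
      x$elements$count, " dots x ", x$n_images, " frames), axis ",
      x$signal_axis, ", coherence ", x$coherence_pct, "%\n", sep = "")
  invisible(x)
}

#' Generate a temporally-defined global-form sequence
#'
#' The dots are split into two fixed populations of equal size that are
#' jittered in strict alternation at the update rate: on odd updates every
#' dot of population 1 is displaced by `displacement_deg` in a random
#' direction while population 2 is static, and conversely on even updates.
#' A fraction `coherence/100` of each population (whole-element quantised)
#' is placed on its own side of the midline boundary -- population 1 on the
#' first side, population 2 on the other -- while the remaining dots are
#' placed uniformly over the whole window. The boundary is therefore
#' carried purely by the spatial arrangement of jitter timing; no single
#' frame contains any orientation cue.
#'
#' @inheritParams collapse_to_static_form
#' @param spec A [coherence_spec()] whose `signal_direction` gives the
#'   boundary orientation (`"vertical"` = left/right split,
#'   `"horizontal"` = bottom/top split).
#' @return A `frame_seq` of task kind `"temporal_form"` with an extra
#'   `population` vector (1 or 2 per dot). `roles` marks the
#'   boundary-constrained dots as `"signal"` on every update.
#' @export
generate_temporal_form_sequence <- function(geometry = display_geometry(),
                                            elements = element_spec("dot"),
                                            spec, seed = NULL) {
  check_dot(elements)
  if (!spec$signal_direction %in% c("vertical", "horizontal")) {
    stop("form tasks need signal_direction 'vertical' or 'horizontal'",
         call. = FALSE)
  }
  n <- elements$count
  if (n %% 2L != 0L) {
    stop("temporal-form task needs an even element count", call. = FALSE)
  }
  half <- n %/% 2L
  k_half <- signal_count(spec$coherence_pct, half)
  d <- spec$displacement_deg
  w <- geometry$window_width_deg
  h <- geometry$window_height_deg
  with_seed(seed, {
    population <- rep(1:2, each = half)
    constrained <- c(sample.int(half, k_half),
                     half + sample.int(half, k_half))
    x <- stats::runif(n, 0, w)
    y <- stats::runif(n, 0, h)
    # place constrained dots on their population's side of the boundary
    for (i in constrained) {
      if (spec$signal_direction == "vertical") {
        x[i] <- if (population[i] == 1L) stats::runif(1, 0, w / 2)
                else stats::runif(1, w / 2, w)
      } else {
        y[i] <- if (population[i] == 1L) stats::runif(1, 0, h / 2)
                else stats::runif(1, h / 2, h)
      }
    }
    pos <- cbind(x, y)
    frames <- vector("list", spec$n_images)
    frames[[1]] <- pos
    roles <- matrix("noise", n, spec$n_images - 1L)
    roles[constrained, ] <- "signal"
    for (u in seq_len(spec$n_images - 1L)) {
      mover <- if (u %% 2L == 1L) 1L else 2L
      idx <- which(population == mover)
      theta <- stats::runif(length(idx), 0, 2 * pi)
      pos[idx, 1] <- wrap_position(pos[idx, 1] + d * cos(theta), w)
      pos[idx, 2] <- wrap_position(pos[idx, 2] + d * sin(theta), h)
      frames[[u + 1L]] <- pos
    }
    new_frame_seq(frames, roles, "temporal_form", spec$signal_direction,
                  spec, geometry, elements,
                  extra = list(population = population))
  })
}

#' Empirical coherence of a motion sequence
#'
#' Validation utility: the percentage of element displacements (pooled over
#' updates) that exactly equal the signal displacement vector. For dot
#' stimuli a noise dot matches the signal vector with probability zero, so
#' the value equals the quantised coherence; for bar stimuli noise bars
#' match with probability 1/2, so a zero-coherence sequence returns about
#' 50.
#'
#' @param seq A `frame_seq` from a motion task.
#' @param tol Numeric tolerance for displacement comparison.
#' @return Percentage in \[0, 100\].
#' @export
empirical_coherence <- function(seq, tol = 1e-9) {
  if (!inherits(seq, "frame_seq") ||
      !seq$task_kind %in% c("rdk_motion", "bar_motion")) {
    stop("empirical_coherence supports motion-task sequences only",
         call. = FALSE)
  }
  sig_vec <- motion_direction_vector(seq$signal_direction,
                                     seq$displacement_deg)
  w <- seq$geometry$window_width_deg
  h <- seq$geometry$window_height_deg
  fracs <- vapply(seq_len(seq$n_images - 1L), function(u) {
    dx <- unwrap_displacement(seq$frames[[u + 1L]][, 1] -
                                seq$frames[[u]][, 1], w)
    dy <- unwrap_displacement(seq$frames[[u + 1L]][, 2] -
                                seq$frames[[u]][, 2], h)
    mean(abs(dx - sig_vec[1]) < tol & abs(dy - sig_vec[2]) < tol)
  }, numeric(1))
  100 * mean(fracs)
}

#' Export a frame sequence as delimited text
#'
#' One row per element per frame: frame index, element id, x, y (degrees)
#' and the role of the update leading into the frame (`NA` for the first
#' frame). A small key-value header (lines starting `#`) records the task
#' kind, direction, coherence, displacement and window size so that
#' [read_frames()] can round-trip the sequence.
#'
#' @param seq A `frame_seq`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(seq, path) {
  stopifnot(inherits(seq, "frame_seq"))
  n <- seq$elements$count
  header <- c(
    paste("# task_kind:", seq$task_kind),
    paste("# signal_direction:", seq$signal_direction),
    paste("# coherence_pct:", format(seq$coherence_pct, digits = 15)),
    paste("# displacement_deg:", format(seq$displacement_deg, digits = 15)),
    paste("# window_deg:", seq$geometry$window_width_deg,
          seq$geometry$window_height_deg),
    paste("# element_kind:", seq$elements$kind))
  rows <- do.call(rbind, lapply(seq_len(seq$n_images), function(f) {
    data.frame(frame = f, element = seq_len(n),
               x_deg = seq$frames[[f]][, 1], y_deg = seq$frames[[f]][, 2],
               role = if (f == 1L) NA_character_ else seq$roles[, f - 1L])
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(rows, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a frame sequence written by [write_frames()]
#'
#' @param path File written by [write_frames()].
#' @return A `frame_seq`.
#' @export
read_frames <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    trimws(sub(paste0("^# ", key, ":"), "", ln))
  }
  task_kind <- get_field("task_kind")
  direction <- get_field("signal_direction")
  coherence <- as.numeric(get_field("coherence_pct"))
  displacement <- as.numeric(get_field("displacement_deg"))
  win <- as.numeric(strsplit(get_field("window_deg"), "\\s+")[[1]])
  kind <- get_field("element_kind")
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  n_images <- max(tab$frame)
  n <- max(tab$element)
  frames <- lapply(seq_len(n_images), function(f) {
    sub <- tab[tab$frame == f, ]
    sub <- sub[order(sub$element), ]
    cbind(sub$x_deg, sub$y_deg)
  })
  roles <- matrix("noise", n, n_images - 1L)
  for (f in 2:n_images) {
    sub <- tab[tab$frame == f, ]
    roles[sub$element[order(sub$element)], f - 1L] <-
      sub$role[order(sub$element)]
  }
  geometry <- display_geometry(window_width_deg = win[1],
                               window_height_deg = win[2])
  elements <- element_spec(kind, count = n)
  spec <- coherence_spec(coherence, direction,
                         displacement_deg = displacement,
                         n_images = n_images)
  new_frame_seq(frames, roles, task_kind, direction, spec, geometry,
                elements)
}
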
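#' Display geometry for stimulus generation
#'
#' Describes the abstract display that stimuli are generated on: a square
#' window (degrees of visual angle) with dark elements on a grey background,
#' refreshed at `refresh_hz` but updated (elements repositioned) at
#' `update_hz`. The update rate must divide the refresh rate evenly, so each
#' update is held for a whole number of refresh frames.
#'
#' @param window_width_deg,window_height_deg Window extent in degrees.
#' @param element_luminance,background_luminance Luminances in cd/m^2;
#'   retained as stimulus metadata (no photometric rendering is performed).
#' @param viewing_distance_cm Viewing distance in centimetres.
#' @param refresh_hz Monitor refresh rate in Hz.
#' @param update_hz Element update rate in Hz.
#' @return An object of class `display_geometry`.
#' @examples
#' geom <- display_geometry()
#' stimulus_duration(coherence_spec(50, "up"), geom)  # ~0.43 s
#' @export
display_geometry <- function(window_width_deg = 12, window_height_deg = 12,
                             element_luminance = 0.01,
                             background_luminance = 34,
                             viewing_distance_cm = 114,
                             refresh_hz = 75, update_hz = 18.75) {
  if (window_width_deg <= 0 || window_height_deg <= 0) {
    stop("window extents must be strictly positive", call. = FALSE)
  }
  if (viewing_distance_cm <= 0 || refresh_hz <= 0 || update_hz <= 0) {
    stop("distances and rates must be strictly positive", call. = FALSE)
  }
  ratio <- refresh_hz / update_hz
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("update_hz must divide refresh_hz evenly", call. = FALSE)
  }
  structure(
    list(window_width_deg = window_width_deg,
         window_height_deg = window_height_deg,
         element_luminance = element_luminance,
         background_luminance = background_luminance,
         viewing_distance_cm = viewing_distance_cm,
         refresh_hz = refresh_hz, update_hz = update_hz,
         frames_per_update = as.integer(round(ratio))),
    class = "display_geometry")
}

#' Element specification (dots or bars)
#'
#' @param kind `"dot"` (default 200 elements of diameter 0.12 deg) or
#'   `"bar"` (default 50 horizontal bars of 0.12 x 12 deg). Bar width equals
#'   the dot diameter by construction.
#' @param count Number of elements; defaults to 200 dots or 50 bars.
#' @param dot_diameter_deg Dot diameter in degrees.
#' @param bar_size_deg Bar width x length in degrees.
#' @return An object of class `element_spec`.
#' @export
element_spec <- function(kind = c("dot", "bar"), count = NULL,
                         dot_diameter_deg = 0.12,
                         bar_size_deg = c(0.12, 12)) {
  kind <- match.arg(kind)
  if (is.null(count)) count <- if (kind == "dot") 200L else 50L
  count <- as.integer(count)
  if (is.na(count) || count <= 0L) {
    stop("element count must be a positive integer", call. = FALSE)
  }
  if (abs(bar_size_deg[1] - dot_diameter_deg) > 1e-9) {
    stop("bar width must equal the dot diameter", call. = FALSE)
  }
  structure(
    list(kind = kind, count = count,
         dot_diameter_deg = dot_diameter_deg,
         bar_size_deg = bar_size_deg),
    class = "element_spec")
}

#' Coherence specification for one stimulus
#'
#' @param coherence_pct Requested coherence, a percentage in \[0, 100\].
#'   Signal counts are quantised to whole elements with
#'   [signal_count()]; the achievable coherence is `100 * k / n`.
#' @param signal_direction `"up"`/`"down"` for motion tasks,
#'   `"vertical"`/`"horizontal"` for form tasks (the streak or boundary
#'   axis).
#' @param displacement_deg Per-update displacement magnitude in degrees.
#' @param n_images Number of images in the sequence.
#' @return An object of class `coherence_spec`.
#' @export
coherence_spec <- function(coherence_pct,
                           signal_direction = c("up", "down",
                                                "vertical", "horizontal"),
                           displacement_deg = 0.12, n_images = 8) {
  if (!is.numeric(coherence_pct) || length(coherence_pct) != 1 ||
      is.na(coherence_pct) || coherence_pct < 0 || coherence_pct > 100) {
    stop("coherence_pct must be a single value in [0, 100]", call. = FALSE)
  }
  signal_direction <- match.arg(signal_direction)
  if (displacement_deg <= 0) {
    stop("displacement_deg must be strictly positive", call. = FALSE)
  }
  n_images <- as.integer(n_images)
  if (n_images < 2L) stop("n_images must be at least 2", call. = FALSE)
  structure(
    list(coherence_pct = coherence_pct, signal_direction = signal_direction,
         displacement_deg = displacement_deg, n_images = n_images),
    class = "coherence_spec")
}

#' Number of signal elements implied by a coherence percentage
#'
#' Coherence is quantised to whole elements: `round(coherence/100 * n)`.
#'
#' @param coherence_pct Coherence percentage in \[0, 100\].
#' @param n Total element count.
#' @return Integer signal count in \[0, n\].
#' @export
signal_count <- function(coherence_pct, n) {
  k <- as.integer(round(coherence_pct / 100 * n))
  clamp(k, 0L, as.integer(n))
}

#' Total stimulus duration in seconds
#'
#' `n_images / update_hz`; with the defaults, 8 / 18.75 = 0.4267 s.
#'
#' @param spec A [coherence_spec()].
#' @param geometry A [display_geometry()].
#' @return Duration in seconds.
#' @export
stimulus_duration <- function(spec, geometry = display_geometry()) {
  spec$n_images / geometry$update_hz
}
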
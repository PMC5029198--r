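# Synthetic participant cohorts: correlated reading measures, gender and
# non-verbal IQ, and per-task coherence thresholds from calibrated linear
# models, so the whole analysis chain can be exercised without human data.

#' Cohort specification
#'
#' @param n Number of participants.
#' @param female_fraction Fraction of females; the female count is
#'   allocated deterministically as `round(n * female_fraction)`.
#' @param reading_correlations Symmetric positive-definite 3x3 correlation
#'   matrix of the three reading measures (NART, TOWRE Sight Word
#'   Efficiency, TOWRE Phonemic Decoding).
#' @param reading_scales Data frame with columns `test`, `mean`, `sd`
#'   giving each reading measure's marginal scale.
#' @param spm_mean,spm_sd Marginal scale of the non-verbal IQ raw score.
#' @param threshold_models Named list (one entry per task) of coefficient
#'   vectors `c(intercept, gender, spm, reading, residual_sd)`; see
#'   [generate_cohort()] for the model.
#' @param truncation Lower/upper threshold bounds; draws outside
#'   `(lower, upper]` are resampled rather than clipped, avoiding a point
#'   mass at the ceiling.
#' @param seed Default seed used by [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 106L, female_fraction = 64 / 106,
                        reading_correlations = default_reading_correlations(),
                        reading_scales = default_reading_scales(),
                        spm_mean = 50.5, spm_sd = 4.8,
                        threshold_models = default_threshold_models(),
                        truncation = c(0, 100), seed = NULL) {
  n <- as.integer(n)
  if (n < 4L) stop("cohort size must be at least 4", call. = FALSE)
  if (female_fraction < 0 || female_fraction > 1) {
    stop("female_fraction must lie in [0, 1]", call. = FALSE)
  }
  r <- reading_correlations
  if (!isTRUE(all.equal(r, t(r))) || any(abs(diag(r) - 1) > 1e-9)) {
    stop("reading_correlations must be symmetric with unit diagonal",
         call. = FALSE)
  }
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("reading_correlations must be positive-definite", call. = FALSE)
  }
  required <- c("intercept", "gender", "spm", "reading", "residual_sd")
  for (m in threshold_models) {
    if (!all(required %in% names(m))) {
      stop("each threshold model needs coefficients: ",
           paste(required, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n = n, female_fraction = female_fraction,
         reading_correlations = r, reading_scales = reading_scales,
         spm_mean = spm_mean, spm_sd = spm_sd,
         threshold_models = threshold_models, truncation = truncation,
         seed = seed),
    class = "cohort_spec")
}

#' Generate a synthetic participant cohort
#'
#' Reading scores are drawn as correlated standard normals (via the
#' specified correlation matrix) and affinely mapped to each test's
#' marginal scale; the latent reading factor is the unit-variance first
#' principal component of the latent scores. Non-verbal IQ is independent
#' of reading. Per-task true coherence thresholds follow
#' `intercept + gender * I(female) + spm * (SPM - spm_mean) +
#' reading * z + eps` with Gaussian residuals resampled until the
#' threshold lies in `(lower, upper]`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A `data.frame` (classed `cohort`) with one row per participant:
#'   `id`, `gender`, `spm_raw`, the three reading scores,
#'   `reading_factor` (the latent composite the thresholds were generated
#'   from), four `thr_*` columns and a `group` column (all
#'   `"unassigned"`; see [assign_groups()]).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 106), seed = 1)
#' table(cohort$gender)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  with_seed(seed, {
    n_female <- as.integer(round(n * spec$female_fraction))
    gender <- sample(rep(c("female", "male"), c(n_female, n - n_female)))
    gender <- factor(gender, levels = c("female", "male"))

    z <- MASS::mvrnorm(n, mu = rep(0, 3),
                       Sigma = spec$reading_correlations)
    eig <- eigen(spec$reading_correlations, symmetric = TRUE)
    v1 <- eig$vectors[, 1]
    if (sum(v1) < 0) v1 <- -v1
    reading_factor <- as.numeric(z %*% v1) / sqrt(eig$values[1])

    sc <- spec$reading_scales
    scores <- lapply(seq_len(3), function(j) {
      sc$mean[j] + sc$sd[j] * z[, j]
    })
    names(scores) <- sc$test

    spm_raw <- stats::rnorm(n, spec$spm_mean, spec$spm_sd)
    female <- as.numeric(gender == "female")
    lo <- spec$truncation[1]
    hi <- spec$truncation[2]
    thresholds <- lapply(spec$threshold_models, function(m) {
      mu <- m[["intercept"]] + m[["gender"]] * female +
        m[["spm"]] * (spm_raw - spec$spm_mean) +
        m[["reading"]] * reading_factor
      thr <- mu + stats::rnorm(n, 0, m[["residual_sd"]])
      bad <- thr <= lo | thr > hi
      guard <- 0L
      while (any(bad)) {
        guard <- guard + 1L
        if (guard > 10000L) {
          stop("threshold resampling failed to respect truncation bounds",
               call. = FALSE)
        }
        thr[bad] <- mu[bad] + stats::rnorm(sum(bad), 0, m[["residual_sd"]])
        bad <- thr <= lo | thr > hi
      }
      thr
    })
    names(thresholds) <- paste0("thr_", names(spec$threshold_models))

    out <- data.frame(id = seq_len(n), gender = gender,
                      spm_raw = spm_raw, scores, thresholds,
                      reading_factor = reading_factor,
                      group = factor(rep("unassigned", n),
                                     levels = c("dyslexia", "good",
                                                "unassigned")),
                      stringsAsFactors = FALSE)
    class(out) <- c("cohort", "data.frame")
    attr(out, "spec") <- spec
    out
  })
}

#' Assign dyslexia / good-reader groups
#'
#' Participants with a phonemic-decoding standard score at or below the
#' cutoff (85, the 15th percentile) form the dyslexia group; the good
#' readers are the same number of highest-scoring participants among the
#' remainder; everyone else is unassigned. The rule depends only on
#' `towre_pd_std` and is idempotent.
#'
#' @param cohort A cohort data frame with a `towre_pd_std` column.
#' @param cutoff Standard-score cutoff for the dyslexia group.
#' @return The cohort with its `group` column filled in.
#' @export
assign_groups <- function(cohort, cutoff = 85) {
  if (!"towre_pd_std" %in% names(cohort)) {
    stop("cohort lacks a towre_pd_std column", call. = FALSE)
  }
  pd <- cohort$towre_pd_std
  dys <- pd <= cutoff
  k <- sum(dys)
  if (sum(!dys) < k) {
    stop("fewer eligible good readers (", sum(!dys),
         ") than readers with dyslexia (", k, ")", call. = FALSE)
  }
  group <- rep("unassigned", nrow(cohort))
  group[dys] <- "dyslexia"
  rest <- which(!dys)
  good <- rest[order(-pd[rest], cohort$id[rest])][seq_len(k)]
  group[good] <- "good"
  cohort$group <- factor(group, levels = c("dyslexia", "good",
                                           "unassigned"))
  cohort
}

#' Replace true thresholds with simulated staircase measurements
#'
#' Closes the measurement loop: each participant's true threshold on each
#' task parameterises a [psychometric_observer()], a session of adaptive
#' staircases is run, and the session estimate replaces the true value
#' (which is retained in a `thr_<task>_true` column). Dot tasks use 200
#' elements and the bar task 50, matching the stimulus defaults.
#'
#' @param cohort A cohort data frame.
#' @param tasks Character vector of task names to measure.
#' @param slope,lapse_rate Observer parameters shared by all participants.
#' @param n_staircases Staircases per session.
#' @param seed Optional integer seed.
#' @return The cohort with measured `thr_*` columns and `thr_*_true`
#'   backups.
#' @export
measure_cohort <- function(cohort,
                           tasks = c("rdk", "bar1d", "static_form",
                                     "temporal_form"),
                           slope = 2, lapse_rate = 0.01,
                           n_staircases = 4L, seed = NULL) {
  seeds <- if (is.null(seed)) vector("list", length(tasks) * nrow(cohort))
           else as.list(spawn_seeds(seed, length(tasks) * nrow(cohort)))
  idx <- 0L
  for (task in tasks) {
    col <- paste0("thr_", task)
    if (!col %in% names(cohort)) {
      stop("cohort lacks column ", col, call. = FALSE)
    }
    total <- if (task == "bar1d") 50L else 200L
    config <- staircase_config(total_elements = total)
    true <- cohort[[col]]
    measured <- numeric(nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      idx <- idx + 1L
      obs <- psychometric_observer(true[i], slope = slope,
                                   lapse_rate = lapse_rate)
      measured[i] <- run_session(obs, config,
                                 n_staircases = n_staircases,
                                 seed = seeds[[idx]])$session_threshold_pct
    }
    cohort[[paste0(col, "_true")]] <- true
    cohort[[col]] <- measured
  }
  cohort
}

#' Write / read a cohort as delimited text
#'
#' @param cohort A cohort data frame.
#' @param path File path (tab-separated, with header).
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if ("gender" %in% names(out)) {
    out$gender <- factor(out$gender, levels = c("female", "male"))
  }
  if ("group" %in% names(out)) {
    out$group <- factor(out$group,
                        levels = c("dyslexia", "good", "unassigned"))
  }
  class(out) <- c("cohort", "data.frame")
  out
}

#' Read a cohort specification from a YAML configuration file
#'
#' Recognised keys mirror the arguments of [cohort_spec()], with the
#' cohort size given as `n_participants` (a bare `n` is a YAML 1.1
#' boolean); nested `threshold_models` entries are named coefficient maps
#' and `reading_correlations` may be given as the three pairwise values
#' `c(nart_swe, nart_pd, swe_pd)`.
#'
#' @param path YAML file path.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$n_participants)) args$n <- cfg$n_participants
  for (key in c("female_fraction", "spm_mean", "spm_sd", "seed")) {
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  }
  if (!is.null(cfg$truncation)) args$truncation <- unlist(cfg$truncation)
  if (!is.null(cfg$reading_correlations)) {
    v <- unlist(cfg$reading_correlations)
    r <- default_reading_correlations()
    r[1, 2] <- r[2, 1] <- v[1]
    r[1, 3] <- r[3, 1] <- v[2]
    r[2, 3] <- r[3, 2] <- v[3]
    args$reading_correlations <- r
  }
  if (!is.null(cfg$threshold_models)) {
    args$threshold_models <- lapply(cfg$threshold_models, unlist)
  }
  do.call(cohort_spec, args)
}
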
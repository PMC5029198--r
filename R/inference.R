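# Inferential machinery: two-step hierarchical regression with an
# R-squared-change F test and local Cohen's f-squared, pooled two-sample
# t tests from summary statistics, and cross-task threshold correlations.

#' Two-step hierarchical regression
#'
#' Fits ordinary least squares at two steps -- step 1 with the control
#' variables (gender, non-verbal IQ), step 2 adding a single predictor
#' (reading composite or reading group) -- and evaluates the step-2
#' increment: `delta_r2 = r2_full - r2_step1`, tested with
#' `F = (delta_r2 / 1) / ((1 - r2_full) / (n - 4))` on (1, n - 4) degrees
#' of freedom, plus the local effect size
#' `f2 = delta_r2 / (1 - r2_full)`. Standardised betas rescale each raw
#' coefficient by `sd(x) / sd(y)` (binary regressors included).
#'
#' @param y Numeric response (raw coherence thresholds).
#' @param controls Data frame (or list) of control variables; a factor
#'   `gender` is coded female = 1, male = 0.
#' @param predictor Step-2 predictor; a factor `group` is coded
#'   dyslexia = 1, good = 0.
#' @param predictor_name Label for the predictor in the coefficient table.
#' @return An object of class `hier_fit`: `r2_step1`, `r2_full`,
#'   `delta_r2`, `f_change`, `df1`, `df2`, `p_change`, `f2_local`, `n`,
#'   and a `coefficients` data frame (per step: B, SE B, standardised
#'   beta).
#' @export
hierarchical_fit <- function(y, controls, predictor,
                             predictor_name = "predictor") {
  controls <- as.data.frame(controls)
  controls[] <- lapply(controls, code_binary)
  predictor <- code_binary(predictor)
  n <- length(y)
  if (nrow(controls) != n || length(predictor) != n) {
    stop("response, controls and predictor lengths differ", call. = FALSE)
  }
  k_full <- ncol(controls) + 1L
  if (n <= k_full + 1L) {
    stop("too few observations for the full model", call. = FALSE)
  }
  dat <- cbind(data.frame(.y = y), controls)
  dat[[predictor_name]] <- predictor
  x_full <- stats::model.matrix(~ ., dat[-1])
  if (qr(x_full)$rank < ncol(x_full)) {
    stop("collinear design (condition number ",
         format(kappa(x_full), digits = 4), ")", call. = FALSE)
  }
  f1 <- stats::as.formula(paste(".y ~",
                                paste(names(controls), collapse = " + ")))
  f2 <- stats::as.formula(paste(".y ~",
                                paste(c(names(controls), predictor_name),
                                      collapse = " + ")))
  m1 <- stats::lm(f1, data = dat)
  m2 <- stats::lm(f2, data = dat)
  r2_step1 <- summary(m1)$r.squared
  r2_full <- summary(m2)$r.squared
  delta_r2 <- r2_full - r2_step1
  df1 <- 1L
  df2 <- n - k_full - 1L
  f_change <- (delta_r2 / df1) / ((1 - r2_full) / df2)
  p_change <- stats::pf(f_change, df1, df2, lower.tail = FALSE)
  f2_local <- if (r2_full > 1 - 1e-12) NA_real_  # saturated full model
              else cohens_f2_local(max(0, delta_r2), r2_full)
  sd_y <- stats::sd(y)
  coef_table <- function(model, step) {
    sm <- summary(model)$coefficients
    terms <- rownames(sm)[-1]
    data.frame(step = step, term = terms,
               B = sm[-1, 1], SE_B = sm[-1, 2],
               beta = sm[-1, 1] *
                 vapply(terms, function(t) stats::sd(dat[[t]]),
                        numeric(1)) / sd_y,
               p = sm[-1, 4], row.names = NULL,
               stringsAsFactors = FALSE)
  }
  structure(
    list(r2_step1 = r2_step1, r2_full = r2_full, delta_r2 = delta_r2,
         f_change = f_change, df1 = df1, df2 = df2, p_change = p_change,
         f2_local = f2_local, n = n,
         coefficients = rbind(coef_table(m1, 1L), coef_table(m2, 2L)),
         predictor_name = predictor_name),
    class = "hier_fit")
}

# female = 1 / male = 0 and dyslexia = 1 / good = 0; other factors error.
code_binary <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(as.numeric(x))
  if (is.factor(x) || is.character(x)) {
    x <- as.character(x)
    lv <- unique(x)
    if (all(lv %in% c("female", "male"))) {
      return(as.numeric(x == "female"))
    }
    if (all(lv %in% c("dyslexia", "good"))) {
      return(as.numeric(x == "dyslexia"))
    }
    stop("cannot code non-numeric variable with levels: ",
         paste(lv, collapse = ", "), call. = FALSE)
  }
  stop("unsupported variable type", call. = FALSE)
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("<hier_fit> n = ", x$n, "\n",
      "  step 1 R2 = ", format(x$r2_step1, digits = 3),
      "; full R2 = ", format(x$r2_full, digits = 3),
      "; delta R2 = ", format(x$delta_r2, digits = 3), "\n",
      "  F(", x$df1, ", ", x$df2, ") = ", format(x$f_change, digits = 4),
      ", p = ", format(x$p_change, digits = 3),
      "; local f2 = ", format(x$f2_local, digits = 3), "\n", sep = "")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Local Cohen's f-squared
#'
#' `f2 = delta_r2 / (1 - r2_full)`: the effect size for one predictor's
#' increment in a hierarchical regression. Conventional benchmarks: 0.02
#' small, 0.15 medium, 0.35 large.
#'
#' @param delta_r2 R-squared increment attributable to the predictor.
#' @param r2_full Full-model R-squared (strictly less than 1).
#' @return The local effect size (vectorised).
#' @examples
#' cohens_f2_local(0.06, 0.22)  # 0.0769...
#' @export
cohens_f2_local <- function(delta_r2, r2_full) {
  if (any(delta_r2 < 0) || any(delta_r2 > r2_full)) {
    stop("need 0 <= delta_r2 <= r2_full", call. = FALSE)
  }
  if (any(r2_full >= 1)) {
    stop("local f2 is undefined when the full model is saturated (R2 = 1)",
         call. = FALSE)
  }
  delta_r2 / (1 - r2_full)
}

#' Two-sample t test from summary statistics
#'
#' Pooled-variance test (df = n1 + n2 - 2) by default; Welch's
#' approximation behind `welch = TRUE`.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param welch Use the Welch unequal-variance test.
#' @return An object of class `group_comparison`: `t`, `df`, `p`, group
#'   means/SDs/sizes.
#' @examples
#' pooled_t(23.72, 6.03, 43, 29.63, 4.32, 43)
#' @export
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative", call. = FALSE)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      t <- 0
      df <- n1 + n2 - 2
    } else {
      stop("zero variance in both groups with unequal means: ",
           "t statistic is infinite", call. = FALSE)
    }
  } else if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / (sd1^4 / (n1^2 * (n1 - 1)) + sd2^4 / (n2^2 * (n2 - 1)))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  structure(
    list(t = t, df = df,
         p = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
         group_means = c(mean1, mean2), group_sds = c(sd1, sd2),
         n_per_group = c(n1, n2), welch = welch),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> t(", format(x$df, digits = 5), ") = ",
      format(x$t, digits = 4), ", p = ", format(x$p, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Pairwise Pearson correlations across task thresholds
#'
#' Thresholds are z-transformed per task (which leaves Pearson r
#' unchanged) and all pairwise correlations are computed with two-sided p
#' values from the t distribution on n - 2 degrees of freedom.
#'
#' @param x Matrix or data frame of threshold columns (one per task).
#' @return An object of class `correlation_report` with `r_matrix`,
#'   `p_matrix` and `n`.
#' @export
task_correlations <- function(x) {
  z <- z_transform(x)
  n <- nrow(z)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  r <- stats::cor(z)
  p <- matrix(NA_real_, ncol(z), ncol(z), dimnames = dimnames(r))
  diag(p) <- 0
  for (i in seq_len(ncol(z) - 1L)) {
    for (j in (i + 1L):ncol(z)) {
      rij <- r[i, j]
      tstat <- rij * sqrt((n - 2) / (1 - rij^2))
      p[i, j] <- p[j, i] <- 2 * stats::pt(abs(tstat), n - 2,
                                          lower.tail = FALSE)
    }
  }
  structure(list(r_matrix = r, p_matrix = p, n = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> n =", x$n, "\n")
  print(round(x$r_matrix, 3))
  invisible(x)
}
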
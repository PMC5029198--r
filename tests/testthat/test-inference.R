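test_that("the step-2 F test matches its algebraic identities", {
  for (s in 1:8) {
    set.seed(s)
    n <- 60
    gender <- rbinom(n, 1, 0.5)
    spm <- rnorm(n, 50, 5)
    pred <- rnorm(n)
    y <- 10 + 2 * gender - 0.3 * spm - 1.5 * pred + rnorm(n, 0, 4)
    fit <- hierarchical_fit(y, data.frame(gender = gender, spm = spm),
                            pred)
    # internal consistency
    expect_equal(fit$delta_r2, fit$r2_full - fit$r2_step1,
                 tolerance = 1e-12)
    expect_equal(fit$f2_local, fit$delta_r2 / (1 - fit$r2_full),
                 tolerance = 1e-12)
    expect_equal(fit$df2, n - 4)
    # F change equals the squared t of the step-2 predictor
    t_pred <- summary(lm(y ~ gender + spm + pred))$coefficients[4, 3]
    expect_equal(fit$f_change, t_pred^2, tolerance = 1e-8)
    # residual-sum-of-squares oracle
    rss1 <- sum(resid(lm(y ~ gender + spm))^2)
    rss2 <- sum(resid(lm(y ~ gender + spm + pred))^2)
    expect_equal(fit$f_change, ((rss1 - rss2) / 1) / (rss2 / (n - 4)),
                 tolerance = 1e-8)
    # standardised beta of the predictor
    beta <- fit$coefficients
    b_pred <- beta[beta$step == 2 & beta$term == "predictor", ]
    expect_equal(b_pred$beta, b_pred$B * sd(pred) / sd(y),
                 tolerance = 1e-12)
  }
})

test_that("degenerate hierarchical designs behave as documented", {
  set.seed(11)
  n <- 50
  gender <- rbinom(n, 1, 0.5)
  spm <- rnorm(n, 50, 5)
  y <- 5 + gender + 0.2 * spm + rnorm(n)
  # predictor orthogonal to everything carries no increment
  z <- resid(lm(rnorm(n) ~ gender + spm + y))
  fit <- hierarchical_fit(y, data.frame(gender = gender, spm = spm), z)
  expect_equal(fit$delta_r2, 0, tolerance = 1e-12)
  expect_equal(fit$f2_local, 0, tolerance = 1e-12)
  # a control identical to the response saturates step 1
  fit2 <- suppressWarnings(  # lm warns about the perfect step-1 fit
    hierarchical_fit(y, data.frame(gender = y, spm = spm), rnorm(n)))
  expect_equal(fit2$r2_step1, 1, tolerance = 1e-12)
  expect_true(is.na(fit2$f2_local))
  # collinear designs abort with a condition-number diagnostic
  expect_error(
    hierarchical_fit(y, data.frame(gender = gender, spm = spm,
                                   spm2 = 2 * spm), rnorm(n)),
    "collinear")
})

test_that("local f2 follows delta-R2 over (1 - R2) with guarded domain", {
  expect_equal(cohens_f2_local(0.06, 0.22), 0.06 / 0.78)
  expect_equal(cohens_f2_local(0, 0.5), 0)
  expect_error(cohens_f2_local(0.3, 0.2), "delta_r2")
  expect_error(cohens_f2_local(0.2, 1), "saturated")
})

test_that("pooled t from summaries agrees with t.test on raw data", {
  set.seed(21)
  g1 <- rnorm(25, 10, 3)
  g2 <- rnorm(31, 12, 4)
  ours <- pooled_t(mean(g1), sd(g1), 25, mean(g2), sd(g2), 31)
  ref <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  welch <- pooled_t(mean(g1), sd(g1), 25, mean(g2), sd(g2), 31,
                    welch = TRUE)
  ref_w <- t.test(g1, g2)
  expect_equal(welch$t, unname(ref_w$statistic), tolerance = 1e-10)
  expect_equal(welch$df, unname(ref_w$parameter), tolerance = 1e-8)
  # degenerate cases
  expect_equal(pooled_t(5, 0, 10, 5, 0, 10)$t, 0)
  expect_error(pooled_t(5, 0, 10, 6, 0, 10), "infinite")
})

test_that("task correlations recover exact and null relationships", {
  set.seed(31)
  x <- rnorm(40)
  crep <- task_correlations(cbind(a = x, b = -x, c = rnorm(40),
                                  d = rnorm(40)))
  expect_equal(diag(crep$r_matrix), rep(1, 4), ignore_attr = TRUE)
  expect_equal(crep$r_matrix["a", "b"], -1, tolerance = 1e-12)
  expect_lt(crep$p_matrix["a", "b"], 1e-12)
  expect_true(isSymmetric(crep$r_matrix))
  expect_error(task_correlations(cbind(rep(1, 10), rnorm(10))),
               "constant")
  # type-I error rate of the p values under independence
  set.seed(32)
  hits <- 0; total <- 0
  for (i in 1:400) {
    pm <- task_correlations(matrix(rnorm(106 * 4), 106))$p_matrix
    ps <- pm[upper.tri(pm)]
    hits <- hits + sum(ps < 0.05); total <- total + length(ps)
  }
  rate <- hits / total
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / total))
})

test_that("known cohort coefficients are recovered with nominal coverage", {
  models <- list(flat = c(intercept = 50, gender = 5, spm = -0.5,
                          reading = -3, residual_sd = 9))
  spec <- cohort_spec(n = 106, threshold_models = models)
  truth <- c(gender = 5, spm = -0.5, reading = -3)
  est <- se <- matrix(NA_real_, 250, 3, dimnames = list(NULL, names(truth)))
  covered <- logical(250)
  for (s in 1:250) {
    cohort <- generate_cohort(spec, seed = 700 + s)
    fit <- hierarchical_fit(cohort$thr_flat,
                            data.frame(gender = cohort$gender,
                                       spm = cohort$spm_raw),
                            cohort$reading_factor,
                            predictor_name = "reading")
    co <- fit$coefficients
    co <- co[co$step == 2, ]
    est[s, ] <- co$B[match(names(truth), co$term)]
    se[s, ] <- co$SE_B[match(names(truth), co$term)]
    ci <- co$B[co$term == "reading"] +
      c(-1, 1) * qt(0.975, fit$df2) * co$SE_B[co$term == "reading"]
    covered[s] <- ci[1] <= -3 && -3 <= ci[2]
  }
  for (term in names(truth)) {
    expect_lt(abs(mean(est[, term]) - truth[term]),
              0.5 * mean(se[, term]),
              label = paste("recovery of", term))
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})
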
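# A balanced one-way random-intercept fixture with closed-form REML
# estimators (classical variance-components ANOVA):
#   sigma2_hat = MSW,  sigma_u2_hat = (MSB - MSW) / n,  mu_hat = grand mean,
#   SE(mu_hat) = sqrt(MSB / (k * n))
balanced_fixture <- function(k = 12, n = 8, mu = 50, sd_u = 12, sd_e = 9,
                             seed = 1) {
  set.seed(seed)
  u <- stats::rnorm(k, 0, sd_u)
  data.frame(subject = factor(rep(seq_len(k), each = n)),
             value = mu + rep(u, each = n) + stats::rnorm(k * n, 0, sd_e))
}

fit_intercept_only <- function(d, method = "REML") {
  d$kind <- "JND"
  fit_lmm(d, "JND", fixed = character(0), random = "(1 | subject)",
          method = method)
}

test_that("REML estimates match closed-form balanced ANOVA estimators", {
  d <- balanced_fixture()
  k <- 12; n <- 8
  gm <- mean(d$value)
  gmeans <- tapply(d$value, d$subject, mean)
  msb <- n * sum((gmeans - gm)^2) / (k - 1)
  msw <- sum((d$value - gmeans[d$subject])^2) / (k * (n - 1))
  f <- fit_intercept_only(d)
  expect_equal(f$coefficients$estimate[1], gm, tolerance = 1e-6)
  expect_equal(f$coefficients$se[1], sqrt(msb / (k * n)), tolerance = 1e-6)
  expect_equal(unname(f$varcomp["sigma2"]), msw, tolerance = 1e-6)
  expect_equal(unname(f$varcomp["Var: subject (Intercept)"]),
               (msb - msw) / n, tolerance = 1e-6)
})

test_that("balanced designs give OLS fixed effects for REML and ML alike", {
  d <- balanced_fixture(seed = 2)
  # a within-subject treatment, balanced within every subject
  d$prepost <- rep(rep(0:1, each = 4), 12)
  d$value <- d$value - 4 * d$prepost
  d$kind <- "JND"
  ols <- stats::lm(value ~ prepost, d)
  freml <- fit_lmm(d, "JND", fixed = "prepost", random = "(1 | subject)",
                   method = "REML")
  fml <- fit_lmm(d, "JND", fixed = "prepost", random = "(1 | subject)",
                 method = "ML")
  expect_equal(coef(freml), coef(ols), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(coef(freml), coef(fml), tolerance = 1e-6)
})

test_that("likelihood-ratio bookkeeping is exact", {
  st <- generate_study(small_config(seed = 20), measurement = "direct")
  fl <- score_flow_table(st$questionnaire)
  md <- build_model_data(st$estimates, fl, st$design)
  m0 <- fit_lmm(md, "JND", fixed = c("condition", "prepost"), method = "ML")
  m1 <- fit_lmm(md, "JND", fixed = c("condition", "prepost", "flow"),
                method = "ML")
  out <- lrt_compare(m0, m1)
  expect_equal(out$statistic, 2 * (m1$loglik - m0$loglik))
  expect_equal(out$df, 1)  # one added fixed term
  expect_equal(out$p, stats::pchisq(out$statistic, 1, lower.tail = FALSE))
  same <- lrt_compare(m0, m0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(lrt_compare(fit_lmm(md, "JND", fixed = "condition"), m1), "ML")
})

test_that("variance shares follow the component arithmetic", {
  comp <- c(subject = 331.62, session = 152.93, residual = 343.18)
  sh <- variance_partition(comp)
  expect_equal(unname(sh), c(331.62, 152.93, 343.18) / 827.73)  # ~ (0.400, 0.185, 0.415)
  expect_equal(sum(sh), 1)
  expect_equal(unname(variance_partition(c(subject = 10, session = 0,
                                           residual = 30))["session"]), 0)
  expect_error(variance_partition(c(subject = 0, residual = 0)), "zero")
})

test_that("centring flow leaves the interaction estimate unchanged", {
  st <- generate_study(small_config(seed = 21), measurement = "direct")
  fl <- score_flow_table(st$questionnaire)
  md <- build_model_data(st$estimates, fl, st$design)
  f1 <- fit_lmm(md, "JND")
  md2 <- md; md2$flow_c <- md2$flow_c + 3.43  # raw-scale coding
  f2 <- fit_lmm(md2, "JND")
  i1 <- f1$coefficients[f1$coefficients$term == "flow_c:prepost", ]
  i2 <- f2$coefficients[f2$coefficients$term == "flow_c:prepost", ]
  expect_equal(i1$estimate, i2$estimate, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(
    f1$coefficients$estimate[1], f2$coefficients$estimate[1])))
})

test_that("a three-way term with no planted condition-specific slope is centred on zero", {
  reps <- 40
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- generate_study(study_config(n_participants = 20, seed = 7000 + r),
                         measurement = "direct")
    fl <- score_flow_table(st$questionnaire)
    md <- build_model_data(st$estimates, fl, st$design)
    f <- fit_lmm(md, "JND", fixed = c("condition", "flow", "prepost",
                                      "prepost:flow",
                                      "prepost:flow:condition"))
    est[r] <- f$coefficients$estimate[
      f$coefficients$term == "condition:flow_c:prepost"]
  }
  expect_lt(abs(mean(est)), 3 * stats::sd(est) / sqrt(reps))
})

test_that("singular fits are flagged, not hidden", {
  d <- balanced_fixture(sd_u = 0, seed = 3)  # no true subject variance
  f <- fit_intercept_only(d)
  expect_true(is.logical(f$singular))
  # with zero between-subject variance the subject component sits near zero
  expect_lt(unname(f$varcomp["Var: subject (Intercept)"]), 5)
})

test_that("moderation models use the prescribed random structures", {
  st <- generate_study(small_config(seed = 30), measurement = "direct")
  fl <- score_flow_table(st$questionnaire)
  md <- build_model_data(st$estimates, fl, st$design)
  fits <- fit_moderation_models(md)
  expect_true("Var: subject:session (Intercept)" %in% names(fits$jnd$varcomp))
  expect_true("Var: subject condition" %in% names(fits$pss$varcomp))
  expect_true("Cov: subject (Intercept) condition" %in% names(fits$pss$varcomp))
  expect_equal(fits$jnd$coefficients$term[1], "(Intercept)")
  # Wald CI convention
  cf <- fits$pss$coefficients
  expect_equal(cf$ci_hi - cf$estimate, 1.96 * cf$se, tolerance = 1e-10)
})
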
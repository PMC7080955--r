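#' Assemble the model input table
#'
#' Joins (screened) estimate records with per-session flow scores and the
#' design table into the single tidy table the hierarchical models consume.
#' Predictor codings: `prepost` 0 = pre, 1 = post; `condition`
#' 0 = endogenous, 1 = exogenous; `domain` 0 = musician, 1 = athlete; flow
#' and the control question are grand-mean-centred over the session scores
#' entering the table (`flow_c`, `control_q_c`), so that "per unit of flow"
#' coefficients are interpretable at the average flow level.
#'
#' @param estimates Estimate records ([estimate_study()]) or a `toj_screen`.
#' @param flow Flow score table ([score_flow_table()]).
#' @param design Data frame `participant`, `domain` (`"athlete"`/`"musician"`).
#' @return Data frame with columns `subject`, `session`, `prepost`,
#'   `condition`, `domain`, `flow_c`, `control_q_c`, `kind`, `value`.
#' @export
build_model_data <- function(estimates, flow, design = NULL) {
  if (inherits(estimates, "toj_screen")) estimates <- estimates$estimates
  est <- estimates[estimates$kind %in% c("JND", "PSS_distance"), ]
  fkey <- paste(flow$participant, flow$session)
  m <- match(paste(est$participant, est$session), fkey)
  flow_bar <- mean(flow$global_flow)
  cq_bar <- mean(flow$control_q)
  out <- data.frame(
    subject = factor(est$participant),
    session = factor(est$session),
    prepost = as.integer(est$phase == "post"),
    condition = as.integer(est$condition == "exogenous"),
    flow_c = flow$global_flow[m] - flow_bar,
    control_q_c = flow$control_q[m] - cq_bar,
    kind = est$kind,
    value = est$value,
    stringsAsFactors = FALSE)
  out$domain <- if (is.null(design)) NA_integer_ else
    as.integer(design$domain[match(est$participant, design$participant)] == "athlete")
  attr(out, "flow_mean") <- flow_bar
  out
}

translate_terms <- function(terms) {
  terms <- gsub("\\bflow\\b", "flow_c", terms)
  gsub("\\bcontrol_q\\b", "control_q_c", terms)
}

#' Fit a hierarchical linear model of JND or PSS estimates
#'
#' Gaussian mixed model fitted by (restricted) maximum likelihood through
#' lme4, presented with the conventions of the measurement literature:
#' Wald 95% confidence intervals (`estimate +- 1.96 SE`) and t tests on the
#' residual degrees of freedom `n_obs - n_fixed`. Rows with a missing
#' response or missing flow score are dropped listwise.
#'
#' @param data Model input table from [build_model_data()].
#' @param response `"JND"` or `"PSS_distance"` (used to filter `data$kind`
#'   when present, and to pick the default random structure: a three-level
#'   session-within-subject intercept model for the JND, a two-level model
#'   with a per-subject random condition slope for the PSS distance).
#' @param fixed Character vector of fixed terms in the field vocabulary
#'   (`"condition"`, `"flow"`, `"prepost"`, `"prepost:flow"`, `"domain"`,
#'   `"prepost:domain"`, `"prepost:flow:condition"`,
#'   `"prepost:flow:control_q"`); the intercept is always included.
#'   `character(0)` gives the fully unconditional model.
#' @param random Character vector of lme4 random-effect terms; `NULL` picks
#'   the default for `response`.
#' @param method `"REML"` (reported coefficients) or `"ML"` (for
#'   likelihood-ratio comparisons).
#' @return An object of class `toj_hlm`: coefficient table, variance
#'   components, log-likelihood, group counts, singularity flag, and the
#'   underlying lme4 fit.
#' @export
fit_lmm <- function(data, response = c("JND", "PSS_distance"),
                    fixed = c("condition", "flow", "prepost", "prepost:flow"),
                    random = NULL, method = c("REML", "ML")) {
  response <- match.arg(response)
  method <- match.arg(method)
  if (!is.null(data$kind)) data <- data[data$kind == response, ]
  if (is.null(random))
    random <- if (response == "JND")
      c("(1 | subject)", "(1 | subject:session)") else "(1 + condition | subject)"
  if (length(unique(data$subject)) < 2L) stop("need at least 2 subjects")
  fixed_tr <- translate_terms(fixed)
  vars_used <- unique(unlist(strsplit(fixed_tr, ":", fixed = TRUE)))
  keep <- is.finite(data$value)
  for (v in vars_used) keep <- keep & !is.na(data[[v]])
  data <- data[keep, , drop = FALSE]
  rhs <- paste(c("1", fixed_tr, random), collapse = " + ")
  form <- stats::as.formula(paste("value ~", rhs))
  fit <- lme4::lmer(form, data = data, REML = method == "REML",
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n <- stats::nobs(fit)
  df_t <- n - length(b)
  tval <- b / se
  coefs <- data.frame(term = names(b), estimate = unname(b), se = unname(se),
                      ci_lo = unname(b - 1.96 * se),
                      ci_hi = unname(b + 1.96 * se),
                      t = unname(tval), df = df_t,
                      p = unname(2 * stats::pt(-abs(tval), df_t)),
                      stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)
  comp <- c()
  for (g in names(vc)) {
    m <- vc[[g]]
    terms_g <- sub("^\\(Intercept\\)$", "(Intercept)", rownames(m))
    for (a in seq_len(nrow(m))) {
      comp[paste0("Var: ", g, " ", terms_g[a])] <- m[a, a]
      if (a < nrow(m)) for (bb in (a + 1):ncol(m))
        comp[paste0("Cov: ", g, " ", terms_g[a], " ", terms_g[bb])] <- m[a, bb]
    }
  }
  comp["sigma2"] <- stats::sigma(fit)^2
  ll <- stats::logLik(fit)
  structure(list(coefficients = coefs, varcomp = comp,
                 loglik = as.numeric(ll), df = attr(ll, "df"),
                 n_obs = n, n_groups = lme4::ngrps(fit),
                 singular = lme4::isSingular(fit),
                 method = method, response = response,
                 fixed = fixed, random = random,
                 formula = form, fit = fit),
            class = "toj_hlm")
}

#' @export
print.toj_hlm <- function(x, digits = 2, ...) {
  cat(sprintf("Hierarchical linear model of the %s (%s)\n", x$response, x$method))
  cat("  ", deparse(x$formula), "\n\n")
  cf <- x$coefficients
  tab <- data.frame(Estimate = round(cf$estimate, digits),
                    `Std. Error` = round(cf$se, digits),
                    CI = sprintf("%.2f to %.2f", cf$ci_lo, cf$ci_hi),
                    P = signif(cf$p, 3), check.names = FALSE)
  rownames(tab) <- cf$term
  print(tab)
  cat("\nRandom effects\n")
  for (nm in names(x$varcomp))
    cat(sprintf("  %-40s %10.2f\n", nm, x$varcomp[[nm]]))
  cat(sprintf("Num. obs. %d; groups:", x$n_obs))
  for (nm in names(x$n_groups)) cat(sprintf(" %s %d", nm, x$n_groups[[nm]]))
  cat("\n")
  if (x$singular) cat("NOTE: singular fit (a variance component is at zero)\n")
  invisible(x)
}

#' @export
coef.toj_hlm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.toj_hlm <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs, class = "logLik")
}

#' Fit the two flow-moderation models
#'
#' The primary analysis pair: a three-level model of the JND (pre/post
#' measurements nested in sessions nested in subjects, random intercepts at
#' both grouping levels) and a two-level model of the cued-PSS distance
#' (per-subject random intercept and random condition slope with their
#' covariance), both with fixed effects for condition, centred flow,
#' pre/post, and the cross-level pre/post x flow interaction whose
#' coefficient is the moderation of interest.
#'
#' @param data Model input table from [build_model_data()].
#' @param method `"REML"` or `"ML"`.
#' @return List of class `toj_moderation` with elements `jnd` and `pss`.
#' @export
fit_moderation_models <- function(data, method = "REML") {
  structure(list(jnd = fit_lmm(data, "JND", method = method),
                 pss = fit_lmm(data, "PSS_distance", method = method)),
            class = "toj_moderation")
}

#' @export
print.toj_moderation <- function(x, ...) {
  cat("=== JND model ===\n"); print(x$jnd)
  cat("\n=== PSS-distance model ===\n"); print(x$pss)
  invisible(x)
}

#' Likelihood-ratio comparison of nested model fits
#'
#' Chi-square test `2 * (logLik1 - logLik0)` with degrees of freedom equal
#' to the parameter-count difference. Both fits must be ML fits of nested
#' specifications on the identical rows.
#'
#' @param m0,m1 `toj_hlm` fits, `m0` nested in `m1`.
#' @return List with `statistic`, `df`, `p`.
#' @export
lrt_compare <- function(m0, m1) {
  stopifnot(inherits(m0, "toj_hlm"), inherits(m1, "toj_hlm"))
  if (m0$method != "ML" || m1$method != "ML")
    stop("likelihood-ratio tests require ML fits")
  if (m0$n_obs != m1$n_obs)
    stop("fits use different rows; refit both on the common data")
  if (m0$df > m1$df || !all(m0$fixed %in% m1$fixed))
    stop("'m0' must be nested in 'm1'")
  stat <- 2 * (m1$loglik - m0$loglik)
  df <- m1$df - m0$df
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Variance partition of an unconditional fit
#'
#' Shares of the total variance attributed to each level of the hierarchy:
#' each random component divided by the sum of all components plus the
#' residual. For the three-level JND structure these are the subject,
#' session-within-subject and residual (pre/post measurement) shares.
#'
#' @param x A `toj_hlm` (intercept-only fit) or a named numeric vector of
#'   variance components including a residual (named `sigma2` or
#'   `residual`).
#' @return Named numeric vector of shares summing to 1.
#' @export
variance_partition <- function(x) {
  comp <- if (inherits(x, "toj_hlm")) x$varcomp else x
  comp <- comp[!grepl("^Cov", names(comp))]
  total <- sum(comp)
  if (total <= 0) stop("total variance is zero; shares are undefined")
  nm <- names(comp)
  nm[nm == "sigma2"] <- "residual"
  nm <- sub("^Var: subject:session.*|^Var: session:subject.*", "session", nm)
  nm <- sub("^Var: subject.*|^subject$", "subject", nm)
  stats::setNames(as.numeric(comp) / total, nm)
}
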
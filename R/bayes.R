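# Bayesian counterparts of the moderation models, via JAGS.
#
# Priors (weakly informative, documented in the methods vignette):
#   fixed effects        ~ Normal(0, sd 1000)        (effectively flat)
#   random-effect SDs,
#   residual SD          ~ half-Student-t(3, 0, 2.5 * sd(y))
#   random-effect corr   ~ Uniform(-1, 1)            (LKJ(1) for dim 2)

jags_model_jnd <- "
model {
  for (n in 1:N) {
    mu[n] <- inprod(X[n, ], beta) + u[subj[n]] + v[run[n]]
    y[n] ~ dnorm(mu[n], tau)
  }
  for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
  for (k in 1:K) { v[k] ~ dnorm(0, tau_v) }
  for (p in 1:P) { beta[p] ~ dnorm(0, 1.0E-6) }
  sigma   ~ dt(0, pt, 3) T(0,)
  sigma_u ~ dt(0, pt, 3) T(0,)
  sigma_v ~ dt(0, pt, 3) T(0,)
  tau   <- pow(sigma, -2)
  tau_u <- pow(sigma_u, -2)
  tau_v <- pow(sigma_v, -2)
}"

jags_model_pss <- "
model {
  for (n in 1:N) {
    mu[n] <- inprod(X[n, ], beta) + u0[subj[n]] + u1[subj[n]] * cond[n]
    y[n] ~ dnorm(mu[n], tau)
  }
  for (j in 1:J) {
    u0[j] ~ dnorm(0, tau_u0)
    u1[j] ~ dnorm(rho * (sigma_u1 / sigma_u0) * u0[j], tau_c)
  }
  for (p in 1:P) { beta[p] ~ dnorm(0, 1.0E-6) }
  sigma    ~ dt(0, pt, 3) T(0,)
  sigma_u0 ~ dt(0, pt, 3) T(0,)
  sigma_u1 ~ dt(0, pt, 3) T(0,)
  rho ~ dunif(-1, 1)
  tau    <- pow(sigma, -2)
  tau_u0 <- pow(sigma_u0, -2)
  tau_c  <- pow(sigma_u1, -2) / (1 - rho * rho)
}"

# split-Rhat (Gelman-Rubin on half-chains) for a draws matrix [iter x chain]
split_rhat <- function(draws) {
  half <- floor(nrow(draws) / 2)
  segs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(segs); n <- nrow(segs)
  mu <- colMeans(segs); s2 <- apply(segs, 2, stats::var)
  W <- mean(s2); B <- n * stats::var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# truncated importance-sampling LOO from a pointwise log-likelihood matrix
# (draws x observations); weights truncated at sqrt(S) times their mean.
loo_elpd <- function(log_lik) {
  S <- nrow(log_lik)
  elpd_i <- vapply(seq_len(ncol(log_lik)), function(i) {
    ll <- log_lik[, i]
    lw <- -ll                       # raw log importance ratios
    lw <- lw - max(lw)
    r <- exp(lw)
    r <- pmin(r, mean(r) * sqrt(S)) # truncation stabilises heavy tails
    log(sum(r * exp(ll)) / sum(r))
  }, 0)
  list(elpd = sum(elpd_i), pointwise = elpd_i)
}

#' Compare two Bayesian fits by approximate leave-one-out prediction
#'
#' Expected log predictive density (elpd) difference, estimated by
#' truncated importance-sampling LOO from each fit's pointwise
#' log-likelihood draws, with the standard error of the difference computed
#' from the pointwise elpd differences.
#'
#' @param fit1,fit0 `toj_bayes` fits of the same data rows.
#' @return List with `elpd_diff` (fit1 minus fit0), `se_diff`, and each
#'   fit's total elpd.
#' @export
loo_compare_bayes <- function(fit1, fit0) {
  stopifnot(inherits(fit1, "toj_bayes"), inherits(fit0, "toj_bayes"))
  if (length(fit1$loo$pointwise) != length(fit0$loo$pointwise))
    stop("fits cover different observations")
  d <- fit1$loo$pointwise - fit0$loo$pointwise
  list(elpd_diff = sum(d), se_diff = sqrt(length(d) * stats::var(d)),
       elpd1 = fit1$loo$elpd, elpd0 = fit0$loo$elpd)
}

#' Bayesian hierarchical moderation model
#'
#' MCMC counterpart of [fit_lmm()]: the same linear predictor and random
#' structure, estimated by Gibbs sampling with weakly-informative priors
#' (flat normals on fixed effects, half-Student-t(3, 0, 2.5 sd(y)) on all
#' standard deviations, uniform correlation for the PSS random effects).
#' At least 4 chains are run and split-R-hat is computed for every reported
#' parameter; a fit with any R-hat at or above 1.01 is marked non-usable
#' (`usable = FALSE`) and should not be reported.
#'
#' @param data Model input table from [build_model_data()].
#' @param response `"JND"` or `"PSS_distance"`.
#' @param fixed Fixed terms, as in [fit_lmm()].
#' @param n_chains Number of chains (minimum 4).
#' @param n_iter Post-warmup iterations per chain.
#' @param n_burn Warmup iterations per chain.
#' @param seed Integer seed (chains use consecutive RNG seeds).
#' @return Object of class `toj_bayes`: posterior `summary` table (mean,
#'   SE = posterior SD, 95% credible interval, R-hat), `loo` (elpd and
#'   pointwise values), `usable`, `max_rhat`, and the monitored draws.
#' @export
bayesian_moderation <- function(data, response = c("JND", "PSS_distance"),
                                fixed = c("condition", "flow", "prepost",
                                          "prepost:flow"),
                                n_chains = 4, n_iter = 1000, n_burn = 500,
                                seed = 1L) {
  response <- match.arg(response)
  if (n_chains < 4) stop("at least 4 chains are required")
  if (!is.null(data$kind)) data <- data[data$kind == response, ]
  fixed_tr <- translate_terms(fixed)
  vars_used <- unique(unlist(strsplit(fixed_tr, ":", fixed = TRUE)))
  keep <- is.finite(data$value)
  for (v in vars_used) keep <- keep & !is.na(data[[v]])
  data <- data[keep, , drop = FALSE]
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c("1", fixed_tr), collapse = " + "))),
    data)
  y <- data$value
  subj <- as.integer(factor(data$subject))
  pt_prec <- (2.5 * stats::sd(y))^-2
  if (response == "JND") {
    run <- as.integer(factor(paste(data$subject, data$session)))
    jd <- list(y = y, X = X, N = length(y), P = ncol(X), subj = subj,
               J = max(subj), run = run, K = max(run), pt = pt_prec)
    model_str <- jags_model_jnd
    monitors <- c("beta", "sigma", "sigma_u", "sigma_v", "u", "v")
  } else {
    jd <- list(y = y, X = X, N = length(y), P = ncol(X), subj = subj,
               J = max(subj), cond = data$condition, pt = pt_prec)
    model_str <- jags_model_pss
    monitors <- c("beta", "sigma", "sigma_u0", "sigma_u1", "rho", "u0", "u1")
  }
  inits <- lapply(seq_len(n_chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed + ch) %% 2147483647L))
  jm <- rjags::jags.model(textConnection(model_str), data = jd, inits = inits,
                          n.chains = n_chains, quiet = TRUE)
  stats::update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitors, n.iter = n_iter,
                              progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))          # all chains
  arr <- array(unlist(lapply(samp, as.matrix)),
               dim = c(n_iter, ncol(draws), n_chains),
               dimnames = list(NULL, colnames(draws), NULL))
  # report fixed effects and scale parameters; random levels stay internal
  report <- c(paste0("beta[", seq_len(ncol(X)), "]"),
              grep("^sigma|^rho", colnames(draws), value = TRUE))
  rhat <- vapply(report, function(p) split_rhat(arr[, p, ]), 0)
  qs <- t(apply(draws[, report, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975)))
  term_names <- c(colnames(X), grep("^sigma|^rho", colnames(draws), value = TRUE))
  summ <- data.frame(term = term_names,
                     mean = colMeans(draws[, report, drop = FALSE]),
                     se = apply(draws[, report, drop = FALSE], 2, stats::sd),
                     ci_lo = qs[, 1], ci_hi = qs[, 2], rhat = rhat,
                     row.names = NULL, stringsAsFactors = FALSE)
  # pointwise conditional log-likelihood for LOO
  S <- nrow(draws)
  beta_d <- draws[, paste0("beta[", seq_len(ncol(X)), "]"), drop = FALSE]
  sig_d <- draws[, "sigma"]
  eta <- beta_d %*% t(X)
  if (response == "JND") {
    eta <- eta + draws[, paste0("u[", subj, "]"), drop = FALSE] +
      draws[, paste0("v[", run, "]"), drop = FALSE]
  } else {
    eta <- eta + draws[, paste0("u0[", subj, "]"), drop = FALSE] +
      draws[, paste0("u1[", subj, "]"), drop = FALSE] *
        matrix(data$condition, S, length(y), byrow = TRUE)
  }
  log_lik <- stats::dnorm(matrix(y, S, length(y), byrow = TRUE),
                          eta, sig_d, log = TRUE)
  structure(list(summary = summ, loo = loo_elpd(log_lik),
                 usable = all(rhat < 1.01), max_rhat = max(rhat),
                 n_obs = length(y), n_chains = n_chains, n_iter = n_iter,
                 response = response, fixed = fixed, draws = draws),
            class = "toj_bayes")
}

#' @export
print.toj_bayes <- function(x, ...) {
  cat(sprintf("Bayesian HLM of the %s (%d chains x %d iterations)\n",
              x$response, x$n_chains, x$n_iter))
  s <- x$summary
  tab <- data.frame(Mean = round(s$mean, 2), SE = round(s$se, 2),
                    `95% CrI` = sprintf("%.2f to %.2f", s$ci_lo, s$ci_hi),
                    Rhat = round(s$rhat, 3), check.names = FALSE)
  rownames(tab) <- s$term
  print(tab)
  if (!x$usable)
    cat(sprintf("NOT USABLE: max split-R-hat %.3f >= 1.01; rerun with more iterations\n",
                x$max_rhat))
  invisible(x)
}
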
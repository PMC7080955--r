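#' Fit a logistic psychometric function to TOJ trials
#'
#' Maximum-likelihood fit of the plain two-parameter logistic model
#' \deqn{P(\mathrm{right\ first}) = \Lambda(\beta_0 + \beta_1\,
#'   \mathrm{SOA}_{signed})}
#' to per-trial binary responses, via iteratively reweighted least squares
#' (convergence when the relative deviance change drops below 1e-10, at most
#' 100 iterations). No lapse or guessing asymptote is fitted; observer
#' lapses therefore show up as attenuation, as they would for an
#' experimenter fitting plain logistic regressions.
#'
#' One-class responses and complete separation make the likelihood maximum
#' non-existent; such fits are returned with `converged = FALSE` and a
#' reason, never as an error, so that a long estimation pipeline can carry
#' on and screening can deal with the fallout.
#'
#' @param signed_soa Signed SOA per trial, ms (positive = right first).
#' @param response Responses: `"left"`/`"right"` strings, or 0/1 with
#'   1 = right first.
#' @return An object of class `psychfit` with elements `beta0`, `beta1`
#'   (per-ms slope), `n_trials`, `converged`, `reason`, `loglik`.
#' @examples
#' set.seed(1)
#' soa <- rep(c(-100, -50, -20, 20, 50, 100), each = 10)
#' y <- rbinom(length(soa), 1, plogis(soa / 40))
#' fit_psychometric(soa, y)
#' @export
fit_psychometric <- function(signed_soa, response) {
  y <- if (is.character(response) || is.factor(response))
    as.integer(as.character(response) == "right") else as.integer(response)
  ok <- is.finite(signed_soa) & !is.na(y)
  x <- signed_soa[ok]; y <- y[ok]
  out <- structure(list(beta0 = NA_real_, beta1 = NA_real_,
                        n_trials = length(y), converged = FALSE,
                        reason = NULL, loglik = NA_real_, data = list(x = x, y = y)),
                   class = "psychfit")
  if (length(unique(x)) < 2L) { out$reason <- "fewer than 2 distinct SOA levels"; return(out) }
  if (length(unique(y)) < 2L) { out$reason <- "one response class only"; return(out) }
  # complete separation: the classes do not overlap on the SOA axis
  if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) {
    out$reason <- "complete separation"; return(out)
  }
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  out$beta0 <- unname(fit$coefficients[1])
  out$beta1 <- unname(fit$coefficients[2])
  out$loglik <- -fit$deviance / 2
  if (!fit$converged) { out$reason <- "IRLS did not converge"; return(out) }
  if (fit$boundary || abs(out$beta1) > 10) {
    # a slope of 10/ms means a 0.1 ms JND: quasi-separation in practice
    out$reason <- "quasi-separation (boundary fit)"; return(out)
  }
  out$converged <- TRUE
  out
}

#' @export
print.psychfit <- function(x, ...) {
  cat("Logistic psychometric fit\n")
  cat(sprintf("  beta0 = %.4f, beta1 = %.6f /ms, n = %d, logLik = %.3f\n",
              x$beta0, x$beta1, x$n_trials, x$loglik))
  if (!x$converged) cat("  NOT converged:", x$reason, "\n")
  else cat(sprintf("  JND = %.2f ms, PSS = %.2f ms\n",
                   log(3) / x$beta1, -x$beta0 / x$beta1))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) c(beta0 = object$beta0, beta1 = object$beta1)

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n_trials, class = "logLik")
}

#' @export
predict.psychfit <- function(object, signed_soa = NULL, ...) {
  if (is.null(signed_soa)) signed_soa <- object$data$x
  stats::plogis(object$beta0 + object$beta1 * signed_soa)
}

#' @export
plot.psychfit <- function(x, ...) {
  agg <- stats::aggregate(x$data$y, list(soa = x$data$x), mean)
  grid <- seq(min(agg$soa), max(agg$soa), length.out = 200)
  plot(agg$soa, agg$x, xlab = "signed SOA (ms)",
       ylab = "P(right first)", ylim = c(0, 1), ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(h = c(0.25, 0.5, 0.75), lty = 3, col = "grey")
  invisible(x)
}

#' Derive JND and PSS from a psychometric fit
#'
#' The JND is half the SOA distance between the 0.25 and 0.75 points of the
#' fitted curve, which for the logistic model has the closed form
#' `log(3) / beta1`; the PSS is the SOA of the 0.50 point, `-beta0 / beta1`.
#' Both are in ms. A non-positive slope produces estimates that are flagged
#' rather than dropped -- downstream robust screening decides their fate.
#'
#' @param fit A converged [fit_psychometric()] result.
#' @return List with `jnd`, `pss` (ms) and `flagged`.
#' @examples
#' f <- structure(list(beta0 = 0, beta1 = log(3) / 50, converged = TRUE),
#'                class = "psychfit")
#' derive_estimates(f)  # JND 50 ms, PSS 0 ms
#' @export
derive_estimates <- function(fit) {
  stopifnot(inherits(fit, "psychfit"))
  if (!fit$converged) stop("estimates require a converged fit")
  list(jnd = log(3) / fit$beta1,
       pss = -fit$beta0 / fit$beta1,
       flagged = fit$beta1 <= 0)
}

# internal: one grouping's records, tolerant of failed fits
fit_value <- function(x, y) {
  f <- fit_psychometric(x, y)
  if (f$converged) {
    d <- derive_estimates(f)
    list(jnd = d$jnd, pss = d$pss, n = f$n_trials,
         converged = TRUE, flagged = d$flagged)
  } else list(jnd = NA_real_, pss = NA_real_, n = f$n_trials,
              converged = FALSE, flagged = TRUE)
}

#' Estimate JND and PSS records for a full study
#'
#' Reproduces the per-run model set of the measurement design: within each
#' participant x session x phase x condition cell, one pooled-cue logistic
#' fit yields the JND (12 per complete 3-session participant), and one fit
#' per cue side yields the left- and right-cued PSS (24 per participant).
#' The cued-PSS distance per cell is `PSS(left-cued) - PSS(right-cued)`
#' (positive = prior entry towards the cued side). Missing runs simply have
#' no records; non-converged or negative-slope fits yield flagged records.
#'
#' @param trials Trial data frame with columns `participant`, `session`,
#'   `phase`, `condition`, `cue_side`, `signed_soa_ms`, `response`.
#' @return Data frame of estimate records: `participant`, `session`,
#'   `phase`, `condition`, `cue_side` (`"left"`, `"right"` or `"pooled"`),
#'   `kind` (`"JND"`, `"PSS"`, `"PSS_distance"`), `value`, `n_trials`,
#'   `converged`, `flagged`.
#' @export
estimate_study <- function(trials) {
  need <- c("participant", "session", "phase", "condition",
            "cue_side", "signed_soa_ms", "response")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  key <- paste(trials$participant, trials$session, trials$phase, trials$condition,
               sep = "\r")
  groups <- split(seq_len(nrow(trials)), key)
  n_rec <- length(groups) * 4L
  participant <- session <- value <- n_trials <- numeric(n_rec)
  phase <- condition <- cue_side <- kind <- character(n_rec)
  converged <- flagged <- logical(n_rec)
  k <- 0L
  put <- function(i1, side, what, v, n, conv, flag) {
    k <<- k + 1L
    participant[k] <<- trials$participant[i1]
    session[k] <<- trials$session[i1]
    phase[k] <<- trials$phase[i1]; condition[k] <<- trials$condition[i1]
    cue_side[k] <<- side; kind[k] <<- what
    value[k] <<- v; n_trials[k] <<- n
    converged[k] <<- conv; flagged[k] <<- flag
  }
  for (idx in groups) {
    x <- trials$signed_soa_ms[idx]; y <- trials$response[idx]
    jf <- fit_value(x, y)
    put(idx[1L], "pooled", "JND", jf$jnd, jf$n, jf$converged, jf$flagged)
    side_fits <- list()
    for (side in c("left", "right")) {
      sel <- trials$cue_side[idx] == side
      sf <- fit_value(x[sel], y[sel])
      side_fits[[side]] <- sf
      put(idx[1L], side, "PSS", sf$pss, sf$n, sf$converged, sf$flagged)
    }
    put(idx[1L], "pooled", "PSS_distance",
        side_fits$left$pss - side_fits$right$pss,
        side_fits$left$n + side_fits$right$n,
        side_fits$left$converged && side_fits$right$converged,
        side_fits$left$flagged || side_fits$right$flagged)
  }
  data.frame(participant = participant, session = session, phase = phase,
             condition = condition, cue_side = cue_side, kind = kind,
             value = value, n_trials = n_trials, converged = converged,
             flagged = flagged, stringsAsFactors = FALSE)
}
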
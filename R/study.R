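#' Study generator configuration
#'
#' Defines the generative conditions of a simulated multi-session TOJ/flow
#' study: participants complete, in each of `n_sessions` sessions, a pre and
#' a post TOJ run (each containing an endogenous and an exogenous staircase
#' block) around a sport/music performance, followed by the AFSS flow
#' questionnaire. A session-level latent flow state moderates the pre-to-post
#' change of the JND and of the cued-PSS distance.
#'
#' The generative laws, per participant `i`, session `s`, condition `c`
#' (0 = endogenous, 1 = exogenous) and phase `p` (0 = pre, 1 = post):
#' \deqn{f_{is} \sim N(\mu_f, \sigma_f^2) \ \mathrm{truncated\ to}\ [1,5]}
#' \deqn{JND_{iscp} = \mu_{JND} + u_i + v_{is} + c\,\beta_c + p\{\delta +
#'   \gamma_{JND}(f_{is}-\mu_f)\} + e_{iscp}}
#' with \eqn{u_i \sim N(0,\sigma_u^2)}, \eqn{v_{is} \sim N(0,\sigma_v^2)},
#' \eqn{e \sim N(0,\sigma^2)} pre and \eqn{N(0,\kappa\sigma^2)} post. The
#' cued-PSS distance follows the analogous two-level law with a per-subject
#' random intercept and random condition slope (covariance `pss_cov`).
#' Each generated JND maps to an observer logistic scale
#' `scale_s = JND/log(3)`; each PSS distance maps to a cue shift of half the
#' distance (the left-cued PSS sits at `+shift`, the right-cued at `-shift`).
#' Draws implying a non-positive `scale_s` are resampled (residual redrawn)
#' and counted, never clamped.
#'
#' Defaults are the study conditions the generator emulates: 27 participants
#' (11 athletes, 16 musicians), 3 sessions, grand-mean JND 53.3 ms with
#' variance components 331.62 (subject), 152.93 (session-in-subject) and
#' 343.18 ms^2 (residual); pre-to-post main shift -5.36 ms and condition
#' offset 10.42 ms for the JND; PSS-distance law 41.12 + 64.12 c + 6.84 p
#' with components 153.05 / 1427.08 / 373.90 / 2053.72; moderation slopes
#' `gamma_jnd = -5.8` and `gamma_pss = -21.31` ms per flow unit; flow mean
#' 3.43, SD 0.7 on the 1-5 Likert scale; a 5/162 chance that any
#' (participant, session, phase) run is lost to dropout.
#'
#' @param n_participants,n_sessions Sample structure.
#' @param n_athletes Number of participants labelled `athlete` (the rest are
#'   `musician`); domain does not enter the generative laws by default.
#' @param mu_jnd,delta_jnd,cond_jnd Grand-mean pre-endogenous JND, pre-to-post
#'   main shift and exogenous condition offset, ms.
#' @param gamma_jnd,gamma_pss Cross-level moderation: ms of pre-to-post change
#'   per unit of (centred) flow.
#' @param var_subject,var_session,var_residual JND variance components, ms^2.
#' @param mu_pss,delta_pss,cond_pss PSS-distance law: pre-endogenous mean,
#'   pre-to-post main shift, exogenous offset, ms.
#' @param pss_var_subject,pss_var_cond,pss_cov,pss_var_residual PSS-distance
#'   variance components (subject intercept, subject condition slope, their
#'   covariance, residual), ms^2.
#' @param flow_mean,flow_sd Latent session flow distribution (truncated
#'   normal on `[1, 5]`).
#' @param sigma_item AFSS item noise SD (Likert units), see [generate_afss()].
#' @param sigma_control Control-question noise SD (Likert units).
#' @param lapse Observer lapse rate used in staircase simulation.
#' @param kappa Post-phase residual variance inflation factor.
#' @param dropout_rate Probability that a (participant, session, phase) run
#'   is missing.
#' @param seed Integer seed; per-participant streams are forked from it so
#'   that dropping or reordering participants leaves the others unchanged.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_participants = 27, n_sessions = 3,
                         n_athletes = round(11 / 27 * n_participants),
                         mu_jnd = 53.3, delta_jnd = -5.36, cond_jnd = 10.42,
                         gamma_jnd = -5.8, gamma_pss = -21.31,
                         var_subject = 331.62, var_session = 152.93,
                         var_residual = 343.18,
                         mu_pss = 41.12, delta_pss = 6.84, cond_pss = 64.12,
                         pss_var_subject = 153.05, pss_var_cond = 1427.08,
                         pss_cov = 373.90, pss_var_residual = 2053.72,
                         flow_mean = 3.43, flow_sd = 0.7,
                         sigma_item = 0.7, sigma_control = 1.0,
                         lapse = 0.02, kappa = 1,
                         dropout_rate = 5 / 162, seed = 1L) {
  vars <- c(var_subject, var_session, var_residual,
            pss_var_subject, pss_var_cond, pss_var_residual)
  if (any(!is.finite(vars)) || any(vars < 0)) stop("variances must be >= 0")
  if (pss_cov^2 > pss_var_subject * pss_var_cond)
    stop("'pss_cov' implies an invalid covariance matrix")
  if (n_sessions < 1) stop("'n_sessions' must be >= 1")
  if (flow_mean < 1 || flow_mean > 5) stop("'flow_mean' must lie in [1, 5]")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("'dropout_rate' must lie in [0, 1)")
  if (n_athletes < 0 || n_athletes > n_participants) stop("invalid 'n_athletes'")
  structure(as.list(environment())[names(formals(study_config))],
            class = "study_config")
}

# truncated-normal draws on [lo, hi] by inversion
rtruncnorm <- function(n, mean, sd, lo = 1, hi = 5) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate AFSS questionnaire responses for one respondent
#'
#' Items are noisy Likert readouts of the latent session flow state:
#' `item_j = clip(round(f + eta_j), 1, 5)` with
#' `eta_j ~ N(0, sigma_item^2)`. The mean of the 26 items is then a
#' consistent estimator of the latent flow (rounding is unbiased to high
#' accuracy for noise SDs of this size, and clipping bias is negligible away
#' from the scale ends). The control question uses the same readout model
#' with its own noise SD.
#'
#' @param latent_flow Latent flow on the 1-5 scale.
#' @param sigma_item Item noise SD.
#' @param sigma_control Control-question noise SD.
#' @param n_items Number of scale items.
#' @return List with `items` (integer vector in 1..5) and `control_q`.
#' @examples
#' set.seed(1)
#' generate_afss(3.4)
#' @export
generate_afss <- function(latent_flow, sigma_item = 0.7, sigma_control = 1.0,
                          n_items = 26L) {
  if (!is.finite(latent_flow) || latent_flow < 1 || latent_flow > 5)
    stop("'latent_flow' must lie in [1, 5]")
  clip15 <- function(x) as.integer(pmin(pmax(round(x), 1), 5))
  list(items = clip15(latent_flow + stats::rnorm(n_items, 0, sigma_item)),
       control_q = clip15(latent_flow + stats::rnorm(1, 0, sigma_control)))
}

# Draw one run-level value from mean m and residual sd, resampling the
# residual while the implied observer parameter would be non-positive.
resample_pos <- function(m, sd, counter_env) {
  x <- m + stats::rnorm(1, 0, sd)
  tries <- 0L
  while (x <= 0) {
    tries <- tries + 1L
    if (tries > 1000L) stop("generative configuration implies non-positive scale_s; cannot resample")
    x <- m + stats::rnorm(1, 0, sd)
  }
  if (tries > 0L) counter_env$n <- counter_env$n + tries
  x
}

#' Generate a full synthetic TOJ/flow study
#'
#' Simulates the study defined by a [study_config()]: latent flow per
#' session, true run-level JNDs and cued-PSS distances following the
#' config's hierarchical laws, AFSS questionnaire responses, domain labels,
#' and -- in `measurement = "staircase"` mode -- full adaptive-staircase
#' trial data for every (participant, session, phase, condition) block,
#' simulated by running the implied observer through [run_block()].
#'
#' With `measurement = "direct"` the true run-level parameters are returned
#' as estimate records directly (no trial simulation, no psychometric
#' fitting); this mode observes the generative laws without measurement
#' error and is intended for estimator-calibration studies of the modelling
#' stage.
#'
#' A `dropout_rate` fraction of (participant, session, phase) runs is
#' deleted, emulating participant dropout.
#'
#' @param cfg A [study_config()].
#' @param measurement `"staircase"` (simulate trials) or `"direct"`.
#' @param staircase A [staircase_config()].
#' @return An object of class `toj_study`: a list with elements
#'   `trials` (data frame, or `NULL` in direct mode), `questionnaire`,
#'   `design` (participant/domain), `truth` (latent flow and true run
#'   parameters), `estimates` (direct mode only), `missing_runs`,
#'   `n_resampled`, `config`.
#' @export
generate_study <- function(cfg = study_config(),
                           measurement = c("staircase", "direct"),
                           staircase = staircase_config()) {
  stopifnot(inherits(cfg, "study_config"))
  measurement <- match.arg(measurement)
  n_i <- cfg$n_participants; n_s <- cfg$n_sessions
  domain <- rep(c("athlete", "musician"),
                c(cfg$n_athletes, n_i - cfg$n_athletes))
  resamples <- new.env(); resamples$n <- 0L
  # covariance factor for the PSS random effects (intercept, condition slope)
  Sig <- matrix(c(cfg$pss_var_subject, cfg$pss_cov,
                  cfg$pss_cov, cfg$pss_var_cond), 2)
  L <- chol(Sig + diag(1e-12, 2))
  trials <- list(); quest <- list(); truth <- list(); est <- list()
  for (i in seq_len(n_i)) {
    # forked per-participant stream: other participants' data are invariant
    # to dropping/reordering this one
    set.seed((cfg$seed + 7919L * i) %% 2147483647L)
    u_i <- stats::rnorm(1, 0, sqrt(cfg$var_subject))
    ab <- drop(crossprod(L, stats::rnorm(2)))  # PSS intercept/slope effects
    for (s in seq_len(n_s)) {
      f_is <- rtruncnorm(1, cfg$flow_mean, cfg$flow_sd)
      v_is <- stats::rnorm(1, 0, sqrt(cfg$var_session))
      afss <- generate_afss(f_is, cfg$sigma_item, cfg$sigma_control)
      quest[[length(quest) + 1L]] <-
        c(participant = i, session = s, afss$items, control_q = afss$control_q)
      for (p in 0:1) {
        sd_j <- sqrt(cfg$var_residual * if (p == 1) cfg$kappa else 1)
        sd_d <- sqrt(cfg$pss_var_residual * if (p == 1) cfg$kappa else 1)
        for (cc in 0:1) {
          m_jnd <- cfg$mu_jnd + u_i + v_is + cc * cfg$cond_jnd +
            p * (cfg$delta_jnd + cfg$gamma_jnd * (f_is - cfg$flow_mean))
          jnd <- resample_pos(m_jnd, sd_j, resamples)
          dist <- cfg$mu_pss + ab[1] + cc * (cfg$cond_pss + ab[2]) +
            p * (cfg$delta_pss + cfg$gamma_pss * (f_is - cfg$flow_mean)) +
            stats::rnorm(1, 0, sd_d)
          cond <- c("endogenous", "exogenous")[cc + 1L]
          phase <- c("pre", "post")[p + 1L]
          truth[[length(truth) + 1L]] <- data.frame(
            participant = i, session = s, phase = phase, condition = cond,
            latent_flow = f_is, true_jnd = jnd, true_pss_distance = dist,
            stringsAsFactors = FALSE)
          if (measurement == "staircase") {
            obs <- toj_observer(scale_s = jnd / log(3), lapse = cfg$lapse,
                                shift_exo = dist / 2, shift_endo = dist / 2)
            blk <- run_block(obs, cond, staircase)
            blk$participant <- i; blk$session <- s
            blk$phase <- phase; blk$condition <- cond
            blk$block <- paste(phase, cond, sep = "_")
            trials[[length(trials) + 1L]] <- blk
          } else {
            est[[length(est) + 1L]] <- data.frame(
              participant = i, session = s, phase = phase, condition = cond,
              cue_side = "pooled", kind = c("JND", "PSS_distance"),
              value = c(jnd, dist), n_trials = NA_integer_,
              converged = TRUE, flagged = FALSE, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  quest <- as.data.frame(do.call(rbind, quest))
  names(quest) <- c("participant", "session", paste0("item_", 1:26), "control_q")
  truth <- do.call(rbind, truth)
  trials <- if (length(trials)) do.call(rbind, trials) else NULL
  est <- if (length(est)) do.call(rbind, est) else NULL

  # dropout of whole (participant, session, phase) runs
  set.seed((cfg$seed + 104729L) %% 2147483647L)
  runs <- unique(truth[c("participant", "session", "phase")])
  drop_idx <- which(stats::runif(nrow(runs)) < cfg$dropout_rate)
  missing_runs <- runs[drop_idx, , drop = FALSE]
  rownames(missing_runs) <- NULL
  if (nrow(missing_runs)) {
    key <- function(d) paste(d$participant, d$session, d$phase)
    bad <- key(missing_runs)
    if (!is.null(trials)) trials <- trials[!(key(trials) %in% bad), ]
    if (!is.null(est)) est <- est[!(key(est) %in% bad), ]
  }
  if (!is.null(trials)) {
    trials <- trials[c("participant", "session", "phase", "condition",
                       "block", "trial", "cue_side", "first_side",
                       "orientation", "signed_soa_ms", "response", "correct")]
    rownames(trials) <- NULL
  }
  structure(list(trials = trials, questionnaire = quest,
                 design = data.frame(participant = seq_len(n_i),
                                     domain = domain,
                                     stringsAsFactors = FALSE),
                 truth = truth, estimates = est,
                 missing_runs = missing_runs,
                 n_resampled = resamples$n, config = cfg),
            class = "toj_study")
}

#' @export
print.toj_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic TOJ/flow study: %d participants x %d sessions\n",
              cfg$n_participants, cfg$n_sessions))
  if (!is.null(x$trials))
    cat(sprintf("  %d staircase trials in %d blocks\n", nrow(x$trials),
                length(unique(paste(x$trials$participant, x$trials$session,
                                    x$trials$block)))))
  else cat("  direct-measurement mode (no trial data)\n")
  cat(sprintf("  %d missing runs (dropout), %d resampled residual draws\n",
              nrow(x$missing_runs), x$n_resampled))
  invisible(x)
}

#' Write a study to CSV files
#'
#' Writes the trial table (`trials.csv`), the questionnaire table
#' (`questionnaire.csv`) and a sidecar metadata file (`study_meta.yaml`)
#' recording the seed and generator configuration.
#'
#' @param study A `toj_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "toj_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(study$trials)) {
    p <- file.path(dir, "trials.csv")
    utils::write.csv(study$trials, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  qp <- file.path(dir, "questionnaire.csv")
  utils::write.csv(study$questionnaire, qp, row.names = FALSE)
  mp <- file.path(dir, "study_meta.yaml")
  yaml::write_yaml(list(seed = study$config$seed,
                        config = unclass(study$config)), mp)
  invisible(c(paths, qp, mp))
}
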
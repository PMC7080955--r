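#' Construct a TOJ observer
#'
#' An observer for a two-alternative temporal order judgement (TOJ) task is
#' described by a logistic temporal discrimination scale, a lapse rate, and a
#' condition-specific prior-entry shift of the point of subjective
#' simultaneity (PSS) towards the cued side.
#'
#' The implied just noticeable difference (JND) of the observer is
#' `scale_s * log(3)`: the half-distance between the stimulus onset
#' asynchronies (SOAs) at which the observer responds "right first" with
#' probability 0.25 and 0.75.
#'
#' @param scale_s Logistic scale of temporal discrimination, in ms. Must be
#'   positive and finite.
#' @param lapse Lapse probability in `[0, 0.1]`: on a lapsed trial the
#'   observer guesses either side with probability 1/2.
#' @param shift_exo PSS shift (ms) induced by an exogenous (peripheral) cue.
#'   Positive values shift perception towards the cued side (prior entry);
#'   negative values are admitted so that generative models with Gaussian
#'   variation in the shift remain well defined.
#' @param shift_endo PSS shift (ms) induced by an endogenous (central) cue.
#' @return An object of class `toj_observer`.
#' @examples
#' obs <- toj_observer(scale_s = 50 / log(3), lapse = 0.02, shift_exo = 20)
#' obs$scale_s * log(3)  # implied JND, 50 ms
#' @export
toj_observer <- function(scale_s, lapse = 0, shift_exo = 0, shift_endo = 0) {
  stopifnot(is.numeric(scale_s), length(scale_s) == 1L)
  if (!is.finite(scale_s) || scale_s <= 0)
    stop("'scale_s' must be positive and finite (implied JND = scale_s*log(3))")
  if (!is.finite(lapse) || lapse < 0 || lapse > 0.1)
    stop("'lapse' must lie in [0, 0.1]")
  if (!is.finite(shift_exo) || !is.finite(shift_endo))
    stop("cue shifts must be finite")
  structure(list(scale_s = scale_s, lapse = lapse,
                 shift_exo = shift_exo, shift_endo = shift_endo),
            class = "toj_observer")
}

#' @export
print.toj_observer <- function(x, ...) {
  cat("TOJ observer\n")
  cat(sprintf("  scale_s: %.3f ms (implied JND %.2f ms)\n",
              x$scale_s, x$scale_s * log(3)))
  cat(sprintf("  lapse:   %.3f\n", x$lapse))
  cat(sprintf("  PSS shift: exogenous %.2f ms, endogenous %.2f ms\n",
              x$shift_exo, x$shift_endo))
  invisible(x)
}

#' Construct a stimulus event
#'
#' One TOJ trial presentation: which side carries the first target, which
#' side is cued, the cue condition, and the unsigned SOA. The signed SOA
#' follows the convention positive = right target first.
#'
#' @param first_side `"left"` or `"right"`: side of the first target.
#' @param cue_side `"left"` or `"right"`: cued side.
#' @param condition `"endogenous"` or `"exogenous"`.
#' @param soa Unsigned SOA magnitude in ms (at least one display frame).
#' @return A list of class `toj_event` with `signed_soa = +soa` when the
#'   right target leads, `-soa` otherwise.
#' @export
stimulus_event <- function(first_side, cue_side, condition, soa) {
  first_side <- match.arg(first_side, c("left", "right"))
  cue_side <- match.arg(cue_side, c("left", "right"))
  condition <- match.arg(condition, c("endogenous", "exogenous"))
  if (!is.finite(soa) || soa <= 0) stop("'soa' must be a positive magnitude")
  structure(list(first_side = first_side, cue_side = cue_side,
                 condition = condition, soa = soa,
                 signed_soa = if (first_side == "right") soa else -soa),
            class = "toj_event")
}

#' Probability of a "right first" response
#'
#' Closed-form response probability of an observer for a stimulus event:
#' \deqn{P(\mathrm{right\ first}) = \lambda/2 + (1-\lambda)\,
#'   \Lambda\{(\mathrm{SOA}_{signed} - \mu_{cue})/s\}}
#' where \eqn{\Lambda} is the standard logistic CDF and \eqn{\mu_{cue}} is
#' `-shift` for a right cue and `+shift` for a left cue (prior entry: the
#' cued side needs less of a head start to be seen first).
#'
#' @param obs A [toj_observer()].
#' @param signed_soa Signed SOA in ms (positive = right first); vectorised.
#' @param cue_side `"left"` or `"right"`.
#' @param condition `"endogenous"` or `"exogenous"`.
#' @return Vector of probabilities.
#' @export
response_prob <- function(obs, signed_soa, cue_side, condition) {
  stopifnot(inherits(obs, "toj_observer"))
  shift <- if (condition == "exogenous") obs$shift_exo else obs$shift_endo
  mu <- if (cue_side == "right") -shift else shift
  obs$lapse / 2 + (1 - obs$lapse) * stats::plogis((signed_soa - mu) / obs$scale_s)
}

#' Simulate one TOJ response
#'
#' Draws a "left"/"right" response from the observer's response probability
#' (see [response_prob()]) and flags correctness against the side of the
#' first target.
#'
#' @param obs A [toj_observer()].
#' @param ev A [stimulus_event()].
#' @return List with `response` (`"left"`/`"right"`) and `correct` (logical).
#' @examples
#' set.seed(1)
#' obs <- toj_observer(scale_s = 50 / log(3))
#' ev <- stimulus_event("right", "left", "exogenous", soa = 100)
#' simulate_response(obs, ev)
#' @export
simulate_response <- function(obs, ev) {
  stopifnot(inherits(ev, "toj_event"))
  p <- response_prob(obs, ev$signed_soa, ev$cue_side, ev$condition)
  resp <- if (stats::runif(1) < p) "right" else "left"
  list(response = resp, correct = resp == ev$first_side)
}
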
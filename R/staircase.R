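#' Staircase configuration
#'
#' Parameters of the 1-up-n-down reversal-terminated adaptive staircase that
#' controls the SOA magnitude during a TOJ block. Defaults reproduce a block
#' that starts at 267 ms (16 frames on a 60 Hz display), steps by one frame
#' (16.7 ms) after each error (up) or after `n_down` consecutive correct
#' responses (down), and terminates after 14 reversals.
#'
#' The SOA floor is one display frame (at SOA 0 "correct" is undefined); the
#' ceiling bounds random-guessing walks. `soa_start` and `step` must sit on
#' the frame grid up to print resolution (a tolerance of 0.025 frames
#' accommodates rounded millisecond values such as 267 for 16 frames).
#'
#' @param soa_start Starting SOA magnitude, ms.
#' @param step Step size, ms.
#' @param n_down Consecutive correct responses required for a downward step.
#' @param n_up Errors required for an upward step (1 in the 1-up rule).
#' @param max_reversals Reversal count terminating the block.
#' @param soa_min,soa_max SOA bounds, ms.
#' @param frame_ms Display frame duration, ms.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(soa_start = 267, step = 16.7, n_down = 3,
                             n_up = 1, max_reversals = 14,
                             soa_min = 16.7, soa_max = 500, frame_ms = 16.7) {
  on_grid <- function(x) abs(x / frame_ms - round(x / frame_ms)) < 0.025
  if (!on_grid(soa_start) || !on_grid(step))
    stop("'soa_start' and 'step' must be multiples of 'frame_ms' (within print tolerance)")
  if (soa_min < frame_ms) stop("'soa_min' must be at least one frame")
  if (max_reversals < 1) stop("'max_reversals' must be >= 1")
  if (n_down < 1 || n_up != 1) stop("only 1-up-n-down rules are supported")
  structure(list(soa_start = soa_start, step = step, n_down = n_down,
                 n_up = n_up, max_reversals = max_reversals,
                 soa_min = soa_min, soa_max = soa_max, frame_ms = frame_ms),
            class = "staircase_config")
}

#' Initial staircase state
#'
#' @param cfg A [staircase_config()].
#' @return An object of class `staircase_state` holding the current SOA,
#'   the correct-response streak, the last applied move, the reversal count
#'   and the termination flag.
#' @export
staircase_init <- function(cfg = staircase_config()) {
  structure(list(soa = cfg$soa_start, correct_streak = 0L,
                 last_move = "none", reversals = 0L, terminated = FALSE),
            class = "staircase_state")
}

#' Advance the staircase by one trial outcome
#'
#' Applies the 1-up-n-down rule: an incorrect response raises the SOA by one
#' step and resets the streak; the `n_down`-th consecutive correct response
#' lowers it. The SOA is clamped to `[soa_min, soa_max]`; a move fully
#' absorbed by the clamp is a non-move and neither updates the move
#' direction nor can create a reversal. A reversal is counted whenever an
#' applied move differs in direction from the previous applied move; the
#' block terminates when `max_reversals` is reached (the triggering trial is
#' the last of the block).
#'
#' @param state A `staircase_state`.
#' @param correct Logical: was the response correct?
#' @param cfg A [staircase_config()].
#' @return Updated `staircase_state`.
#' @examples
#' st <- staircase_init()
#' staircase_update(st, correct = FALSE)$soa  # 267 + 16.7
#' @export
staircase_update <- function(state, correct, cfg = staircase_config()) {
  if (state$terminated) stop("staircase already terminated; no further updates allowed")
  move <- "none"
  if (!correct) {
    new_soa <- min(state$soa + cfg$step, cfg$soa_max)
    if (new_soa != state$soa) move <- "up"
    state$soa <- new_soa
    state$correct_streak <- 0L
  } else {
    state$correct_streak <- state$correct_streak + 1L
    if (state$correct_streak == cfg$n_down) {
      new_soa <- max(state$soa - cfg$step, cfg$soa_min)
      if (new_soa != state$soa) move <- "down"
      state$soa <- new_soa
      state$correct_streak <- 0L
    }
  }
  if (move != "none") {
    if (state$last_move != "none" && move != state$last_move)
      state$reversals <- state$reversals + 1L
    state$last_move <- move
  }
  if (state$reversals >= cfg$max_reversals) state$terminated <- TRUE
  state
}

#' Run one adaptive staircase block for a simulated observer
#'
#' Simulates a full TOJ block: on every trial the first-target side and the
#' cue side are drawn independently with probability 1/2 each, the target
#' orientation (horizontal/vertical, recorded but unused by the analysis) is
#' drawn likewise, the unsigned SOA is taken from the staircase state, the
#' observer's response is simulated, and the state is updated with the
#' correctness flag. The block ends when the reversal criterion is met.
#'
#' @param obs A [toj_observer()].
#' @param condition `"endogenous"` or `"exogenous"`.
#' @param cfg A [staircase_config()].
#' @param max_trials Abort guard: observers that never terminate (for
#'   example error-free ideal observers, which produce no upward moves and
#'   hence no reversals) raise an error after this many trials.
#' @return A data frame of trials with columns `trial`, `cue_side`,
#'   `first_side`, `orientation`, `signed_soa_ms`, `response`, `correct`.
#' @export
run_block <- function(obs, condition = "endogenous", cfg = staircase_config(),
                      max_trials = 10000L) {
  stopifnot(inherits(obs, "toj_observer"))
  condition <- match.arg(condition, c("endogenous", "exogenous"))
  shift <- if (condition == "exogenous") obs$shift_exo else obs$shift_endo
  st <- staircase_init(cfg)
  n <- 0L
  cap <- 512L
  cue <- first <- resp <- integer(cap)  # 1 = right, 0 = left
  orient <- integer(cap)                # 1 = vertical, 0 = horizontal
  ssoa <- numeric(cap)
  corr <- logical(cap)
  lapse <- obs$lapse; s <- obs$scale_s
  while (!st$terminated) {
    n <- n + 1L
    if (n > max_trials)
      stop(sprintf(
        "staircase did not terminate within %d trials (pathological observer: reversals=%d, soa=%.1f)",
        max_trials, st$reversals, st$soa))
    if (n > cap) {
      cap <- cap * 2L
      length(cue) <- cap; length(first) <- cap; length(resp) <- cap
      length(orient) <- cap; length(ssoa) <- cap; length(corr) <- cap
    }
    u <- stats::runif(4L)
    first[n] <- (u[1L] < 0.5)
    cue[n] <- (u[2L] < 0.5)
    orient[n] <- (u[3L] < 0.5)
    x <- if (first[n] == 1L) st$soa else -st$soa
    mu <- if (cue[n] == 1L) -shift else shift
    p <- lapse / 2 + (1 - lapse) * stats::plogis((x - mu) / s)
    resp[n] <- (u[4L] < p)
    ssoa[n] <- x
    corr[n] <- resp[n] == first[n]
    st <- staircase_update(st, corr[n], cfg)
  }
  side <- c("left", "right")
  data.frame(trial = seq_len(n),
             cue_side = side[cue[1:n] + 1L],
             first_side = side[first[1:n] + 1L],
             orientation = c("horizontal", "vertical")[orient[1:n] + 1L],
             signed_soa_ms = ssoa[1:n],
             response = side[resp[1:n] + 1L],
             correct = corr[1:n],
             stringsAsFactors = FALSE)
}
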
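# Shared fixtures: small observers and study configurations used across
# the suite. All randomness in tests is seeded locally with withr-free
# base set.seed() calls.

default_observer <- function(jnd = 50, lapse = 0, shift_exo = 0,
                             shift_endo = 0) {
  toj_observer(scale_s = jnd / log(3), lapse = lapse,
               shift_exo = shift_exo, shift_endo = shift_endo)
}

# a small study that keeps staircase-mode tests fast
small_config <- function(seed = 1L, ...) {
  study_config(n_participants = 6, n_sessions = 2, dropout_rate = 0,
               seed = seed, ...)
}

# simulate binary responses on a fixed SOA grid (bypasses the staircase)
grid_trials <- function(obs, soas, n_each, cue_side = "left",
                        condition = "endogenous") {
  x <- rep(soas, each = n_each)
  p <- response_prob(obs, x, cue_side, condition)
  y <- as.integer(stats::runif(length(x)) < p)
  data.frame(signed_soa_ms = x, response = y)
}

# exhaustive grid-search maximiser of the Bernoulli logistic likelihood,
# independent of the IRLS path: coarse pass then refinement to `step`
grid_mle <- function(x, y, step = 1e-3) {
  ll <- function(b0, b1) {
    p <- stats::plogis(b0 + b1 * x)
    sum(y * log(p) + (1 - y) * log1p(-p))
  }
  best <- c(0, 0)
  rng0 <- seq(-2, 2, by = 0.05); rng1 <- seq(-0.1, 0.1, by = 0.002)
  for (pass in 1:3) {
    vals <- outer(rng0, rng1, Vectorize(ll))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    best <- c(rng0[ix[1]], rng1[ix[2]])
    w0 <- diff(range(rng0)) / 10; w1 <- diff(range(rng1)) / 10
    rng0 <- seq(best[1] - w0, best[1] + w0, by = max(step, w0 / 40))
    rng1 <- seq(best[2] - w1, best[2] + w1, by = max(step / 10, w1 / 40))
  }
  # final pass exactly on the requested grid step
  rng0 <- seq(best[1] - 20 * step, best[1] + 20 * step, by = step)
  rng1 <- seq(best[2] - 20 * step / 10, best[2] + 20 * step / 10, by = step / 10)
  vals <- outer(rng0, rng1, Vectorize(ll))
  ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  c(beta0 = rng0[ix[1]], beta1 = rng1[ix[2]])
}
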
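test_that("the study layout matches the design grid", {
  st <- generate_study(small_config(seed = 2))
  tr <- st$trials
  expect_true(all(tr$condition %in% c("endogenous", "exogenous")))
  expect_true(all(tr$phase %in% c("pre", "post")))
  blocks <- unique(tr[c("participant", "session", "phase", "condition")])
  expect_equal(nrow(blocks), 6 * 2 * 2 * 2)  # participants x sessions x phases x conditions
  expect_equal(nrow(st$questionnaire), 6 * 2)
  expect_equal(table(st$design$domain)[["athlete"]], round(11 / 27 * 6))
})

test_that("true JNDs are positive and resampling is logged, never clamping", {
  cfg <- study_config(n_participants = 10, mu_jnd = 12, var_subject = 100,
                      var_session = 50, var_residual = 200, seed = 3)
  st <- generate_study(cfg, measurement = "direct")
  expect_true(all(st$truth$true_jnd > 0))
  expect_gt(st$n_resampled, 0)
})

test_that("dropout removes whole runs at the configured expected count", {
  set.seed(1)
  n_missing <- vapply(1:200, function(r) {
    cfg <- study_config(seed = 4000 + r)
    nrow(generate_study(cfg, measurement = "direct")$missing_runs)
  }, 0)
  # rate 5/162 over 162 runs: expected 5 missing runs per study
  expect_lt(abs(mean(n_missing) - 5), 3 * stats::sd(n_missing) / sqrt(200))
  # and the removed runs really are absent from the estimate table
  cfg <- study_config(seed = 4001)
  st <- generate_study(cfg, measurement = "direct")
  if (nrow(st$missing_runs)) {
    bad <- paste(st$missing_runs$participant, st$missing_runs$session,
                 st$missing_runs$phase)
    have <- paste(st$estimates$participant, st$estimates$session,
                  st$estimates$phase)
    expect_false(any(have %in% bad))
  }
})

test_that("zero flow sensitivity makes pre and post identical in law", {
  # with no moderation, no pre-post shift and no residual inflation the
  # pre and post parameter distributions coincide
  cfg <- study_config(n_participants = 120, gamma_jnd = 0, gamma_pss = 0,
                      delta_jnd = 0, delta_pss = 0, kappa = 1,
                      dropout_rate = 0, seed = 8)
  st <- generate_study(cfg, measurement = "direct")
  tr <- st$truth
  ks1 <- suppressWarnings(stats::ks.test(tr$true_jnd[tr$phase == "pre"],
                                         tr$true_jnd[tr$phase == "post"]))
  ks2 <- suppressWarnings(stats::ks.test(
    tr$true_pss_distance[tr$phase == "pre"],
    tr$true_pss_distance[tr$phase == "post"]))
  expect_gt(ks1$p.value, 0.01)
  expect_gt(ks2$p.value, 0.01)
})

test_that("unconditional variance shares recover the generating shares", {
  # components chosen so subject/session shares are 0.15 and 0.38
  shares <- c(subject = 0.15, session = 0.38, residual = 0.47)
  tot <- 900
  reps <- 30
  got <- matrix(0, reps, 3)
  for (r in 1:reps) {
    cfg <- study_config(var_subject = shares[1] * tot,
                        var_session = shares[2] * tot,
                        var_residual = shares[3] * tot,
                        gamma_jnd = 0, delta_jnd = 0, cond_jnd = 0,
                        dropout_rate = 0, seed = 6000 + r)
    st <- generate_study(cfg, measurement = "direct")
    fl <- score_flow_table(st$questionnaire)
    md <- build_model_data(st$estimates, fl, st$design)
    u <- fit_lmm(md, "JND", fixed = character(0))
    got[r, ] <- variance_partition(u)[c("subject", "session", "residual")]
  }
  mc_se <- apply(got, 2, stats::sd) / sqrt(reps)
  expect_true(all(abs(colMeans(got) - shares) < pmax(3 * mc_se, 0.02)))
})

test_that("studies round-trip through CSV unchanged", {
  st <- generate_study(small_config(seed = 10))
  dir <- tempfile("study_")
  write_study(st, dir)
  tr2 <- utils::read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  q2 <- utils::read.csv(file.path(dir, "questionnaire.csv"),
                        stringsAsFactors = FALSE)
  expect_equal(tr2, st$trials)
  expect_equal(q2, st$questionnaire)
  meta <- yaml::read_yaml(file.path(dir, "study_meta.yaml"))
  expect_equal(meta$seed, st$config$seed)
  unlink(dir, recursive = TRUE)
})

test_that("participant streams are forked: extra participants do not perturb earlier ones", {
  a <- generate_study(study_config(n_participants = 4, dropout_rate = 0, seed = 5),
                      measurement = "direct")
  b <- generate_study(study_config(n_participants = 6, dropout_rate = 0, seed = 5),
                      measurement = "direct")
  b4 <- b$truth[b$truth$participant <= 4, ]
  rownames(b4) <- NULL
  expect_equal(a$truth, b4)
})
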
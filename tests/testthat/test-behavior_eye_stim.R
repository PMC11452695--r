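# quick behavior-only sessions
eye_session <- function(seed, eye = eye_model_spec(), n_blocks = 4, stim = FALSE,
                        ...) {
  generate_session(synthetic_config(neurons = list(), n_choice_blocks = n_blocks,
                                    n_delayed_blocks = 0, eye = eye,
                                    stimulation_session = stim,
                                    master_seed = seed, ...))
}

test_that("eye preprocessing removes offsets and preserves condition differences", {
  s <- eye_session(61)
  es <- preprocess_eye(s)
  # per-trial baseline means are ~0 by construction
  expect_lt(max(abs(rowMeans(es$per_trial[, es$t < 0]))), 1e-12)
  # adding a constant to every raw trace changes nothing (affine invariance)
  s2 <- s
  s2$eyes <- lapply(s2$eyes, function(e) { e$x_deg <- e$x_deg + 5; e })
  es2 <- preprocess_eye(s2)
  expect_equal(es2$cond_mean, es$cond_mean, tolerance = 1e-10)
  # grand-mean normalization leaves the condition difference unchanged
  diff_raw <- es$cond_mean_raw["L", ] - es$cond_mean_raw["R", ]
  diff_norm <- es$cond_mean["L", ] - es$cond_mean["R", ]
  expect_equal(diff_norm, diff_raw, tolerance = 1e-12)
})

test_that("noise-free traces reproduce the planted bias exactly", {
  s <- eye_session(62, eye = eye_model_spec(ou_sigma_deg = 0,
                                            opposite_shift_prob = 0))
  es <- preprocess_eye(s)
  plateau <- es$t > 0.17 + 0.15 + 0.02
  expect_equal(unique(round(es$cond_mean_raw["R", plateau], 10)), 0.14)
  expect_equal(unique(round(es$cond_mean_raw["L", plateau], 10)), -0.14)
})

test_that("divergence detection applies the persistence rule", {
  # crafted summaries: 12 sessions on a 240-Hz grid
  tt <- seq(-0.1, 0.5, by = 1 / 240)
  mk <- function(seed, effect) {
    set.seed(seed)
    base <- matrix(rnorm(2 * length(tt), 0, 0.02), 2)
    cm <- rbind(L = base[1, ] - effect / 2, R = base[2, ] + effect / 2)
    structure(list(t = tt, cond_mean = cm), class = "sef_eye_summary")
  }
  # a sustained effect from 0.2 s on
  eff <- ifelse(tt >= 0.2, 0.2, 0)
  sums <- lapply(1:12, function(k) mk(k, eff))
  dv <- detect_divergence(sums)
  expect_lt(abs(dv$onset_s - 0.2), 0.03)
  # a single isolated significant timepoint is ignored
  eff1 <- ifelse(abs(tt - 0.2) < 1e-9, 5, 0)
  dv1 <- detect_divergence(lapply(1:12, function(k) mk(k, eff1)))
  expect_true(is.na(dv1$onset_s))
  expect_error(detect_divergence(sums[1:2]), ">= 3")
})

test_that("zero-bias sessions rarely produce a divergence onset", {
  onsets <- vapply(1:3, function(r) {
    sums <- lapply(1:8, function(k)
      preprocess_eye(eye_session(700 + 10 * r + k,
                                 eye = eye_model_spec(bias_amp_deg = 0),
                                 n_blocks = 2)))
    detect_divergence(sums)$onset_s
  }, 1)
  expect_gte(sum(is.na(onsets)), 2)
})

test_that("shift-direction classification recovers the flip probability", {
  low_drift <- function(p) eye_model_spec(ou_sigma_deg = 0.02,
                                          opposite_shift_prob = p)
  s0 <- eye_session(63, eye = low_drift(0))
  r0 <- classify_shift_direction(preprocess_eye(s0))
  expect_gte(mean(r0$shift == r0$hemifield), 0.97)
  s3 <- eye_session(64, eye = low_drift(0.3), n_blocks = 10)
  r3 <- classify_shift_direction(preprocess_eye(s3))
  n <- length(r3$shift)
  expect_lt(abs(r3$prop_opposite - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # flat-zero traces: deterministic tie rule
  flat <- structure(list(t = c(0.1, 0.2), t_max_diff = 0.1,
                         per_trial = matrix(0, 2, 2), trial_ids = 0:1,
                         hemifield = c("L", "R")), class = "sef_eye_summary")
  rf <- classify_shift_direction(flat)
  expect_equal(rf$shift, c("R", "R"))
})

test_that("the hemifield vs eye-shift ANOVA separates the two drivers", {
  set.seed(66)
  n <- 120; W <- 30
  hemi <- sample(rep(c("L", "R"), n / 2))
  shift <- ifelse(runif(n) < 0.75, hemi, ifelse(hemi == "L", "R", "L"))
  base <- matrix(rnorm(n * W, 10, 2), n, W)
  # instruction-driven activity in windows 10-20
  act <- base; act[, 10:20] <- act[, 10:20] + 3 * (hemi == "L")
  r <- hemifield_vs_eyeshift_anova(act, hemi, shift)
  expect_true(all(r$instruction_modulated[12:18]))
  expect_lte(mean(r$eye_modulated), 0.1)
  # eye-driven activity instead
  act2 <- base; act2[, 10:20] <- act2[, 10:20] + 3 * (shift == "L")
  r2 <- hemifield_vs_eyeshift_anova(act2, hemi, shift)
  expect_true(any(r2$eye_modulated[10:20]))
  # null neuron: both families near their nominal rates
  r3 <- hemifield_vs_eyeshift_anova(base, hemi, shift)
  expect_lte(mean(r3$instruction_modulated), 0.1)
  expect_lte(mean(r3$eye_modulated), 0.1)
})

test_that("the hemifield regression is unbiased and its shuffle null is centered", {
  set.seed(67)
  n <- 120; W <- 6; b <- 0.8; sigma <- 2
  code <- rep(c(1, -1), n / 2)
  rho <- b / sqrt(b^2 + sigma^2)  # population standardized coefficient
  est <- replicate(300, {
    y <- matrix(b * code + rnorm(n * W, 0, sigma), n, W)
    eye <- matrix(rnorm(n * W, 0, 0.2), n, W)
    r <- regress_activity_on_eye(y, code, eye, n_shuffle = 100, seed = NULL)
    c(mean(r$beta_hemi), mean(r$null_mean_hemi), mean(r$null_mean_hemi_eye))
  })
  se <- sd(est[1, ]) / sqrt(300)
  expect_lt(abs(mean(est[1, ]) - rho), 2 * se + 0.005)
  expect_lt(abs(mean(est[2, ])), 0.01)  # both nulls centered at zero
  expect_lt(abs(mean(est[3, ])), 0.01)
  y <- matrix(rnorm(n * W), n, W)
  expect_error(regress_activity_on_eye(y[1:8, ], code[1:8],
                                       y[1:8, ] * 0, n_shuffle = 100), ">= 10")
})

test_that("stimulation statistics degenerate correctly on identical samples", {
  expect_equal(cohens_d(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  # two stim sessions with identical per-cell rates: paired diff 0, d NaN-free
  mk <- function(k) eye_session(800 + k, n_blocks = 2, stim = TRUE,
                                stim_ipsi_error_increase = 0, p_correct = 1,
                                p_fixation_break = 0)
  st <- stim_behavior_stats(list(mk(1), mk(2), mk(3)))
  expect_equal(st$ipsi_test$diff, 0)
  expect_equal(st$contra_test$diff, 0)
  expect_true(all(st$rates$rate_all[st$rates$stimulation_session] == 1))
})
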
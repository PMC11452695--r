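test_that("same master seed reproduces byte-identical session files", {
  cfg <- synthetic_config(neurons = list(a = neuron_spec("hemifield_spatial",
                                                         pd_direction = "RU")),
                          n_choice_blocks = 1, n_delayed_blocks = 1,
                          master_seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_session(generate_session(cfg), d1)
  write_session(generate_session(cfg), d2)
  for (f in c("trials.tsv", "spikes.tsv", "eye.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("perfect performance yields only success outcomes", {
  s <- generate_session(synthetic_config(neurons = list(),
                                         n_choice_blocks = 2, n_delayed_blocks = 1,
                                         p_correct = 1, p_fixation_break = 0,
                                         generate_eyes = FALSE, master_seed = 2))
  expect_true(all(s$trials$outcome == "success"))
  expect_error(generate_session(synthetic_config(neurons = list(),
                                                 n_choice_blocks = 0,
                                                 n_delayed_blocks = 0)),
               "zero neurons and zero blocks")
})

test_that("rate profiles encode the documented response structure", {
  trial <- make_trial(0L, cue_id = "L1", angle = 0)
  # null archetype: constant baseline
  lam0 <- rate_profile(neuron_spec("null", baseline_hz = 12), trial)
  tt <- seq(trial$t_fix_on, trial$t_go + 0.5, by = 0.01)
  expect_equal(lam0(tt), rep(12, length(tt)))
  # hemifield gain doubles the rate exactly during [cue on, targets on)
  spec <- neuron_spec("hemifield_spatial", pd_direction = "L", hemi_gain = 2,
                      vis_gain = 0, baseline_hz = 10)
  lam <- rate_profile(spec, trial)
  expect_equal(lam(trial$t_cue_on + 0.1), 20)
  expect_equal(lam(trial$t_targets_on - 0.01), 20)
  expect_equal(lam(trial$t_cue_on - 0.01), 10)
  expect_equal(lam(trial$t_targets_on + 0.01), 10)
  # right-instructed trial: no gain for a left-preferring neuron
  trial_r <- make_trial(1L, cue_id = "R1", angle = 0, t0 = 30)
  expect_equal(rate_profile(spec, trial_r)(trial_r$t_cue_on + 0.1), 10)
  # kappa -> 0 gives a direction-blind visual drive
  s0 <- neuron_spec("hemifield_spatial", pd_direction = "L", kappa = 0,
                    vis_gain = 1, hemi_gain = 1, distractor_weight = 0,
                    baseline_hz = 10)
  lam_blind <- rate_profile(s0, trial_r)
  peak_t <- trial_r$t_targets_on + 0.15
  expect_equal(lam_blind(peak_t), 10 * (1 + 1))  # fdir == 1 at the transient peak
})

test_that("thinning matches Poisson theory and a time-rescaling oracle", {
  # zero rate: empty train
  expect_length(sample_spikes(function(t) numeric(length(t)) , c(0, 5),
                              lambda_max = 0), 0)
  # constant 100 Hz over 10 s: mean count 1000 within 3 SE over replicates
  lam <- function(t) rep(100, length(t))
  counts <- vapply(1:400, function(k)
    length(sample_spikes(lam, c(0, 10), lambda_max = 100, seed = 1e5 + k)), 1)
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 400))
  # step-function rate: spike-time distribution equals the oracle sampler
  rates <- c(20, 60); breaks <- c(0, 1, 2)
  step_lam <- function(t) ifelse(t < 1, 20, 60)
  thin <- unlist(lapply(1:1000, function(k)
    sample_spikes(step_lam, c(0, 2), lambda_max = 60, seed = 2e5 + k)))
  set.seed(42)
  orac <- unlist(lapply(1:1000, function(k) oracle_piecewise_poisson(rates, breaks)))
  ks <- suppressWarnings(stats::ks.test(thin, orac))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(length(thin) - length(orac)) / 1000, 3 * sqrt(2 * 80 / 1000))
  # an invalid bound is detected
  expect_error(sample_spikes(lam, c(0, 1), lambda_max = 50, seed = 1), "lambda_max")
  expect_error(sample_spikes(lam, c(0, 1), lambda_max = Inf), "finite")
})

test_that("eye traces follow the drift-plus-bias model", {
  trial <- make_trial(0L, cue_id = "R1")
  quiet <- eye_model_spec(ou_sigma_deg = 0, bias_amp_deg = 0)
  tr0 <- generate_eye_trace(trial, quiet, seed = 1)
  expect_true(all(tr0$x_deg == 0) && all(tr0$y_deg == 0))
  # deterministic bias: plateau is exactly +amp on a right-instructed trial
  biased <- eye_model_spec(ou_sigma_deg = 0, bias_amp_deg = 0.14,
                           opposite_shift_prob = 0)
  tr1 <- generate_eye_trace(trial, biased, seed = 1)
  tt <- tr1$t0_s + (seq_along(tr1$x_deg) - 1) / tr1$sample_rate_hz
  plateau <- tt > trial$t_cue_on + 0.17 + 0.15 + 0.05
  expect_equal(unique(tr1$x_deg[plateau]), 0.14)
  expect_true(all(tr1$x_deg[tt < trial$t_cue_on + 0.17] == 0))
  # ensemble mean at plateau ~ +-amp under drift noise
  spec <- eye_model_spec(opposite_shift_prob = 0)
  xs <- vapply(1:400, function(k) {
    e <- generate_eye_trace(trial, spec, seed = 3e5 + k)
    e$x_deg[length(e$x_deg) - 10]
  }, 1)
  expect_lt(abs(mean(xs) - 0.14), 3 * sd(xs) / sqrt(400))
  # stimulation adds a contralateral (positive-x) shift
  trial_stim <- make_trial(1L, cue_id = "L1", stim = TRUE, t0 = 30)
  st <- eye_model_spec(ou_sigma_deg = 0, bias_amp_deg = 0,
                       stim_contra_shift_deg = 0.1)
  tr2 <- generate_eye_trace(trial_stim, st, seed = 1)
  expect_equal(max(tr2$x_deg), 0.1)
})

test_that("neuron specs enforce their archetype invariants", {
  expect_error(neuron_spec("hemifield_spatial"), "pd_direction")
  expect_error(neuron_spec("hemifield_conceptual"), "pref_side")
  expect_error(neuron_spec("null", hemi_gain = 2), "neutral")
  expect_equal(neuron_spec("movement")$mov_gain, 30)
  expect_equal(neuron_spec("hemifield_spatial", pd_direction = "RD")$pref_side, "R")
})
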
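# Programmatic fixtures shared across test files. Sessions are generated
# once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# one hand-built choice trial row with consistent event times
make_trial <- function(trial_id = 0L, task = "choice", cue_id = "L1",
                       angle = 0, outcome = "success", stim = FALSE,
                       t0 = 10, target_direction = NULL) {
  hemi <- if (task == "choice") c(L1 = "L", L2 = "L", R1 = "R", R2 = "R")[[cue_id]]
    else NA_character_
  t_cue_on <- if (task == "choice") t0 + 1 else NA_real_
  t_cue_off <- if (task == "choice") t_cue_on + 0.7 else NA_real_
  t_targets <- if (task == "choice") t_cue_off + 0.5 else t0 + 1
  t_go <- t_targets + 1
  responded <- outcome %in% c("success", "wrong_choice")
  dir <- target_direction %||% (if (task == "choice")
    choice_target_direction(angle, hemi) else "R")
  data.frame(trial_id = as.integer(trial_id), task = task,
             cue_id = if (task == "choice") cue_id else NA_character_,
             instructed_hemifield = hemi,
             target_angle_deg = if (task == "choice") angle else NA_real_,
             target_direction = dir,
             regular_trial = task == "choice" && angle %in% c(-45, 0, 45),
             t_fix_on = t0 - 0.3, t_fix_acquired = t0,
             t_cue_on = t_cue_on, t_cue_off = t_cue_off,
             t_targets_on = t_targets, t_go = t_go,
             t_saccade_on = if (responded) t_go + 0.2 else NA_real_,
             t_reward = if (outcome == "success") t_go + 0.65 else NA_real_,
             outcome = outcome, stim = stim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small mixed-archetype session reused by classification/pipeline tests
small_mixed_session <- function() fixture("small_mixed", function() {
  specs <- list(
    hemi = neuron_spec("hemifield_spatial", pd_direction = "L", hemi_gain = 2),
    obj  = neuron_spec("object_selective",
                       obj_gains = c(L1 = 2, L2 = 1, R1 = 2, R2 = 1)),
    tpos = neuron_spec("target_position", pref_side = "R", hemi_gain = 2,
                       angle_gains = c(`-45` = 2, `0` = 1, `45` = 1)),
    nul  = neuron_spec("null")
  )
  generate_session(synthetic_config(neurons = specs, n_choice_blocks = 10,
                                    n_delayed_blocks = 6, generate_eyes = FALSE,
                                    master_seed = 1234))
})

small_choice_trials <- function() {
  s <- small_mixed_session()
  select_trials(s, task = "choice")
}
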
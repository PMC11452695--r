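# Synthetic session generator: inhomogeneous-Poisson spiking with
# direction-tuned, hemifield-selective, object-selective and movement-related
# archetypes; Ornstein-Uhlenbeck fixational eye drift with an instructed-side
# bias; block-randomized task structure; stimulation behavioral effects.

.ARCHETYPES <- c("hemifield_spatial", "hemifield_conceptual", "object_selective",
                 "angle_selective", "target_position", "movement", "null",
                 "eye_coupled")

#' Specify a synthetic neuron
#'
#' An archetype fixes which response components are non-neutral; every gain
#' can still be overridden. Firing follows
#' `lambda(t) = (baseline + eye term) * H(t) * O(cue) * A(angle) *
#' (1 + vis_gain * f_dir * k_vis(t - t_targets)) + mov_gain * k_mov(t - t_saccade)`
#' where `H` is the hemifield gain applied while the instructed hemifield
#' matches the neuron's preferred side, `f_dir` a von Mises direction tuning
#' normalized to max 1, `k_vis` a boxcar-with-exponential-decay visual
#' transient and `k_mov` a Gaussian peri-saccadic bump.
#'
#' @param archetype One of `r paste0('"', .ARCHETYPES, '"', collapse = ", ")`.
#' @param baseline_hz Baseline rate (Hz), >= 0.
#' @param pd_direction Preferred direction (one of the six target directions)
#'   or `NULL`; required for `hemifield_spatial`.
#' @param pref_side Preferred hemifield `"L"`/`"R"` for conceptual hemifield
#'   coding; defaults to the hemifield of `pd_direction` when that is given.
#' @param kappa Von Mises concentration (>= 0; 0 = direction-blind).
#' @param vis_gain Amplitude of the transient visual response (>= 0).
#' @param hemi_gain Multiplicative sustained gain (>= 1) when the instructed
#'   hemifield matches the preferred side.
#' @param mov_gain Peri-saccadic kernel amplitude (Hz, additive, >= 0).
#' @param obj_gains Named per-cue multipliers (L1, L2, R1, R2) active while
#'   the symbolic cue is on.
#' @param angle_gains Named multipliers for the regular target angles
#'   (`"-45"`, `"0"`, `"45"`) active between target onset and go.
#' @param distractor_weight Weight of the unchosen target's direction drive
#'   in the choice-task visual transient.
#' @param eye_gain_hz_per_deg Additive rate coupling to horizontal eye
#'   position (Hz/deg); only non-zero for the `eye_coupled` control archetype.
#' @return An object of class `sef_neuron_spec`.
#' @export
neuron_spec <- function(archetype, baseline_hz = 20, pd_direction = NULL,
                        pref_side = NULL, kappa = 2, vis_gain = 1,
                        hemi_gain = 1.5, mov_gain = 0,
                        obj_gains = c(L1 = 1, L2 = 1, R1 = 1, R2 = 1),
                        angle_gains = c(`-45` = 1, `0` = 1, `45` = 1),
                        distractor_weight = 0.5, eye_gain_hz_per_deg = 0) {
  archetype <- match.arg(archetype, .ARCHETYPES)
  defaults <- switch(archetype,
    hemifield_spatial   = list(),
    hemifield_conceptual = list(kappa = 0, vis_gain = 0.5),
    object_selective    = list(hemi_gain = 1, kappa = 0,
                               obj_gains = c(L1 = 1.6, L2 = 1, R1 = 1.6, R2 = 1)),
    angle_selective     = list(hemi_gain = 1, kappa = 0,
                               angle_gains = c(`-45` = 1.6, `0` = 1, `45` = 1)),
    target_position     = list(kappa = 0,
                               angle_gains = c(`-45` = 1.5, `0` = 1, `45` = 1)),
    movement            = list(hemi_gain = 1, vis_gain = 0, mov_gain = 30),
    null                = list(hemi_gain = 1, vis_gain = 0, kappa = 0),
    eye_coupled         = list(hemi_gain = 1, vis_gain = 0, kappa = 0,
                               eye_gain_hz_per_deg = 25))
  call_args <- as.list(match.call())[-1]
  for (nm in names(defaults))
    if (!nm %in% names(call_args)) assign(nm, defaults[[nm]])
  if (archetype == "hemifield_spatial" && is.null(pd_direction))
    stop("hemifield_spatial archetype requires pd_direction")
  if (!is.null(pd_direction)) {
    stopifnot(pd_direction %in% .DIR_LEVELS)
    if (is.null(pref_side)) pref_side <- direction_hemifield(pd_direction)
  }
  if (archetype %in% c("hemifield_conceptual", "target_position") && is.null(pref_side))
    stop(archetype, " archetype requires pref_side (or pd_direction)")
  stopifnot(baseline_hz >= 0, kappa >= 0, vis_gain >= 0, hemi_gain >= 1,
            mov_gain >= 0, all(obj_gains > 0), all(angle_gains > 0))
  if (archetype == "null" &&
      !(hemi_gain == 1 && vis_gain == 0 && mov_gain == 0 &&
        all(obj_gains == 1) && all(angle_gains == 1) && eye_gain_hz_per_deg == 0))
    stop("null archetype requires all gains neutral")
  structure(list(archetype = archetype, baseline_hz = baseline_hz,
                 pd_direction = pd_direction, pref_side = pref_side,
                 kappa = kappa, vis_gain = vis_gain, hemi_gain = hemi_gain,
                 mov_gain = mov_gain, obj_gains = obj_gains,
                 angle_gains = angle_gains, distractor_weight = distractor_weight,
                 eye_gain_hz_per_deg = eye_gain_hz_per_deg,
                 hemi_epoch = if (archetype == "target_position") "determination"
                              else "preselection"),
            class = "sef_neuron_spec")
}

#' Build a cohort of neuron specs
#'
#' Cycles `pd_direction` (and hence `pref_side`) through the six directions.
#'
#' @param n Number of neurons.
#' @param archetype Passed to [neuron_spec()].
#' @param ... Further arguments passed to [neuron_spec()].
#' @return Named list of `sef_neuron_spec` objects.
#' @export
neuron_cohort <- function(n, archetype, ...) {
  dirs <- rep_len(.DIR_LEVELS, n)
  specs <- lapply(seq_len(n), function(i) {
    if (archetype %in% c("hemifield_spatial", "hemifield_conceptual", "target_position"))
      neuron_spec(archetype, pd_direction = dirs[i], ...)
    else neuron_spec(archetype, ...)
  })
  names(specs) <- sprintf("%s_%03d", substr(archetype, 1, 4), seq_len(n))
  specs
}

#' Specify the fixational eye model
#'
#' Horizontal eye position is an Ornstein-Uhlenbeck drift plus, on choice
#' trials, a ramped bias toward the instructed hemifield whose sign is
#' flipped on a random fraction of trials, plus a ramped contralateral shift
#' on stimulation trials.
#'
#' @param ou_tau_s OU time constant (s).
#' @param ou_sigma_deg OU stationary standard deviation (deg).
#' @param bias_amp_deg Plateau amplitude of the instructed-side bias (deg).
#' @param bias_onset_s Latency of the bias after cue onset (s).
#' @param bias_ramp_s Rise time of the bias ramp (s).
#' @param opposite_shift_prob Per-trial probability (in [0, 0.5]) that the
#'   bias sign is flipped away from the instructed side.
#' @param stim_contra_shift_deg Plateau amplitude of the stimulation-induced
#'   contralateral shift (deg).
#' @return An object of class `sef_eye_spec`.
#' @export
eye_model_spec <- function(ou_tau_s = 0.35, ou_sigma_deg = 0.25,
                           bias_amp_deg = 0.14, bias_onset_s = 0.17,
                           bias_ramp_s = 0.15, opposite_shift_prob = 0.25,
                           stim_contra_shift_deg = 0.08) {
  stopifnot(ou_tau_s > 0, ou_sigma_deg >= 0, bias_amp_deg >= 0,
            bias_onset_s >= 0, bias_ramp_s > 0,
            opposite_shift_prob >= 0, opposite_shift_prob <= 0.5,
            stim_contra_shift_deg >= 0)
  structure(list(ou_tau_s = ou_tau_s, ou_sigma_deg = ou_sigma_deg,
                 bias_amp_deg = bias_amp_deg, bias_onset_s = bias_onset_s,
                 bias_ramp_s = bias_ramp_s,
                 opposite_shift_prob = opposite_shift_prob,
                 stim_contra_shift_deg = stim_contra_shift_deg),
            class = "sef_eye_spec")
}

#' Configuration for one synthetic session
#'
#' Defaults reproduce the recording-session task structure: 10 blocks of the
#' saccadic choice task (16 trials each: 4 symbolic cues x 3 regular angles
#' plus 4 additional angles) and 30 blocks of the visually guided delayed
#' saccade task (6 target directions each; recording sessions alternated the
#' two task sets two to three times, so the delayed-task default pools three
#' passes); 700-ms cue (120 ms in stimulation sessions), 500-ms delay, go
#' signal 750-1200 ms after target onset.
#'
#' @param neurons List of [neuron_spec()] objects (possibly empty for
#'   behavior-only sessions).
#' @param n_choice_blocks,n_delayed_blocks Block counts.
#' @param cue_dur_s Symbolic-cue duration; `NULL` picks 0.7 s, or 0.12 s in
#'   stimulation sessions.
#' @param delay_s Delay between cue offset and target onset (s).
#' @param go_wait_range_s Range of the target-onset-to-go wait (s).
#' @param p_correct Probability of a correct choice among completed trials
#'   (the correct choice rate).
#' @param p_fixation_break Probability that a trial is aborted by a fixation
#'   break before completion.
#' @param stimulation_session Logical; stimulation sessions interleave
#'   stimulated and non-stimulated trials 50/50 within blocks of 32.
#' @param stim_ipsi_error_increase Drop in the success probability on
#'   stimulated trials whose instructed hemifield is ipsilateral to the
#'   stimulated (left) hemisphere.
#' @param eye An [eye_model_spec()].
#' @param generate_eyes Logical; skip eye traces for speed when `FALSE`.
#' @param session_id,monkey,hemisphere Metadata.
#' @param master_seed Integer seed; every random element of the session is a
#'   deterministic function of it.
#' @return An object of class `sef_synth_config`.
#' @export
synthetic_config <- function(neurons = list(), n_choice_blocks = 10,
                             n_delayed_blocks = 30, cue_dur_s = NULL,
                             delay_s = 0.5, go_wait_range_s = c(0.75, 1.2),
                             p_correct = 0.97, p_fixation_break = 0.02,
                             stimulation_session = FALSE,
                             stim_ipsi_error_increase = 0.05,
                             eye = eye_model_spec(), generate_eyes = TRUE,
                             session_id = "synthetic", monkey = "S",
                             hemisphere = "L", master_seed = 1) {
  cue_dur_s <- cue_dur_s %||% (if (stimulation_session) 0.12 else 0.7)
  stopifnot(cue_dur_s > 0, delay_s > 0, all(go_wait_range_s > 0),
            go_wait_range_s[1] <= go_wait_range_s[2],
            p_correct >= 0, p_correct <= 1,
            p_fixation_break >= 0, p_fixation_break <= 1,
            stim_ipsi_error_increase >= 0, stim_ipsi_error_increase <= 1,
            n_choice_blocks >= 0, n_delayed_blocks >= 0)
  structure(list(neurons = neurons, n_choice_blocks = n_choice_blocks,
                 n_delayed_blocks = n_delayed_blocks, cue_dur_s = cue_dur_s,
                 delay_s = delay_s, go_wait_range_s = go_wait_range_s,
                 p_correct = p_correct, p_fixation_break = p_fixation_break,
                 stimulation_session = stimulation_session,
                 stim_ipsi_error_increase = stim_ipsi_error_increase,
                 eye = eye, generate_eyes = generate_eyes,
                 session_id = session_id, monkey = monkey,
                 hemisphere = hemisphere, master_seed = master_seed),
            class = "sef_synth_config")
}

# von Mises direction drive, normalized to max 1; kappa = 0 is direction-blind
.fdir <- function(theta_deg, pd_deg, kappa) {
  if (is.null(pd_deg) || kappa == 0) return(rep(1, length(theta_deg)))
  exp(kappa * (cos((theta_deg - pd_deg) * pi / 180) - 1))
}

.antipode <- c(R = "L", RU = "LD", RD = "LU", L = "R", LD = "RU", LU = "RD")

# visual transient: 80-ms latency, flat 150-ms peak, 200-ms exponential decay
.kvis <- function(u) {
  out <- numeric(length(u))
  flat <- u >= 0.08 & u < 0.23
  tail <- u >= 0.23
  out[flat] <- 1
  out[tail] <- exp(-(u[tail] - 0.23) / 0.2)
  out
}

# peri-saccadic bump centered 20 ms before saccade onset, sigma 40 ms
.kmov <- function(t, t_sacc) exp(-(t - (t_sacc - 0.02))^2 / (2 * 0.04^2))

#' Instantaneous firing-rate profile of a synthetic neuron on one trial
#'
#' @param spec A [neuron_spec()].
#' @param trial One trial: a one-row `data.frame` or list with the trial
#'   table fields (event times resolved).
#' @param eye_trace Optional [sef_eyetrace()] for the same trial; required by
#'   the `eye_coupled` archetype.
#' @return A vectorized rate function `t -> Hz` (session clock) with
#'   attribute `lambda_max`, a finite upper bound used for thinning.
#' @export
rate_profile <- function(spec, trial, eye_trace = NULL) {
  tr <- as.list(trial)
  pd_deg <- if (is.null(spec$pd_direction)) NULL else direction_angle(spec$pd_direction)
  is_choice <- identical(tr$task, "choice")

  hemi_on <- FALSE
  if (is_choice && !is.null(spec$pref_side) && !is.na(tr$instructed_hemifield) &&
      spec$hemi_gain != 1)
    hemi_on <- tr$instructed_hemifield == spec$pref_side
  hemi_win <- if (spec$hemi_epoch == "preselection") c(tr$t_cue_on, tr$t_targets_on)
              else c(tr$t_targets_on, tr$t_go)

  obj_gain <- if (is_choice && !is.na(tr$cue_id)) unname(spec$obj_gains[tr$cue_id]) else 1
  if (is.na(obj_gain)) obj_gain <- 1
  ang_gain <- 1
  if (is_choice && !is.na(tr$target_angle_deg)) {
    g <- spec$angle_gains[as.character(tr$target_angle_deg)]
    if (!is.na(g)) ang_gain <- unname(g)
  }

  dir_drive <- if (is_choice) {
    .fdir(direction_angle(tr$target_direction), pd_deg, spec$kappa) +
      spec$distractor_weight *
        .fdir(direction_angle(.antipode[[tr$target_direction]]), pd_deg, spec$kappa)
  } else {
    .fdir(direction_angle(tr$target_direction), pd_deg, spec$kappa)
  }

  eye_fun <- NULL
  if (spec$eye_gain_hz_per_deg != 0) {
    if (is.null(eye_trace)) stop("eye_coupled rate profile requires an eye trace")
    eye_fun <- stats::approxfun(eyetrace_times(eye_trace), eye_trace$x_deg, rule = 2)
  }

  fn <- function(t) {
    base <- rep(spec$baseline_hz, length(t))
    if (!is.null(eye_fun)) base <- base + spec$eye_gain_hz_per_deg * eye_fun(t)
    H <- rep(1, length(t))
    if (hemi_on && !anyNA(hemi_win))
      H[t >= hemi_win[1] & t < hemi_win[2]] <- spec$hemi_gain
    O <- rep(1, length(t))
    if (obj_gain != 1 && !is.na(tr$t_cue_on) && !is.na(tr$t_cue_off))
      O[t >= tr$t_cue_on & t < tr$t_cue_off] <- obj_gain
    A <- rep(1, length(t))
    if (ang_gain != 1 && !is.na(tr$t_targets_on) && !is.na(tr$t_go))
      A[t >= tr$t_targets_on & t < tr$t_go] <- ang_gain
    vis <- if (!is.na(tr$t_targets_on) && spec$vis_gain > 0)
      spec$vis_gain * dir_drive * .kvis(t - tr$t_targets_on) else 0
    mov <- if (!is.na(tr$t_saccade_on) && spec$mov_gain > 0)
      spec$mov_gain * .kmov(t, tr$t_saccade_on) else 0
    pmax(base * H * O * A * (1 + vis) + mov, 0)
  }
  lam_max <- (spec$baseline_hz + abs(spec$eye_gain_hz_per_deg) * 2.5) *
    max(spec$hemi_gain, 1) * max(spec$obj_gains, 1) * max(spec$angle_gains, 1) *
    (1 + spec$vis_gain * (1 + spec$distractor_weight)) + spec$mov_gain
  attr(fn, "lambda_max") <- lam_max
  fn
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' @param lambda Rate function (Hz); typically from [rate_profile()].
#' @param t_range Length-2 numeric, the span to sample over (s).
#' @param lambda_max Finite upper bound on `lambda` over `t_range`; defaults
#'   to the function's `lambda_max` attribute. An unbounded (non-finite)
#'   bound is an error.
#' @param seed Optional integer seed evaluated in a local RNG stream.
#' @return Sorted spike times within `t_range`.
#' @export
sample_spikes <- function(lambda, t_range, lambda_max = NULL, seed = NULL) {
  lambda_max <- lambda_max %||% attr(lambda, "lambda_max")
  if (is.null(lambda_max) || !is.finite(lambda_max) || lambda_max < 0)
    stop("sample_spikes requires a finite, non-negative lambda_max")
  stopifnot(length(t_range) == 2, t_range[1] < t_range[2])
  if (lambda_max == 0) return(numeric(0))
  with_seed(seed, {
    n <- stats::rpois(1, lambda_max * diff(t_range))
    if (n == 0) numeric(0) else {
      # unique(): the RNG's ~2^-32 output granularity can produce exact
      # duplicate candidates, which would break strict spike-time ordering
      cand <- unique(sort(stats::runif(n, t_range[1], t_range[2])))
      lam <- lambda(cand)
      if (any(lam > lambda_max * (1 + 1e-9)))
        stop("rate exceeds lambda_max; bound invalid")
      cand[stats::runif(length(cand)) < lam / lambda_max]
    }
  })
}

#' Generate one fixational eye trace
#'
#' @param trial One trial row (list or one-row `data.frame`).
#' @param spec An [eye_model_spec()].
#' @param seed Optional local seed.
#' @param sample_rate_hz Sampling rate; 240 Hz nominal.
#' @return A [sef_eyetrace()]. The trace is clamped to the 2.5-degree
#'   fixation window.
#' @export
generate_eye_trace <- function(trial, spec, seed = NULL, sample_rate_hz = 240) {
  tr <- as.list(trial)
  t0 <- tr$t_fix_acquired - 0.2
  t_end <- max(c(tr$t_saccade_on + 0.4, tr$t_go + 0.3, tr$t_targets_on + 0.3),
               na.rm = TRUE)
  tt <- seq(t0, t_end, by = 1 / sample_rate_hz)
  n <- length(tt)
  with_seed(seed, {
    ou <- function() {
      if (spec$ou_sigma_deg == 0) return(numeric(n))
      a <- exp(-1 / (sample_rate_hz * spec$ou_tau_s))
      innov <- stats::rnorm(n, 0, spec$ou_sigma_deg * sqrt(1 - a^2))
      innov[1] <- stats::rnorm(1, 0, spec$ou_sigma_deg)
      as.numeric(stats::filter(innov, a, method = "recursive"))
    }
    x <- ou(); y <- ou()
    if (identical(tr$task, "choice") && !is.na(tr$instructed_hemifield) &&
        spec$bias_amp_deg > 0) {
      side <- if (tr$instructed_hemifield == "R") 1 else -1
      if (stats::runif(1) < spec$opposite_shift_prob) side <- -side
      u <- (tt - tr$t_cue_on - spec$bias_onset_s) / spec$bias_ramp_s
      x <- x + side * spec$bias_amp_deg * pmin(pmax(u, 0), 1)
    }
    if (isTRUE(tr$stim) && !is.na(tr$t_cue_on) && spec$stim_contra_shift_deg > 0) {
      # stimulation runs through cue + delay; contralateral = +x
      u <- (tt - tr$t_cue_on - 0.05) / 0.3
      x <- x + spec$stim_contra_shift_deg * pmin(pmax(u, 0), 1)
    }
    x <- pmin(pmax(x, -2.49), 2.49)
    y <- pmin(pmax(y, -2.49), 2.49)
    sef_eyetrace(tr$trial_id, sample_rate_hz, t0, x, y)
  })
}

# block-randomized choice trial types for one block
.choice_block_types <- function(stim_session) {
  reg <- expand.grid(cue_id = .CUE_LEVELS, angle = c(-45, 0, 45),
                     stringsAsFactors = FALSE)
  add_pool <- setdiff(seq(-40, 40, by = 5), 0)
  add <- data.frame(cue_id = sample(.CUE_LEVELS, 4, replace = FALSE),
                    angle = sample(add_pool, 4, replace = TRUE))
  blk <- rbind(reg, add)
  if (stim_session) {
    blk <- rbind(transform(blk, stim = FALSE), transform(blk, stim = TRUE))
  } else blk$stim <- FALSE
  blk[sample(nrow(blk)), , drop = FALSE]
}

#' Generate a complete synthetic session
#'
#' Builds the block-randomized trial sequence, samples outcomes, simulates
#' every neuron's spike train by Poisson thinning and (optionally) a
#' 240-Hz eye trace per trial. Fully deterministic given
#' `config$master_seed`: trials, each neuron-trial spike train and each eye
#' trace draw from independently derived sub-seeds.
#'
#' @param config A [synthetic_config()].
#' @return A validated [sef_session()].
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "sef_synth_config"))
  if (length(config$neurons) == 0 &&
      config$n_choice_blocks + config$n_delayed_blocks == 0)
    stop("nothing to generate: zero neurons and zero blocks")
  if (config$n_choice_blocks + config$n_delayed_blocks == 0)
    stop("at least one block is required")
  ipsi_side <- if (identical(config$hemisphere, "L")) "L" else "R"

  trials <- with_seed(derive_seed(config$master_seed, 1), {
    rows <- list()
    t_cursor <- stats::runif(1, 3.6, 4.5)
    tid <- 0L
    emit <- function(task, cue_id, angle, direction, stim) {
      t_fix_on <- t_cursor
      t_fix_acq <- t_fix_on + stats::runif(1, 0.15, 0.4)
      if (task == "choice") {
        hemifield <- .CUE_HEMIFIELD[[cue_id]]
        t_cue_on <- t_fix_acq + 1.0
        t_cue_off <- t_cue_on + config$cue_dur_s
        t_targets <- t_cue_off + config$delay_s
      } else {
        hemifield <- NA_character_
        t_cue_on <- t_cue_off <- NA_real_
        t_targets <- t_fix_acq + 1.0
      }
      t_go <- t_targets + stats::runif(1, config$go_wait_range_s[1],
                                       config$go_wait_range_s[2])
      p <- config$p_correct
      if (task == "choice" && stim && hemifield == ipsi_side)
        p <- max(0, p - config$stim_ipsi_error_increase)
      # fixation breaks abort the trial independently of choice accuracy, so
      # p_correct is the correct choice rate among completed trials
      outcome <- if (stats::runif(1) < config$p_fixation_break) "fixation_break"
        else if (stats::runif(1) < p) "success"
        else if (task == "choice") "wrong_choice"
        else "fixation_break"
      if (task == "choice") {
        dir_correct <- choice_target_direction(angle, hemifield)
        direction <- if (outcome == "wrong_choice") .antipode[[dir_correct]] else dir_correct
      }
      responded <- outcome %in% c("success", "wrong_choice")
      t_sacc <- if (responded) t_go + stats::runif(1, 0.15, 0.3) else NA_real_
      t_rew <- if (outcome == "success") t_sacc + 0.42 else NA_real_
      t_cursor <<- max(c(t_rew, t_sacc + 0.4, t_go), na.rm = TRUE) +
        stats::runif(1, 3.6, 4.5)
      tid <<- tid + 1L
      data.frame(trial_id = tid - 1L, task = task, cue_id = cue_id,
                 instructed_hemifield = hemifield,
                 target_angle_deg = if (task == "choice") angle else NA_real_,
                 target_direction = direction,
                 regular_trial = task == "choice" && angle %in% c(-45, 0, 45),
                 t_fix_on = t_fix_on, t_fix_acquired = t_fix_acq,
                 t_cue_on = t_cue_on, t_cue_off = t_cue_off,
                 t_targets_on = t_targets, t_go = t_go,
                 t_saccade_on = t_sacc, t_reward = t_rew,
                 outcome = outcome, stim = stim)
    }
    for (b in seq_len(config$n_choice_blocks)) {
      blk <- .choice_block_types(config$stimulation_session)
      for (i in seq_len(nrow(blk)))
        rows[[length(rows) + 1]] <- emit("choice", blk$cue_id[i], blk$angle[i],
                                         NA_character_, blk$stim[i])
    }
    for (b in seq_len(config$n_delayed_blocks)) {
      for (d in sample(.DIR_LEVELS))
        rows[[length(rows) + 1]] <- emit("delayed", NA_character_, NA_real_, d, FALSE)
    }
    do.call(rbind, rows)
  })

  eyes <- list()
  if (config$generate_eyes) {
    eyes <- lapply(seq_len(nrow(trials)), function(i) {
      generate_eye_trace(trials[i, ], config$eye,
                         seed = derive_seed(config$master_seed, 3, i))
    })
  }
  eye_by_trial <- if (length(eyes))
    stats::setNames(eyes, vapply(eyes, function(e) as.character(e$trial_id), "")) else list()

  spikes <- list()
  specs <- config$neurons
  if (length(specs) && is.null(names(specs)))
    names(specs) <- sprintf("n%03d", seq_along(specs))
  for (j in seq_along(specs)) {
    spec <- specs[[j]]
    if (spec$eye_gain_hz_per_deg != 0 && !length(eyes))
      stop("eye_coupled neurons require generate_eyes = TRUE")
    train <- lapply(seq_len(nrow(trials)), function(i) {
      tr <- trials[i, ]
      t_end <- max(c(tr$t_reward + 0.3, tr$t_saccade_on + 0.5, tr$t_go + 0.8),
                   na.rm = TRUE)
      lam <- rate_profile(spec, tr,
                          eye_trace = eye_by_trial[[as.character(tr$trial_id)]])
      sample_spikes(lam, c(tr$t_fix_on - 0.5, t_end),
                    seed = derive_seed(config$master_seed, 2, j, i))
    })
    spikes[[names(specs)[j]]] <- sef_spiketrain(names(specs)[j], config$session_id,
                                                unlist(train), monkey = config$monkey)
  }

  sef_session(config$session_id, trials, spikes, eyes,
              metadata = list(monkey = config$monkey,
                              hemisphere = config$hemisphere,
                              stimulation_session = config$stimulation_session))
}
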
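# trial labels for a balanced 4-cue x 3-angle design with n repeats per cell
balanced_labels <- function(n_rep) {
  g <- expand.grid(cue_id = c("L1", "L2", "R1", "R2"),
                   target_angle_deg = c(-45, 0, 45), rep = seq_len(n_rep),
                   stringsAsFactors = FALSE)
  g$instructed_hemifield <- ifelse(g$cue_id %in% c("L1", "L2"), "L", "R")
  g
}

test_that("classify_window recovers planted effects and gates stage 2", {
  lab <- balanced_labels(10)
  set.seed(11)
  noise <- function() rnorm(nrow(lab), 10, 1)
  # hemifield main effect only -> potential_space, stage-1 p-values all open
  v_hemi <- noise() + 3 * (lab$instructed_hemifield == "L")
  r <- classify_window(v_hemi, lab)
  expect_equal(as.character(r$raw), "potential_space")
  expect_false(is.na(r$p_hemi))
  # angle main effect only -> choice_targets
  v_ang <- noise() + 2 * (lab$target_angle_deg == 45)
  expect_equal(as.character(classify_window(v_ang, lab)$raw), "choice_targets")
  # hemifield and angle -> target_position
  v_tp <- noise() + 3 * (lab$instructed_hemifield == "L") +
    2 * (lab$target_angle_deg == 45)
  expect_equal(as.character(classify_window(v_tp, lab)$raw), "target_position")
  # cue-object effect -> object, and stage 2 is not evaluated (gating)
  v_obj <- noise() + 3 * (lab$cue_id %in% c("L1", "R1"))
  r_obj <- classify_window(v_obj, lab)
  expect_equal(as.character(r_obj$raw), "object")
  expect_true(is.na(r_obj$p_hemi) && is.na(r_obj$p_ang) && is.na(r_obj$p_int))
  # object x angle -> object_and_choice, which takes precedence over object
  v_oc <- noise() + 3 * (lab$cue_id %in% c("L1", "R1")) *
    (lab$target_angle_deg == 0)
  expect_equal(as.character(classify_window(v_oc, lab)$raw), "object_and_choice")
  # no effect -> none
  expect_equal(as.character(classify_window(noise(), lab)$raw), "none")
  # all-zero window is undefined -> none with NA p-values
  r0 <- classify_window(rep(0, nrow(lab)), lab)
  expect_equal(as.character(r0$raw), "none")
  expect_true(is.na(r0$p_hemi))
})

test_that("the persistence rule removes short runs and is idempotent", {
  x <- c("potential_space", "potential_space", "none",
         "potential_space", "potential_space", "potential_space")
  out <- as.character(apply_persistence(x))
  expect_equal(out, c("none", "none", "none",
                      "potential_space", "potential_space", "potential_space"))
  expect_equal(as.character(apply_persistence(rep("none", 5))), rep("none", 5))
  set.seed(21)
  for (r in 1:20) {
    lab <- sample(c("none", "object", "potential_space"), 30, TRUE)
    once <- apply_persistence(lab)
    expect_identical(apply_persistence(once), once)
  }
})

test_that("synthetic archetypes are recovered with the expected labels", {
  s <- small_mixed_session()
  ch <- small_choice_trials()
  g_cue <- window_grid("cue_on", -0.2, 1.2, 0.01, 0.01)
  g_tgt <- window_grid("targets_on", -0.2, 0.75, 0.01, 0.01)
  track_of <- function(nid, g) {
    classify_neuron(windowed_iisi(s$spikes[[nid]]$spike_times_s, ch, g,
                                  neuron_id = nid), ch)
  }
  # hemifield-gain neuron: potential_space spanning the cue+delay epoch
  t_hemi <- track_of("hemi", g_cue)
  expect_true(summarize_epochs(t_hemi,
    list(preselection = c(0, 1.2)))[1, "potential_space"])
  expect_gt(sum(t_hemi$labels == "potential_space"), 20)
  # cue-object neuron: object during the cue epoch
  t_obj <- track_of("obj", g_cue)
  expect_true(summarize_epochs(t_obj, list(cue = c(0, 0.7)))[1, "object"])
  # target-position neuron: target_position after target onset
  t_tp <- track_of("tpos", g_tgt)
  expect_true(summarize_epochs(t_tp,
    list(determination = c(0, 0.75)))[1, "target_position"])
  # null neuron: no potential_space epoch claim
  t_null <- track_of("nul", g_cue)
  expect_lt(sum(t_null$labels != "none"), 10)
})

test_that("population fractions aggregate tracks on a shared grid", {
  s <- small_mixed_session()
  ch <- small_choice_trials()
  g <- window_grid("cue_on", 0, 0.5, 0.01, 0.01)
  tracks <- lapply(names(s$spikes), function(nid)
    classify_neuron(windowed_iisi(s$spikes[[nid]]$spike_times_s, ch, g,
                                  neuron_id = nid), ch))
  fr <- population_fractions(tracks)
  expect_equal(dim(fr), c(length(g$starts), 5))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(all(rowSums(fr) <= 1 + 1e-12))
  expect_error(population_fractions(list()), "empty")
  g2 <- window_grid("cue_on", 0, 0.4, 0.01, 0.01)
  t2 <- classify_neuron(windowed_iisi(s$spikes[[1]]$spike_times_s, ch, g2,
                                      neuron_id = "x"), ch)
  expect_error(population_fractions(c(tracks[1], list(t2))), "heterogeneous")
})

test_that("epoch summaries use the any-overlap rule", {
  g <- window_grid("cue_on", 0, 0.2, 0.01, 0.01)
  mk_track <- function(lab) structure(list(neuron_id = "x", grid = g,
                                           raw = factor(lab), labels = apply_persistence(lab)),
                                      class = "sef_factor_track")
  lab <- rep("none", length(g$starts))
  lab[5:7] <- "potential_space"
  tr <- mk_track(lab)
  expect_true(summarize_epochs(tr, list(e = c(0.04, 0.08)))[1, "potential_space"])
  # run straddling the epoch edge by one window still counts
  expect_true(summarize_epochs(tr, list(e = c(0.065, 0.1)))[1, "potential_space"])
  expect_false(summarize_epochs(tr, list(e = c(0.1, 0.15)))[1, "potential_space"])
  expect_false(any(summarize_epochs(mk_track(rep("none", length(g$starts))),
                                    list(e = c(0, 0.1)))))
  expect_error(summarize_epochs(tr, list(e = c(0, 5))), "outside")
})
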
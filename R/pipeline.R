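# End-to-end orchestration: simulate or load -> windowed metrics -> factor
# classification -> PD/typing/ROC -> eye analyses -> structured report.

.default_grids <- function() {
  list(cue = window_grid("cue_on", -0.2, 1.2, 0.01, 0.01),
       targets = window_grid("targets_on", -0.2, 0.75, 0.01, 0.01),
       roc = window_grid("cue_on", -0.2, 1.2, 0.1, 0.1))
}

#' Run the full analysis of one session
#'
#' Orchestrates the complete pipeline: per-neuron iISI factor classification
#' on cue- and target-aligned 10-ms grids, population fractions and epoch
#' summaries; PD determination, neuron typing and the Rayleigh test;
#' PD-referenced AUC tracks with shuffle nulls, the signed-count binomial
#' test and, when eye traces exist, the hemifield/eye-position regression;
#' and the eye-position summary. All stages are cross-linked by `neuron_id`
#' and the result is deterministic given `seed`.
#'
#' @param session A `sef_session`, or `NULL` to generate one from `config`.
#' @param config A [synthetic_config()] (used when `session` is `NULL`).
#' @param seed Integer seed for the permutation/shuffle stages.
#' @param n_perm Permutations for the AUC null and regression shuffles.
#' @param grids Optional list with elements `cue`, `targets`, `roc`
#'   (see the defaults in the implementation).
#' @return An object of class `sef_report`.
#' @export
run_full_analysis <- function(session = NULL, config = NULL, seed = 1,
                              n_perm = 1000, grids = NULL) {
  if (is.null(session)) {
    if (is.null(config)) stop("provide a session or a config")
    session <- generate_session(config)
  }
  grids <- grids %||% .default_grids()
  choice <- select_trials(session, task = "choice", regular_only = FALSE)
  delayed <- select_trials(session, task = "delayed")
  neuron_ids <- names(session$spikes)

  # --- factor classification -----------------------------------------------
  tracks_cue <- list(); tracks_tgt <- list()
  if (length(neuron_ids) && nrow(choice)) {
    for (nid in neuron_ids) {
      st <- session$spikes[[nid]]$spike_times_s
      ii_cue <- windowed_iisi(st, choice, grids$cue, neuron_id = nid)
      tracks_cue[[nid]] <- classify_neuron(ii_cue, choice)
      ii_tgt <- windowed_iisi(st, choice, grids$targets, neuron_id = nid)
      tracks_tgt[[nid]] <- classify_neuron(ii_tgt, choice)
    }
  }
  presel_span <- c(0, stats::median(choice$t_targets_on - choice$t_cue_on,
                                    na.rm = TRUE))
  determ_span <- c(0, min(0.75, stats::median(choice$t_go - choice$t_targets_on,
                                              na.rm = TRUE)))
  epoch_summary <- NULL
  if (length(tracks_cue)) {
    epoch_summary <- data.frame(
      neuron_id = neuron_ids,
      potential_space_preselection = vapply(neuron_ids, function(nid)
        summarize_epochs(tracks_cue[[nid]],
                         list(preselection = presel_span))[1, "potential_space"], TRUE),
      target_position_determination = vapply(neuron_ids, function(nid)
        summarize_epochs(tracks_tgt[[nid]],
                         list(determination = determ_span))[1, "target_position"], TRUE),
      row.names = NULL)
  }

  # --- PD, typing, Rayleigh ------------------------------------------------
  pd_table <- NULL; types <- NULL; rayleigh <- NULL
  if (length(neuron_ids) && nrow(delayed) && all(table(delayed$target_direction) >= 2) &&
      length(unique(delayed$target_direction)) == 6) {
    pd_list <- lapply(neuron_ids, function(nid) {
      cnt <- spike_count(session$spikes[[nid]]$spike_times_s,
                         delayed$t_targets_on, c(0, 0.3))
      determine_pd(cnt, delayed$target_direction)
    })
    names(pd_list) <- neuron_ids
    pd_table <- data.frame(
      neuron_id = neuron_ids,
      has_pd = vapply(pd_list, `[[`, TRUE, "has_pd"),
      pd_direction = vapply(pd_list, `[[`, "", "pd_direction"),
      anova_p = vapply(pd_list, `[[`, 1, "anova_p"), row.names = NULL)
    ty <- lapply(neuron_ids, function(nid)
      classify_neuron_type(session$spikes[[nid]]$spike_times_s, delayed))
    types <- data.frame(neuron_id = neuron_ids,
                        type = vapply(ty, `[[`, "", "type"),
                        p_visual = vapply(ty, `[[`, 1, "p_visual"),
                        p_movement = vapply(ty, `[[`, 1, "p_movement"),
                        row.names = NULL)
    if (sum(pd_table$has_pd) >= 3)
      rayleigh <- rayleigh_uniformity(pd_table$pd_direction[pd_table$has_pd])
  } else if (length(neuron_ids) && nrow(delayed) == 0) {
    warning("no delayed-task trials: PD and neuron-type sections left empty")
  }

  # --- PD-referenced population contrasts ----------------------------------
  auc_pop <- NULL; count_binomial <- NULL; regression <- NULL
  pd_neurons <- if (!is.null(pd_table)) pd_table$neuron_id[pd_table$has_pd] else character()
  if (length(pd_neurons) >= 5) {
    counts_list <- list(); cond_list <- list(); auc_tracks <- list()
    for (nid in pd_neurons) {
      lab <- pd_condition_labels(choice, list(has_pd = TRUE,
        pd_direction = pd_table$pd_direction[pd_table$neuron_id == nid]))
      cm <- spike_count_matrix(session$spikes[[nid]]$spike_times_s,
                               choice$t_cue_on, grids$roc)
      counts_list[[nid]] <- cm
      cond_list[[nid]] <- lab
      auc_tracks[[nid]] <- auc_track_with_null(cm, lab, n_perm = n_perm,
                                               seed = derive_seed(seed, 11, match(nid, pd_neurons)))
    }
    auc_pop <- population_auc_test(auc_tracks)
    count_binomial <- signed_count_binomial(counts_list, cond_list)
    if (length(session$eyes)) {
      eye_sum <- preprocess_eye(session)
      id_row <- match(choice$trial_id, eye_sum$trial_ids)
      eye_win <- vapply(seq_along(grids$roc$starts), function(w) {
        cols <- eye_sum$t >= grids$roc$starts[w] &
          eye_sum$t < grids$roc$starts[w] + grids$roc$width_s
        rowMeans(eye_sum$per_trial[id_row, cols, drop = FALSE])
      }, numeric(nrow(choice)))
      ok <- !is.na(id_row)
      reg_list <- list()
      for (nid in pd_neurons) {
        code <- ifelse(cond_list[[nid]] == "pd_included", 1, -1)
        reg_list[[nid]] <- regress_activity_on_eye(
          counts_list[[nid]][ok, , drop = FALSE], code[ok],
          eye_win[ok, , drop = FALSE], n_shuffle = n_perm,
          seed = derive_seed(seed, 12, match(nid, pd_neurons)))
      }
      regression <- regression_population_test(reg_list)
    }
  }

  # --- eye summary ----------------------------------------------------------
  eye_summary <- if (length(session$eyes)) preprocess_eye(session) else NULL
  shift <- if (!is.null(eye_summary)) classify_shift_direction(eye_summary) else NULL

  structure(list(
    session_id = session$session_id,
    n_neurons = length(neuron_ids),
    factor_tracks_cue = tracks_cue,
    factor_tracks_targets = tracks_tgt,
    population_fractions = if (length(tracks_cue)) population_fractions(tracks_cue),
    epoch_summary = epoch_summary,
    pd = pd_table, types = types, rayleigh = rayleigh,
    auc_population = auc_pop, count_binomial = count_binomial,
    regression = regression,
    eye_summary = eye_summary, shift = shift,
    provenance = list(seed = seed, n_perm = n_perm,
                      package_version = as.character(utils::packageVersion("sefspace")))),
    class = "sef_report")
}

#' @export
print.sef_report <- function(x, ...) {
  cat("<sef_report>", x$session_id, "-", x$n_neurons, "neurons\n")
  if (!is.null(x$epoch_summary)) {
    cat(sprintf("  potential space during preselection: %d/%d neurons\n",
                sum(x$epoch_summary$potential_space_preselection), x$n_neurons))
    cat(sprintf("  target position during determination: %d/%d neurons\n",
                sum(x$epoch_summary$target_position_determination), x$n_neurons))
  }
  if (!is.null(x$pd))
    cat(sprintf("  neurons with a PD: %d/%d (Rayleigh p = %s)\n",
                sum(x$pd$has_pd), nrow(x$pd),
                if (is.null(x$rayleigh)) "-" else format(x$rayleigh$p, digits = 3)))
  if (!is.null(x$types))
    cat("  types:", paste(names(table(x$types$type)), table(x$types$type),
                          sep = "=", collapse = ", "), "\n")
  if (!is.null(x$auc_population))
    cat(sprintf("  AUC windows significant vs shuffle (FDR): %d/%d\n",
                sum(x$auc_population$sig_fdr), nrow(x$auc_population)))
  if (!is.null(x$shift))
    cat(sprintf("  eye shifts opposite to instruction: %.1f%%\n",
                100 * x$shift$prop_opposite))
  invisible(x)
}
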
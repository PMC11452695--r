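# Session data model: trial table, spike trains, eye traces, and the TSV
# dialect used to persist them.

.TRIAL_COLS <- c(
  trial_id = "integer", task = "character", cue_id = "character",
  instructed_hemifield = "character", target_angle_deg = "numeric",
  target_direction = "character", regular_trial = "logical",
  t_fix_on = "numeric", t_fix_acquired = "numeric", t_cue_on = "numeric",
  t_cue_off = "numeric", t_targets_on = "numeric", t_go = "numeric",
  t_saccade_on = "numeric", t_reward = "numeric",
  outcome = "character", stim = "logical"
)

#' Construct a spike train
#'
#' @param neuron_id,session_id Identifiers.
#' @param spike_times_s Strictly increasing, non-negative spike times in
#'   seconds relative to session start.
#' @param monkey Animal identifier.
#' @param site_xy_mm Optional length-2 numeric recording-site coordinate.
#' @return An object of class `sef_spiketrain`.
#' @export
sef_spiketrain <- function(neuron_id, session_id, spike_times_s,
                           monkey = NA_character_, site_xy_mm = NULL) {
  spike_times_s <- as.numeric(spike_times_s)
  if (length(spike_times_s) && any(spike_times_s < 0))
    stop("spike times must be non-negative (neuron ", neuron_id, ")")
  if (is.unsorted(spike_times_s, strictly = TRUE))
    stop("spike times must be strictly increasing (neuron ", neuron_id, ")")
  structure(list(neuron_id = as.character(neuron_id),
                 session_id = as.character(session_id),
                 spike_times_s = spike_times_s,
                 monkey = as.character(monkey),
                 site_xy_mm = site_xy_mm),
            class = "sef_spiketrain")
}

#' Construct an eye-position trace
#'
#' Positive x is rightward, i.e. contralateral to a left-hemisphere recording.
#'
#' @param trial_id Trial the trace belongs to (0-based id).
#' @param sample_rate_hz Sampling rate; 240 Hz nominal.
#' @param t0_s Time of the first sample, seconds relative to session start.
#' @param x_deg,y_deg Equal-length position sequences in degrees of visual angle.
#' @return An object of class `sef_eyetrace`.
#' @export
sef_eyetrace <- function(trial_id, sample_rate_hz, t0_s, x_deg, y_deg) {
  if (length(x_deg) != length(y_deg)) stop("x_deg and y_deg must have equal length")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  structure(list(trial_id = as.integer(trial_id),
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 t0_s = as.numeric(t0_s),
                 x_deg = as.numeric(x_deg), y_deg = as.numeric(y_deg)),
            class = "sef_eyetrace")
}

# sample times of a trace
eyetrace_times <- function(tr) tr$t0_s + (seq_along(tr$x_deg) - 1) / tr$sample_rate_hz

#' Construct and validate a recording session
#'
#' @param session_id Session identifier.
#' @param trials Trial table (`data.frame`) with the documented columns; one
#'   row per behavioral trial.
#' @param spikes List of [sef_spiketrain] objects (may be empty).
#' @param eyes List of [sef_eyetrace] objects (may be empty).
#' @param metadata List with at least `monkey`, `hemisphere` (`"L"`/`"R"`),
#'   and `stimulation_session` (logical).
#' @return A validated object of class `sef_session`.
#' @export
sef_session <- function(session_id, trials, spikes = list(), eyes = list(),
                        metadata = list(monkey = NA_character_, hemisphere = "L",
                                        stimulation_session = FALSE)) {
  s <- structure(list(session_id = as.character(session_id),
                      trials = trials, spikes = spikes, eyes = eyes,
                      metadata = metadata),
                 class = "sef_session")
  names(s$spikes) <- vapply(s$spikes, `[[`, "", "neuron_id")
  validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks column types, event ordering, the cue-to-hemifield mapping, the
#' regular-trial definition, spike-time monotonicity, and that every eye trace
#' references an existing trial. Called by [sef_session()] and [load_session()].
#'
#' @param session A `sef_session`.
#' @return The session, invisibly; errors on the first violated invariant.
#' @export
validate_session <- function(session) {
  tr <- session$trials
  if (!is.data.frame(tr) || nrow(tr) == 0) stop("session has no trials")
  missing_cols <- setdiff(names(.TRIAL_COLS), names(tr))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tr$trial_id)) stop("duplicate trial_id in trial table")
  if (!all(tr$task %in% c("choice", "delayed"))) stop("task must be 'choice' or 'delayed'")
  ch <- tr$task == "choice"
  if (any(ch & !(tr$cue_id %in% .CUE_LEVELS)))
    stop("choice trials must carry a cue_id in {L1, L2, R1, R2}")
  # cue -> hemifield must be the fixed session-wide function
  map <- .CUE_HEMIFIELD[tr$cue_id[ch]]
  if (any(map != tr$instructed_hemifield[ch]))
    stop("cue_id/instructed_hemifield mapping violated (L1,L2 -> L; R1,R2 -> R)")
  reg <- !is.na(tr$target_angle_deg) & tr$target_angle_deg %in% c(-45, 0, 45)
  if (any(reg != tr$regular_trial))
    stop("regular_trial must equal (target_angle_deg %in% {-45, 0, 45})")
  if (!all(tr$target_direction %in% .DIR_LEVELS))
    stop("target_direction must be one of ", paste(.DIR_LEVELS, collapse = ", "))
  ord <- cbind(tr$t_fix_acquired, tr$t_cue_on, tr$t_cue_off, tr$t_targets_on, tr$t_go)
  bad <- apply(ord, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) > 1 && is.unsorted(r, strictly = TRUE)
  })
  if (any(bad))
    stop("event times out of order in trial(s) ", paste(tr$trial_id[bad], collapse = ", "))
  resp <- tr$outcome %in% c("success", "wrong_choice")
  sac_bad <- resp & (!is.na(tr$t_go)) &
    (is.na(tr$t_saccade_on) | tr$t_saccade_on <= tr$t_go)
  if (any(sac_bad))
    stop("t_saccade_on must follow t_go for responded trial(s) ",
         paste(tr$trial_id[sac_bad], collapse = ", "))
  # block composition: full choice blocks carry 12 regular + 4 additional types
  n_choice <- sum(ch)
  if (n_choice >= 16 && n_choice %% 16 == 0) {
    if (sum(ch & tr$regular_trial) != 3 * sum(ch & !tr$regular_trial))
      stop("choice blocks must contain 12 regular + 4 additional trials each")
  }
  for (st in session$spikes) {
    if (!inherits(st, "sef_spiketrain")) stop("spikes must be sef_spiketrain objects")
    if (is.unsorted(st$spike_times_s, strictly = TRUE))
      stop("non-monotonic spike times for neuron ", st$neuron_id)
  }
  for (ey in session$eyes) {
    if (!ey$trial_id %in% tr$trial_id)
      stop("eye trace references absent trial_id ", ey$trial_id)
  }
  invisible(session)
}

#' @export
print.sef_session <- function(x, ...) {
  cat("<sef_session>", x$session_id, "\n")
  cat("  trials:", nrow(x$trials),
      sprintf("(choice %d, delayed %d)", sum(x$trials$task == "choice"),
              sum(x$trials$task == "delayed")), "\n")
  cat("  neurons:", length(x$spikes), " eye traces:", length(x$eyes), "\n")
  cat("  monkey:", x$metadata$monkey %||% NA, " hemisphere:",
      x$metadata$hemisphere %||% NA, " stimulation:",
      isTRUE(x$metadata$stimulation_session), "\n")
  invisible(x)
}

# ---- TSV dialect -----------------------------------------------------------
# One UTF-8 tab-separated table per entity, each headed by a versioned comment
# line. Times are doubles in seconds relative to session start; doubles are
# written with 17 significant digits so a write/load round trip is exact.

.fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

.write_tsv <- function(df, path, header_line) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header_line, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}

.read_tsv <- function(path, expect_tag) {
  if (!file.exists(path)) stop("missing file: ", path)
  first <- readLines(path, n = 1)
  if (!startsWith(first, paste0("#", expect_tag)))
    stop(path, " does not start with the expected header '#", expect_tag, "'")
  kv <- regmatches(first, gregexpr("[A-Za-z_]+=[^\t ]*", first))[[1]]
  meta <- list()
  for (p in kv) {
    parts <- strsplit(p, "=", fixed = TRUE)[[1]]
    meta[[parts[1]]] <- parts[2]
  }
  df <- utils::read.delim(path, skip = 1, sep = "\t", na.strings = "NA",
                          stringsAsFactors = FALSE)
  list(meta = meta, df = df)
}

#' Write a session to a directory of TSV tables
#'
#' Writes `trials.tsv`, `spikes.tsv` (long form, one row per spike) and
#' `eye.tsv` (long form, one row per sample) such that
#' `load_session(write_session(s, d))` reproduces `s` up to float round-trip.
#'
#' @param session A valid `sef_session`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_session <- function(session, dir) {
  validate_session(session)
  if (nrow(session$trials) == 0) stop("nothing to write: empty trial list")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("unwritable path: ", dir)
  md <- session$metadata
  head_tr <- sprintf("#sefspace-trials v1\tsession_id=%s\tmonkey=%s\themisphere=%s\tstimulation_session=%s",
                     session$session_id, md$monkey %||% NA, md$hemisphere %||% NA,
                     isTRUE(md$stimulation_session))
  tr <- session$trials
  num <- names(.TRIAL_COLS)[.TRIAL_COLS == "numeric"]
  tr[num] <- lapply(tr[num], .fmt_num)
  paths <- c(trials = file.path(dir, "trials.tsv"),
             spikes = file.path(dir, "spikes.tsv"),
             eye = file.path(dir, "eye.tsv"))
  .write_tsv(tr[names(.TRIAL_COLS)], paths["trials"], head_tr)

  sp <- do.call(rbind, lapply(session$spikes, function(st) {
    n <- length(st$spike_times_s)
    data.frame(neuron_id = rep(st$neuron_id, n),
               monkey = rep(st$monkey, n),
               site_x_mm = rep(if (is.null(st$site_xy_mm)) NA_real_ else st$site_xy_mm[1], n),
               site_y_mm = rep(if (is.null(st$site_xy_mm)) NA_real_ else st$site_xy_mm[2], n),
               spike_time_s = .fmt_num(st$spike_times_s))
  }))
  if (is.null(sp)) sp <- data.frame(neuron_id = character(), monkey = character(),
                                    site_x_mm = numeric(), site_y_mm = numeric(),
                                    spike_time_s = character())
  .write_tsv(sp, paths["spikes"], "#sefspace-spikes v1")

  ey <- do.call(rbind, lapply(session$eyes, function(tr_) {
    n <- length(tr_$x_deg)
    data.frame(trial_id = rep(tr_$trial_id, n),
               sample_rate_hz = .fmt_num(rep(tr_$sample_rate_hz, n)),
               t0_s = .fmt_num(rep(tr_$t0_s, n)),
               x_deg = .fmt_num(tr_$x_deg), y_deg = .fmt_num(tr_$y_deg))
  }))
  if (is.null(ey)) ey <- data.frame(trial_id = integer(), sample_rate_hz = character(),
                                    t0_s = character(), x_deg = character(),
                                    y_deg = character())
  .write_tsv(ey, paths["eye"], "#sefspace-eye v1")
  invisible(paths)
}

#' Load a session from TSV tables
#'
#' @param dir Directory containing `trials.tsv`, `spikes.tsv`, `eye.tsv`
#'   as written by [write_session()].
#' @return A validated `sef_session`.
#' @export
load_session <- function(dir) {
  tr <- .read_tsv(file.path(dir, "trials.tsv"), "sefspace-trials")
  sp <- .read_tsv(file.path(dir, "spikes.tsv"), "sefspace-spikes")
  ey <- .read_tsv(file.path(dir, "eye.tsv"), "sefspace-eye")
  trials <- tr$df
  for (cl in names(.TRIAL_COLS)) {
    trials[[cl]] <- switch(.TRIAL_COLS[[cl]],
                           integer = as.integer(trials[[cl]]),
                           numeric = as.numeric(trials[[cl]]),
                           logical = as.logical(trials[[cl]]),
                           character = as.character(trials[[cl]]))
  }
  session_id <- tr$meta$session_id %||% "session"
  spikes <- list()
  if (nrow(sp$df)) {
    for (nid in unique(sp$df$neuron_id)) {
      rows <- sp$df[sp$df$neuron_id == nid, ]
      site <- if (all(is.na(rows$site_x_mm))) NULL else c(rows$site_x_mm[1], rows$site_y_mm[1])
      spikes[[nid]] <- sef_spiketrain(nid, session_id, as.numeric(rows$spike_time_s),
                                      monkey = rows$monkey[1], site_xy_mm = site)
    }
  }
  eyes <- list()
  if (nrow(ey$df)) {
    for (tid in unique(ey$df$trial_id)) {
      rows <- ey$df[ey$df$trial_id == tid, ]
      eyes[[length(eyes) + 1]] <- sef_eyetrace(tid, as.numeric(rows$sample_rate_hz[1]),
                                               as.numeric(rows$t0_s[1]),
                                               as.numeric(rows$x_deg),
                                               as.numeric(rows$y_deg))
    }
  }
  stim <- identical(tr$meta$stimulation_session, "TRUE")
  sef_session(session_id, trials, spikes, eyes,
              metadata = list(monkey = tr$meta$monkey %||% NA_character_,
                              hemisphere = tr$meta$hemisphere %||% "L",
                              stimulation_session = stim))
}

#' Filter the trial table of a session
#'
#' Order-preserving subset. Neural analyses default to success trials only;
#' pass `outcome = NULL` to keep every outcome. Contradictory predicates
#' yield an empty table (with a message), not an error.
#'
#' @param session A `sef_session`.
#' @param task `"choice"`, `"delayed"` or `NULL` (both).
#' @param outcome Outcome filter (default `"success"`), or `NULL`.
#' @param regular_only Keep only the regular choice-target angles (-45, 0, 45).
#' @param stim `TRUE`/`FALSE` to filter stimulation trials, or `NULL`.
#' @param cue_id,hemifield,angle Optional value sets to keep.
#' @return A `data.frame` subset of `session$trials`.
#' @export
select_trials <- function(session, task = NULL, outcome = "success",
                          regular_only = FALSE, stim = NULL,
                          cue_id = NULL, hemifield = NULL, angle = NULL) {
  tr <- session$trials
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(task)) keep <- keep & tr$task %in% task
  if (!is.null(outcome)) keep <- keep & tr$outcome %in% outcome
  if (regular_only) keep <- keep & tr$regular_trial
  if (!is.null(stim)) keep <- keep & tr$stim == stim
  if (!is.null(cue_id)) keep <- keep & tr$cue_id %in% cue_id
  if (!is.null(hemifield)) keep <- keep & tr$instructed_hemifield %in% hemifield
  if (!is.null(angle)) keep <- keep & !is.na(tr$target_angle_deg) & tr$target_angle_deg %in% angle
  out <- tr[keep, , drop = FALSE]
  if (nrow(out) == 0) message("select_trials: no trials match the given predicates")
  out
}
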
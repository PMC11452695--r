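# Eye-position preprocessing and bias detection, trial-wise shift
# classification, disentangling hemifield coding from eye position in neural
# activity, and stimulation-experiment behavioral statistics.

#' Preprocess horizontal eye position around the symbolic cue
#'
#' Cue-aligns each choice trial's horizontal trace on a common 240-Hz grid,
#' subtracts the per-trial baseline mean (the 0.5 s before cue onset), forms
#' the left/right-instructed condition means, and normalizes them by
#' subtracting the pointwise grand mean of the two conditions. Trials whose
#' trace does not cover the full analysis span are dropped with a message.
#'
#' @param session A `sef_session` with eye traces.
#' @param t_range Cue-relative analysis span (s), default `c(-0.5, 1.3)`.
#' @param outcome Trial outcomes to keep (default success).
#' @param sample_rate_hz Resampling rate of the common grid.
#' @return An object of class `sef_eye_summary`: `t` (cue-relative times),
#'   `cond_mean` (2 x T normalized condition means, rows `L`, `R`),
#'   `per_trial` (trials x T baseline-subtracted matrix), `hemifield`,
#'   `trial_ids`, `stim`, `t_max_diff` (time of maximal L/R separation after
#'   cue onset), `n_dropped`.
#' @export
preprocess_eye <- function(session, t_range = c(-0.5, 1.3), outcome = "success",
                           sample_rate_hz = 240) {
  tr <- select_trials(session, task = "choice", outcome = outcome)
  eyes <- session$eyes[vapply(session$eyes, function(e) e$trial_id %in% tr$trial_id, TRUE)]
  if (length(eyes) == 0) stop("session has no eye traces for the selected trials")
  tt <- seq(t_range[1], t_range[2], by = 1 / sample_rate_hz)
  rows <- list(); hemi <- character(); ids <- integer(); stim <- logical()
  n_dropped <- 0
  for (e in eyes) {
    row <- tr[tr$trial_id == e$trial_id, ]
    x <- stats::approx(eyetrace_times(e), e$x_deg, xout = row$t_cue_on + tt)$y
    if (anyNA(x)) { n_dropped <- n_dropped + 1; next }
    rows[[length(rows) + 1]] <- x - mean(x[tt < 0])
    hemi <- c(hemi, row$instructed_hemifield)
    ids <- c(ids, row$trial_id)
    stim <- c(stim, row$stim)
  }
  if (n_dropped) message(n_dropped, " trial(s) dropped: trace shorter than the analysis span")
  if (length(rows) == 0) stop("no usable eye traces")
  per_trial <- do.call(rbind, rows)
  cm <- rbind(L = colMeans(per_trial[hemi == "L", , drop = FALSE]),
              R = colMeans(per_trial[hemi == "R", , drop = FALSE]))
  cm_norm <- sweep(cm, 2, colMeans(cm))
  post <- tt > 0
  t_max <- tt[post][which.max(abs(cm["L", post] - cm["R", post]))]
  structure(list(session_id = session$session_id, t = tt, cond_mean = cm_norm,
                 cond_mean_raw = cm, per_trial = per_trial, hemifield = hemi,
                 trial_ids = ids, stim = stim, t_max_diff = t_max,
                 n_dropped = n_dropped),
            class = "sef_eye_summary")
}

#' Detect the onset of the instructed-side eye-position divergence
#'
#' Paired t-test (left- vs right-instructed condition means across sessions)
#' at every time point; the onset is the start of the first run of
#' significant points lasting at least `min_dur_s`. Returns `NA` onset when
#' no such run exists.
#'
#' @param summaries List of `sef_eye_summary` objects (>= 3 sessions) on a
#'   common time grid.
#' @param alpha Per-timepoint level (default 0.01).
#' @param min_dur_s Persistence threshold (s); default 0.02 (a 0.01-s
#'   threshold is also in use in the field; both are exposed here).
#' @param t_min Earliest time considered for the onset run (default 0: the
#'   bias is defined as emerging after cue onset; the pre-cue baseline is
#'   noise by construction).
#' @return List: `onset_s` (or `NA`), `t`, `p` (per timepoint), `sig`.
#' @export
detect_divergence <- function(summaries, alpha = 0.01, min_dur_s = 0.02,
                              t_min = 0) {
  if (length(summaries) < 3) stop("need >= 3 sessions")
  tt <- summaries[[1]]$t
  L <- t(vapply(summaries, function(s) s$cond_mean["L", ], numeric(length(tt))))
  R <- t(vapply(summaries, function(s) s$cond_mean["R", ], numeric(length(tt))))
  d <- L - R
  n <- nrow(d)
  tstat <- colMeans(d) / (apply(d, 2, stats::sd) / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  fs <- 1 / diff(tt[1:2])
  k_min <- ceiling(min_dur_s * fs - 1e-9)
  sig <- !is.na(p) & p <= alpha
  sig[tt < t_min] <- FALSE
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= k_min)
  onset <- if (length(hit)) tt[starts[hit[1]]] else NA_real_
  list(onset_s = onset, t = tt, p = p, sig = sig)
}

#' Classify the per-trial direction of the eye-position shift
#'
#' At the session's time of maximal separation between the left- and
#' right-instructed condition means, each trial is labeled by the hemifield
#' its (baseline-subtracted) eye position lies in. An exactly zero position
#' takes the sign of the next sample (deterministic tie rule).
#'
#' @param summary A `sef_eye_summary`.
#' @return List: `shift` (`"L"`/`"R"` per trial), `t_max_diff`, `trial_ids`,
#'   `hemifield` (instructed), `prop_opposite`.
#' @export
classify_shift_direction <- function(summary) {
  i <- which.min(abs(summary$t - summary$t_max_diff))
  x <- summary$per_trial[, i]
  zero <- x == 0
  if (any(zero) && i < ncol(summary$per_trial))
    x[zero] <- summary$per_trial[zero, i + 1]
  shift <- ifelse(x >= 0, "R", "L")
  list(shift = shift, t_max_diff = summary$t_max_diff,
       trial_ids = summary$trial_ids, hemifield = summary$hemifield,
       prop_opposite = mean(shift != summary$hemifield))
}

#' Window-wise hemifield vs eye-shift two-way ANOVA
#'
#' For one neuron: per 10-ms window, a 2x2 ANOVA of the mean iISI with the
#' instructed hemifield and the eye-shift direction as factors. A window is
#' instruction-modulated when the hemifield main effect is significant
#' (`p < alpha`) in a run of at least `min_run` consecutive windows;
#' eye-modulated when the shift main effect or the interaction is.
#'
#' @param values Trials-by-windows iISI matrix.
#' @param hemifield,shift Per-trial factors (`"L"`/`"R"`).
#' @param alpha Per-window level (default 0.01).
#' @param min_run Persistence run length (default 3).
#' @return `data.frame` per window: `p_hemi`, `p_shift`, `p_int`,
#'   `instruction_modulated`, `eye_modulated`.
#' @export
hemifield_vs_eyeshift_anova <- function(values, hemifield, shift, alpha = 0.01,
                                        min_run = 3) {
  res <- fast_anova2(as.matrix(values), factor(hemifield, c("L", "R")),
                     factor(shift, c("L", "R")))
  run_filter <- function(flag) {
    r <- rle(flag)
    r$values[r$lengths < min_run] <- FALSE
    inverse.rle(r)
  }
  instr <- run_filter(!is.na(res$p_a) & res$p_a < alpha)
  eye <- run_filter((!is.na(res$p_b) & res$p_b < alpha) |
                    (!is.na(res$p_ab) & res$p_ab < alpha))
  data.frame(window = seq_len(ncol(as.matrix(values))),
             p_hemi = res$p_a, p_shift = res$p_b, p_int = res$p_ab,
             instruction_modulated = instr, eye_modulated = eye)
}

#' Regress windowed spike counts on hemifield condition and eye position
#'
#' Per 100-ms window, two ordinary-least-squares fits on standardized
#' variables: single regression on the PD-condition code (+1 PD-included,
#' -1 PD-opposite) giving `beta_hemi`, and multiple regression adding the
#' window-mean horizontal eye position giving `beta_hemi_eye` and
#' `beta_eye`. A label-shuffle null (trial correspondence permuted) is
#' attached for both hemifield coefficients.
#'
#' @param counts Trials-by-windows spike-count matrix.
#' @param code Numeric +1/-1 condition code per trial.
#' @param eye Trials-by-windows matrix of window-mean horizontal eye
#'   position (deg).
#' @param n_shuffle Number of shuffles (default 1000).
#' @param seed Optional local seed.
#' @return An object of class `sef_regression`: per-window `beta_hemi`,
#'   `beta_hemi_eye`, `beta_eye`, `r12` (code/eye correlation), `unstable`
#'   (|r12| > 0.999), and null means/SDs `null_*`.
#' @export
regress_activity_on_eye <- function(counts, code, eye, n_shuffle = 1000,
                                    seed = NULL) {
  counts <- as.matrix(counts); eye <- as.matrix(eye)
  n <- nrow(counts); W <- ncol(counts)
  stopifnot(length(code) == n, all(dim(eye) == dim(counts)))
  if (n < 10) stop("need >= 10 trials")
  if (stats::sd(code) == 0) stop("condition code is constant")
  zs <- function(m) {
    s <- apply(m, 2, stats::sd)
    s[s == 0] <- NA
    sweep(sweep(m, 2, colMeans(m)), 2, s, "/")
  }
  Y <- zs(counts); E <- zs(eye)
  x1 <- as.numeric(scale(code))
  r12 <- colSums(E * x1) / (n - 1)
  betas <- function(Yp) {
    ry1 <- colSums(Yp * x1) / (n - 1)
    ry2 <- colSums(Yp * E) / (n - 1)
    b1 <- (ry1 - ry2 * r12) / (1 - r12^2)
    b2 <- (ry2 - ry1 * r12) / (1 - r12^2)
    list(hemi = ry1, hemi_eye = b1, eye = b2)
  }
  obs <- betas(Y)
  nulls <- with_seed(seed, {
    nh <- nhe <- matrix(NA_real_, n_shuffle, W)
    for (k in seq_len(n_shuffle)) {
      b <- betas(Y[sample(n), , drop = FALSE])
      nh[k, ] <- b$hemi; nhe[k, ] <- b$hemi_eye
    }
    list(nh = nh, nhe = nhe)
  })
  structure(list(beta_hemi = obs$hemi, beta_hemi_eye = obs$hemi_eye,
                 beta_eye = obs$eye, r12 = r12,
                 unstable = !is.na(r12) & abs(r12) > 0.999,
                 null_mean_hemi = colMeans(nulls$nh),
                 null_sd_hemi = apply(nulls$nh, 2, stats::sd),
                 null_mean_hemi_eye = colMeans(nulls$nhe),
                 null_sd_hemi_eye = apply(nulls$nhe, 2, stats::sd),
                 n_shuffle = n_shuffle),
            class = "sef_regression")
}

#' Population comparison of hemifield betas with and without eye position
#'
#' Per window, across neurons: (i) paired test of `beta_hemi` vs
#' `beta_hemi_eye`; (ii) each coefficient against its shuffle-null mean
#' (one-sided, greater). Benjamini-Hochberg across windows for each family.
#'
#' @param results List of `sef_regression` objects (one per neuron).
#' @param alpha FDR level.
#' @param method `"ttest"` (paired t, default) or `"wilcoxon"`.
#' @return `data.frame` per window: mean betas, `p_diff`/`sig_diff`
#'   (with-vs-without eye), `p_hemi_null`/`sig_hemi_null`,
#'   `p_hemi_eye_null`/`sig_hemi_eye_null`.
#' @export
regression_population_test <- function(results, alpha = 0.05,
                                       method = c("ttest", "wilcoxon")) {
  method <- match.arg(method)
  W <- length(results[[1]]$beta_hemi)
  get <- function(f) t(vapply(results, `[[`, numeric(W), f))
  bh <- get("beta_hemi"); bhe <- get("beta_hemi_eye")
  nh <- get("null_mean_hemi"); nhe <- get("null_mean_hemi_eye")
  ptest <- function(x, y, alternative) {
    vapply(seq_len(W), function(w) {
      d <- x[, w] - y[, w]
      if (all(d == 0)) return(1)
      if (method == "ttest")
        stats::t.test(x[, w], y[, w], paired = TRUE, alternative = alternative)$p.value
      else suppressWarnings(stats::wilcox.test(x[, w], y[, w], paired = TRUE,
                                               alternative = alternative)$p.value)
    }, numeric(1))
  }
  p_diff <- ptest(bh, bhe, "two.sided")
  p_h <- ptest(bh, nh, "greater")
  p_he <- ptest(bhe, nhe, "greater")
  data.frame(window = seq_len(W), beta_hemi_mean = colMeans(bh),
             beta_hemi_eye_mean = colMeans(bhe),
             p_diff = p_diff, sig_diff = fdr_bh(p_diff, alpha),
             p_hemi_null = p_h, sig_hemi_null = fdr_bh(p_h, alpha),
             p_hemi_eye_null = p_he, sig_hemi_eye_null = fdr_bh(p_he, alpha))
}

# per-session correct choice rate among completed choices
.correct_rate <- function(session, stim = NULL, hemifield = NULL) {
  tr <- session$trials
  keep <- tr$task == "choice" & tr$outcome %in% c("success", "wrong_choice")
  if (!is.null(stim)) keep <- keep & tr$stim == stim
  if (!is.null(hemifield)) keep <- keep & tr$instructed_hemifield %in% hemifield
  if (!any(keep)) return(NA_real_)
  mean(tr$outcome[keep] == "success")
}

# per-session mean horizontal eye position in a cue-relative window,
# baseline-subtracted, for one stim x hemifield cell
.eye_window_mean <- function(summary, window, stim, hemifield) {
  sel <- summary$stim == stim & summary$hemifield == hemifield
  if (!any(sel)) return(NA_real_)
  cols <- summary$t >= window[1] & summary$t <= window[2]
  mean(summary$per_trial[sel, cols, drop = FALSE])
}

#' Behavioral statistics of the stimulation experiment
#'
#' Computes (i) the session-level correct-rate comparison between
#' stimulation and non-stimulation sessions (two-sample t, pooled-SD
#' Cohen's d); (ii) within stimulation sessions, paired comparisons of the
#' stimulated vs non-stimulated trial correct rate separately for trials
#' instructed toward the hemifield ipsilateral and contralateral to the
#' stimulated hemisphere (paired t, d = mean diff / SD diff); and (iii) a
#' two-way ANOVA (stimulation x trial type) on the per-session window-mean
#' horizontal eye position, with eta-squared effect sizes.
#'
#' @param sessions List of `sef_session` objects; stimulation sessions are
#'   recognized by `metadata$stimulation_session`.
#' @param window Cue-relative eye-position window (s), default 0.35-0.45.
#' @param eye_summaries Optional pre-computed [preprocess_eye()] results for
#'   the stimulation sessions (computed on demand otherwise; sessions
#'   without eye traces skip the ANOVA).
#' @return An object of class `sef_stim_summary` with `rates` (per-session
#'   table), `session_test`, `ipsi_test`, `contra_test`, `eye_anova`.
#' @export
stim_behavior_stats <- function(sessions, window = c(0.35, 0.45),
                                eye_summaries = NULL) {
  is_stim <- vapply(sessions, function(s) isTRUE(s$metadata$stimulation_session), TRUE)
  if (sum(is_stim) < 2) stop("need >= 2 stimulation sessions")
  ipsi <- vapply(sessions, function(s)
    if (identical(s$metadata$hemisphere, "R")) "R" else "L", "")
  contra <- ifelse(ipsi == "L", "R", "L")

  rates <- data.frame(
    session_id = vapply(sessions, `[[`, "", "session_id"),
    stimulation_session = is_stim,
    rate_all = vapply(sessions, .correct_rate, numeric(1)),
    rate_stim_ipsi = NA_real_, rate_nonstim_ipsi = NA_real_,
    rate_stim_contra = NA_real_, rate_nonstim_contra = NA_real_)
  for (i in which(is_stim)) {
    rates$rate_stim_ipsi[i] <- .correct_rate(sessions[[i]], TRUE, ipsi[i])
    rates$rate_nonstim_ipsi[i] <- .correct_rate(sessions[[i]], FALSE, ipsi[i])
    rates$rate_stim_contra[i] <- .correct_rate(sessions[[i]], TRUE, contra[i])
    rates$rate_nonstim_contra[i] <- .correct_rate(sessions[[i]], FALSE, contra[i])
  }

  session_test <- NULL
  if (any(!is_stim)) {
    a <- rates$rate_all[!is_stim]; b <- rates$rate_all[is_stim]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    session_test <- list(statistic = "t", value = unname(tt$statistic),
                         dof = unname(tt$parameter), p = tt$p.value,
                         effect = cohens_d(a, b),
                         mean_nonstim = mean(a), mean_stim = mean(b))
  }
  paired_rates <- function(ns, st) {
    ok <- !is.na(ns) & !is.na(st)
    if (sum(ok) < 2) return(NULL)
    if (stats::sd(ns[ok] - st[ok]) == 0) {
      d0 <- mean(ns[ok] - st[ok])
      return(list(statistic = "t", value = NA_real_, dof = sum(ok) - 1,
                  p = if (d0 == 0) 1 else 0, effect = 0,
                  mean_nonstim = mean(ns[ok]), mean_stim = mean(st[ok]),
                  diff = d0, diff_ci = c(d0, d0), n = sum(ok)))
    }
    tt <- stats::t.test(ns[ok], st[ok], paired = TRUE)
    list(statistic = "t", value = unname(tt$statistic),
         dof = unname(tt$parameter), p = tt$p.value,
         effect = cohens_d(ns[ok] - st[ok], paired = TRUE),
         mean_nonstim = mean(ns[ok]), mean_stim = mean(st[ok]),
         diff = mean(ns[ok] - st[ok]),
         diff_ci = unname(tt$conf.int), n = sum(ok))
  }
  ipsi_test <- paired_rates(rates$rate_nonstim_ipsi[is_stim],
                            rates$rate_stim_ipsi[is_stim])
  contra_test <- paired_rates(rates$rate_nonstim_contra[is_stim],
                              rates$rate_stim_contra[is_stim])

  eye_anova <- NULL
  stim_sessions <- sessions[is_stim]
  have_eyes <- vapply(stim_sessions, function(s) length(s$eyes) > 0, TRUE)
  if (all(have_eyes)) {
    sums <- eye_summaries %||% lapply(stim_sessions, preprocess_eye)
    cells <- expand.grid(stim = c(FALSE, TRUE), type = c("ipsi", "contra"),
                         session = seq_along(sums))
    ip <- ipsi[is_stim]
    cells$x <- mapply(function(st, ty, se) {
      hf <- if (ty == "ipsi") ip[se] else ifelse(ip[se] == "L", "R", "L")
      .eye_window_mean(sums[[se]], window, st, hf)
    }, cells$stim, cells$type, cells$session)
    cells <- cells[!is.na(cells$x), ]
    fit <- stats::aov(x ~ stim * type, data = cells)
    tab <- stats::anova(fit)
    eye_anova <- list(F_stim = tab["stim", "F value"],
                      p_stim = tab["stim", "Pr(>F)"],
                      F_type = tab["type", "F value"],
                      p_type = tab["type", "Pr(>F)"],
                      dof = c(1, tab["Residuals", "Df"]),
                      eta2 = eta_squared(fit), cells = cells)
  }
  structure(list(rates = rates, session_test = session_test,
                 ipsi_test = ipsi_test, contra_test = contra_test,
                 eye_anova = eye_anova, window = window),
            class = "sef_stim_summary")
}
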
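# Preferred-direction determination, neuron typing, PD-referenced condition
# contrasts, shuffle-null ROC tracks, count-based binomial tests,
# tuning-matrix construction and rotation, and shared statistical utilities.

#' Determine a neuron's preferred direction
#'
#' One-way ANOVA on visual-epoch spike counts across the six target
#' directions of the delayed saccade task. The neuron has a PD iff the ANOVA
#' is significant at `alpha` and the maximal mean count is attained by a
#' unique direction (ties give no PD).
#'
#' @param counts Per-trial spike counts (0-300 ms after target onset).
#' @param directions Direction code per trial; all six directions must occur.
#' @param alpha Significance level, default 0.05.
#' @return List: `has_pd`, `pd_direction` (or `NA`), `anova_p`,
#'   `mean_counts` (named, one per direction).
#' @export
determine_pd <- function(counts, directions, alpha = 0.05) {
  stopifnot(length(counts) == length(directions))
  missing_dir <- setdiff(.DIR_LEVELS, unique(directions))
  if (length(missing_dir))
    stop("no trials for direction(s): ", paste(missing_dir, collapse = ", "))
  if (any(table(directions) < 2)) stop("need >= 2 trials per direction")
  f <- factor(directions, levels = .DIR_LEVELS)
  p <- suppressWarnings(stats::anova(stats::lm(counts ~ f))[["Pr(>F)"]][1])
  if (is.na(p)) p <- 1  # zero-variance counts: no direction effect
  m <- tapply(counts, f, mean)
  at_max <- abs(m - max(m)) < 1e-9
  unique_max <- sum(at_max) == 1
  has_pd <- p <= alpha && unique_max
  list(has_pd = has_pd,
       pd_direction = if (has_pd) names(m)[which(at_max)] else NA_character_,
       anova_p = p, mean_counts = m)
}

#' Classify a neuron as visual, visuomovement, movement or none
#'
#' One-sided Wilcoxon signed-rank tests on paired delayed-task counts:
#' visual-related if counts 0-300 ms after target onset exceed those 300-0 ms
#' before; saccade-related if counts -100-50 ms around saccade onset exceed
#' those 350-200 ms before. Visual = visual-only, movement = saccade-only,
#' visuomovement = both, none otherwise.
#'
#' @param spike_times_s Sorted spike times (s).
#' @param trials Delayed-task success trials (need `t_targets_on`,
#'   `t_saccade_on`).
#' @param alpha Significance level per contrast.
#' @return List: `type`, `p_visual`, `p_movement`.
#' @export
classify_neuron_type <- function(spike_times_s, trials, alpha = 0.05) {
  p_one_sided <- function(after, before) {
    d <- after - before
    if (all(d == 0)) return(1)
    suppressWarnings(stats::wilcox.test(after, before, paired = TRUE,
                                        alternative = "greater")$p.value)
  }
  p_vis <- p_one_sided(spike_count(spike_times_s, trials$t_targets_on, c(0, 0.3)),
                       spike_count(spike_times_s, trials$t_targets_on, c(-0.3, 0)))
  p_mov <- p_one_sided(spike_count(spike_times_s, trials$t_saccade_on, c(-0.1, 0.05)),
                       spike_count(spike_times_s, trials$t_saccade_on, c(-0.35, -0.2)))
  vis <- .sig(p_vis, alpha); mov <- .sig(p_mov, alpha)
  type <- if (vis && mov) "visuomovement" else if (vis) "visual"
          else if (mov) "movement" else "none"
  list(type = type, p_visual = p_vis, p_movement = p_mov)
}

#' Label trials by the relation between instruction and PD
#'
#' Choice trials: `pd_included` when the instructed hemifield contains the
#' neuron's PD (left directions LD/L/LU belong to hemifield L), else
#' `pd_opposite`. Delayed trials: `pd` when the target is at the PD,
#' `anti_pd` when diametrically opposite, `NA` otherwise.
#'
#' @param trials Trial table rows.
#' @param pd A [determine_pd()] result with `has_pd = TRUE`.
#' @return Character vector, one label per trial.
#' @export
pd_condition_labels <- function(trials, pd) {
  if (!isTRUE(pd$has_pd)) stop("neuron has no PD")
  pd_hemi <- direction_hemifield(pd$pd_direction)
  out <- rep(NA_character_, nrow(trials))
  ch <- trials$task == "choice" & !is.na(trials$instructed_hemifield)
  out[ch] <- ifelse(trials$instructed_hemifield[ch] == pd_hemi,
                    "pd_included", "pd_opposite")
  dl <- trials$task == "delayed"
  out[dl & trials$target_direction == pd$pd_direction] <- "pd"
  out[dl & trials$target_direction == .antipode[[pd$pd_direction]]] <- "anti_pd"
  out
}

#' Area under the ROC curve between two spike-count samples
#'
#' Mann-Whitney probability that a draw from `a` exceeds a draw from `b`,
#' with ties counted one half. 1 means every `a` count exceeds every `b`
#' count; 0.5 means indistinguishable distributions.
#'
#' @param a,b Non-empty numeric samples (`a` = PD-included convention).
#' @return Number in \[0, 1\].
#' @export
auc <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("auc requires non-empty samples")
  r <- rank(c(a, b))
  (sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2) /
    (length(a) * length(b))
}

# observed + permuted AUC per window given a rank matrix (trials x windows)
.auc_cols <- function(rank_mat, idx_a, n_a, n_b) {
  (colSums(rank_mat[idx_a, , drop = FALSE]) - n_a * (n_a + 1) / 2) / (n_a * n_b)
}

#' Windowed AUC track with a label-shuffle null
#'
#' Computes the observed AUC in each sliding window and a permutation null
#' obtained by shuffling the correspondence between trials and conditions.
#'
#' @param counts Trials-by-windows spike-count matrix (100 ms / 100 ms grid
#'   typically).
#' @param cond Two-level condition per trial; the first level of
#'   `factor(cond)` (alphabetically `pd_included` before `pd_opposite`) is
#'   the "greater" group of the AUC.
#' @param n_perm Number of label permutations (>= 100 enforced; default 1000).
#' @param seed Optional local seed for the permutations.
#' @return An object of class `sef_auc_track`: `auc`, `null_mean`,
#'   `null_q` (2.5/97.5 % permutation quantiles per window), `degenerate`
#'   (windows with zero count variance), `n_perm`.
#' @export
auc_track_with_null <- function(counts, cond, n_perm = 1000, seed = NULL) {
  counts <- as.matrix(counts)
  cond <- factor(cond)
  stopifnot(nlevels(cond) == 2, nrow(counts) == length(cond))
  if (n_perm < 100) stop("n_perm below the enforced minimum of 100")
  if (min(table(cond)) < 5) stop("need >= 5 trials per condition")
  n <- nrow(counts)
  idx_a <- which(cond == levels(cond)[1])
  n_a <- length(idx_a); n_b <- n - n_a
  rank_mat <- apply(counts, 2, rank)
  obs <- .auc_cols(rank_mat, idx_a, n_a, n_b)
  null <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(k) {
      .auc_cols(rank_mat, sample(n, n_a), n_a, n_b)
    }, numeric(ncol(counts))))
  })
  structure(list(auc = obs, null_mean = colMeans(null),
                 null_q = apply(null, 2, stats::quantile, c(0.025, 0.975)),
                 degenerate = apply(counts, 2, function(x) stats::var(x) == 0),
                 n_perm = n_perm),
            class = "sef_auc_track")
}

#' Population test of AUC against the shuffle null
#'
#' Per window, compares the observed AUC across neurons with each neuron's
#' null-mean AUC (Wilcoxon signed-rank by default, paired t optionally),
#' then applies Benjamini-Hochberg across windows.
#'
#' @param tracks List of `sef_auc_track` objects on a common grid.
#' @param alpha FDR level.
#' @param method `"wilcoxon"` (default) or `"ttest"`.
#' @param alternative Defaults to `"greater"` (AUC above the null).
#' @return `data.frame`: per window mean observed AUC, mean null AUC, `p`,
#'   `sig_fdr`.
#' @export
population_auc_test <- function(tracks, alpha = 0.05, method = c("wilcoxon", "ttest"),
                                alternative = "greater") {
  method <- match.arg(method)
  obs <- t(vapply(tracks, `[[`, numeric(length(tracks[[1]]$auc)), "auc"))
  nul <- t(vapply(tracks, `[[`, numeric(length(tracks[[1]]$auc)), "null_mean"))
  p <- vapply(seq_len(ncol(obs)), function(w) {
    d <- obs[, w] - nul[, w]
    if (all(d == 0)) return(1)
    if (method == "wilcoxon")
      suppressWarnings(stats::wilcox.test(obs[, w], nul[, w], paired = TRUE,
                                          alternative = alternative)$p.value)
    else stats::t.test(obs[, w], nul[, w], paired = TRUE,
                       alternative = alternative)$p.value
  }, numeric(1))
  data.frame(window = seq_len(ncol(obs)), auc_mean = colMeans(obs),
             null_mean = colMeans(nul), p = p, sig_fdr = fdr_bh(p, alpha))
}

#' Signed counts of condition-selective neurons with a binomial test
#'
#' Per window, each neuron's counts are compared between the two conditions
#' (two-sample t-test, pooled variance, `alpha`); neurons significant in
#' each direction are counted and the two counts compared with an exact
#' two-sided binomial test against 1/2, Benjamini-Hochberg corrected across
#' windows. Windows with no significant neuron get p = 1.
#'
#' @param counts_list One trials-by-windows count matrix per neuron.
#' @param cond_list The matching per-neuron condition vectors (two levels;
#'   first level = "included").
#' @param alpha Per-neuron test level and FDR level.
#' @return `data.frame`: `n_greater_included`, `n_greater_opposite`,
#'   `binom_p`, `sig_fdr` per window.
#' @export
signed_count_binomial <- function(counts_list, cond_list, alpha = 0.05) {
  stopifnot(length(counts_list) == length(cond_list))
  W <- ncol(counts_list[[1]])
  sign_mat <- vapply(seq_along(counts_list), function(j) {
    cm <- as.matrix(counts_list[[j]])
    cond <- factor(cond_list[[j]])
    a <- cond == levels(cond)[1]
    vapply(seq_len(W), function(w) {
      x <- cm[a, w]; y <- cm[!a, w]
      if (stats::var(x) + stats::var(y) == 0) return(0)
      tt <- stats::t.test(x, y, var.equal = TRUE)
      if (tt$p.value <= alpha) sign(tt$estimate[1] - tt$estimate[2]) else 0
    }, numeric(1))
  }, numeric(W))
  n_inc <- rowSums(sign_mat > 0)
  n_opp <- rowSums(sign_mat < 0)
  p <- vapply(seq_len(W), function(w) {
    n <- n_inc[w] + n_opp[w]
    if (n == 0) return(1)
    stats::binom.test(n_inc[w], n, 0.5)$p.value
  }, numeric(1))
  data.frame(window = seq_len(W), n_greater_included = n_inc,
             n_greater_opposite = n_opp, binom_p = p, sig_fdr = fdr_bh(p, alpha))
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up FDR control at level `alpha`; `NA` p-values are never rejected.
#'
#' @param p Vector of p-values.
#' @param alpha FDR level.
#' @return Logical vector of rejections (empty input gives empty output).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(logical(0))
  adj <- stats::p.adjust(p, method = "BH")
  !is.na(adj) & adj <= alpha
}

#' Direction-by-time tuning matrix
#'
#' Mean firing rate (Hz) per canonical target direction in each sliding
#' window (200 ms / 10 ms by default), averaged across the trials with the
#' saccade target in that direction. Directions without trials give `NA`
#' rows.
#'
#' @param spike_times_s Sorted spike times (s).
#' @param trials Trial rows (choice or delayed); grouping uses
#'   `target_direction`.
#' @param grid A [window_grid()]; default 200-ms windows stepped 10 ms,
#'   aligned to target onset, spanning the preceding cue/delay epoch too.
#' @return 6-by-T matrix, rows in the order LD, L, LU, RU, R, RD.
#' @export
tuning_matrix <- function(spike_times_s, trials,
                          grid = window_grid("targets_on", -1.45, 0.85, 0.2, 0.01)) {
  ev <- trials[[.ALIGN_COLS[[grid$align_event]]]]
  cnt <- spike_count_matrix(spike_times_s, ev, grid) / grid$width_s
  out <- matrix(NA_real_, 6, length(grid$starts),
                dimnames = list(.DIR_LEVELS, NULL))
  for (d in .DIR_LEVELS) {
    rows <- which(trials$target_direction == d & !is.na(ev))
    if (length(rows)) out[d, ] <- colMeans(cnt[rows, , drop = FALSE])
  }
  out
}

# relative angular slots of the 8-point circular grid
.REL_SLOTS <- seq(0, 315, by = 45)

#' PD-aligned population tuning matrix
#'
#' Pre-target columns: each neuron's six direction rows are reordered so the
#' three directions of the PD-containing hemifield come first (LD/L/LU vs
#' RU/R/RD kept in mirror order). Post-target columns: each neuron's rows
#' are placed on an 8-point 45-degree circular grid at their angular offset
#' from the PD (PD at 0); the two empty slots (Up and Down for a horizontal
#' PD) are filled by linear interpolation from their circular neighbors.
#' Neurons without a PD are excluded with a message.
#'
#' @param mats Named list of [tuning_matrix()] outputs (shared grid).
#' @param pds Named character vector of PD directions (`NA` = no PD).
#' @param pre_cols Logical or integer index of the pre-target columns.
#' @return List: `pre` (6 x T_pre matrix, rows `included_1..3`,
#'   `opposite_1..3`), `post` (8 x T_post, rows = relative angle), `n`.
#' @export
align_tuning_population <- function(mats, pds, pre_cols) {
  pds <- pds[names(mats)]
  keep <- !is.na(pds)
  if (any(!keep)) message(sum(!keep), " neuron(s) without PD excluded from alignment")
  if (!any(keep)) stop("no neuron with a PD")
  mats <- mats[keep]; pds <- pds[keep]
  if (is.logical(pre_cols)) pre_cols <- which(pre_cols)
  T_all <- ncol(mats[[1]])
  post_cols <- setdiff(seq_len(T_all), pre_cols)

  pre_stack <- lapply(seq_along(mats), function(j) {
    m <- mats[[j]][, pre_cols, drop = FALSE]
    if (direction_hemifield(pds[j]) == "L")
      m[c("LD", "L", "LU", "RU", "R", "RD"), , drop = FALSE]
    else m[c("RU", "R", "RD", "LD", "L", "LU"), , drop = FALSE]
  })
  pre <- Reduce(`+`, pre_stack) / length(pre_stack)
  rownames(pre) <- c(paste0("included_", 1:3), paste0("opposite_", 1:3))

  post_stack <- lapply(seq_along(mats), function(j) {
    m <- mats[[j]][, post_cols, drop = FALSE]
    out <- matrix(NA_real_, 8, ncol(m), dimnames = list(.REL_SLOTS, NULL))
    rel <- (direction_angle(rownames(m)) - direction_angle(pds[j])) %% 360
    out[as.character(rel), ] <- m
    empty <- which(is.na(out[, 1]))
    for (k in empty) {
      lo <- if (k == 1) 8 else k - 1
      hi <- if (k == 8) 1 else k + 1
      out[k, ] <- (out[lo, ] + out[hi, ]) / 2
    }
    out
  })
  post <- Reduce(`+`, post_stack) / length(post_stack)
  rownames(post) <- paste0(ifelse(.REL_SLOTS > 180, .REL_SLOTS - 360, .REL_SLOTS), "deg")
  list(pre = pre, post = post, n = length(mats))
}

#' Rayleigh test of circular uniformity for preferred directions
#'
#' Standard Rayleigh statistic `z = n * Rbar^2` with the closed-form
#' p-value approximation used by circular-statistics toolboxes.
#'
#' @param directions Character vector of PD codes (>= 3).
#' @return List: `statistic = "rayleigh_z"`, `value`, `n`, `p`.
#' @export
rayleigh_uniformity <- function(directions) {
  if (length(directions) < 3) stop("need >= 3 preferred directions")
  th <- direction_angle(directions) * pi / 180
  n <- length(th)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * rbar^2
  Rn <- n * rbar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(statistic = "rayleigh_z", value = z, n = n, p = min(p, 1))
}

#' Cohen's d
#'
#' Two-sample: mean difference over the pooled standard deviation.
#' Paired: mean difference over the standard deviation of the differences.
#'
#' @param x,y Samples; `y` omitted when `x` already holds paired differences.
#' @param paired Logical.
#' @return Numeric effect size.
#' @export
cohens_d <- function(x, y = NULL, paired = FALSE) {
  if (paired) {
    d <- if (is.null(y)) x else x - y
    return(mean(d) / stats::sd(d))
  }
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

#' Eta-squared effect sizes from a fitted aov
#'
#' @param fit An `aov`/`lm` factorial fit.
#' @return Named numeric vector, `SS_effect / SS_total` per model term.
#' @export
eta_squared <- function(fit) {
  tab <- stats::anova(fit)
  ss <- tab[["Sum Sq"]]
  stats::setNames(ss[-length(ss)] / sum(ss), rownames(tab)[-length(ss)])
}
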
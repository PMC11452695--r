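# Time-resolved two-stage two-way-ANOVA classification of each neuron's
# windowed iISI into six task-factor categories, with a consecutive-window
# persistence rule.
#
# Stage 1 asks, separately for each pair of same-hemifield symbolic cues
# (L1/L2 and R1/R2), whether the window's activity depends on the cue object
# and/or the regular target angle (alpha = 0.005 per pair). Stage 2 runs only
# where stage 1 assigned nothing, testing instructed hemifield (2) x angle (3)
# at alpha = 0.01. Categories: object, object_and_choice, potential_space,
# choice_targets, target_position, none.

#' Classify every window of an iISI matrix
#'
#' Vectorized over windows; the two-stage gating is preserved (stage-2
#' p-values are `NA` for windows that stage 1 already assigned).
#' Only regular trials enter the ANOVAs. Windows with an empty design cell or
#' no residual variance are labeled `none` with `NA` p-values.
#'
#' @param values Trials-by-windows matrix of mean iISI (from
#'   [windowed_iisi()]).
#' @param labels `data.frame` with one row per trial: `cue_id`,
#'   `instructed_hemifield`, `target_angle_deg`.
#' @param alpha_stage1,alpha_stage2 Significance levels of the two stages.
#' @return `data.frame` with one row per window: the six stage-1 p-values
#'   (`p_obj_L`, `p_ang_L`, `p_int_L` and the R-pair equivalents), the three
#'   stage-2 p-values (`p_hemi`, `p_ang`, `p_int`), and `raw` (category).
#' @export
classify_windows <- function(values, labels, alpha_stage1 = 0.005,
                             alpha_stage2 = 0.01) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(labels))
  reg <- !is.na(labels$target_angle_deg) &
    labels$target_angle_deg %in% c(-45, 0, 45)
  values <- values[reg, , drop = FALSE]
  labels <- labels[reg, , drop = FALSE]
  W <- ncol(values)
  ang <- factor(labels$target_angle_deg, levels = c(-45, 0, 45))

  pair <- function(side) {
    rows <- labels$cue_id %in% paste0(side, 1:2)
    fast_anova2(values[rows, , drop = FALSE],
                factor(labels$cue_id[rows]), droplevels(ang[rows]))
  }
  L <- pair("L"); R <- pair("R")

  a1 <- alpha_stage1
  oc <- (.sig(L$p_a, a1) & .sig(L$p_b, a1)) | .sig(L$p_ab, a1) |
        (.sig(R$p_a, a1) & .sig(R$p_b, a1)) | .sig(R$p_ab, a1)
  obj <- (.sig(L$p_a, a1) | .sig(R$p_a, a1)) & !oc

  p_hemi <- p_ang2 <- p_int2 <- rep(NA_real_, W)
  open <- which(!(oc | obj))
  if (length(open)) {
    s2 <- fast_anova2(values[, open, drop = FALSE],
                      factor(labels$instructed_hemifield, levels = c("L", "R")), ang)
    p_hemi[open] <- s2$p_a; p_ang2[open] <- s2$p_b; p_int2[open] <- s2$p_ab
  }
  a2 <- alpha_stage2
  sh <- .sig(p_hemi, a2); sa <- .sig(p_ang2, a2); si <- .sig(p_int2, a2)
  raw <- rep("none", W)
  raw[sh & !sa & !si] <- "potential_space"
  raw[sa & !sh & !si] <- "choice_targets"
  raw[si | (sh & sa)] <- "target_position"
  raw[oc] <- "object_and_choice"
  raw[obj] <- "object"

  data.frame(window = seq_len(W),
             p_obj_L = L$p_a, p_ang_L = L$p_b, p_int_L = L$p_ab,
             p_obj_R = R$p_a, p_ang_R = R$p_b, p_int_R = R$p_ab,
             p_hemi = p_hemi, p_ang = p_ang2, p_int = p_int2,
             raw = factor(raw, levels = .FACTOR_CATEGORIES))
}

#' Classify a single window
#'
#' Convenience wrapper around [classify_windows()] for one vector of
#' per-trial window means.
#'
#' @param values Numeric vector, one mean iISI per trial.
#' @inheritParams classify_windows
#' @return One-row `data.frame` as in [classify_windows()].
#' @export
classify_window <- function(values, labels, alpha_stage1 = 0.005,
                            alpha_stage2 = 0.01) {
  classify_windows(matrix(values, ncol = 1), labels, alpha_stage1, alpha_stage2)
}

#' Enforce the consecutive-window persistence rule
#'
#' Runs of identical non-`none` raw categories shorter than `min_run`
#' windows become `none`. Idempotent.
#'
#' @param labels Character or factor vector of per-window raw categories.
#' @param min_run Minimum run length (windows), default 3.
#' @return Factor of filtered labels (levels = the six categories).
#' @export
apply_persistence <- function(labels, min_run = 3) {
  x <- as.character(labels)
  r <- rle(x)
  r$values[r$lengths < min_run & r$values != "none"] <- "none"
  factor(inverse.rle(r), levels = .FACTOR_CATEGORIES)
}

#' Time-resolved factor classification of one neuron
#'
#' Runs [classify_windows()] on the windowed iISI of the regular success
#' choice trials and applies the persistence rule.
#'
#' @param iisi A `sef_iisi` object (see [windowed_iisi()]); rows must match
#'   `trials`.
#' @param trials Trial table rows matching `iisi$trial_ids`.
#' @param alpha_stage1,alpha_stage2,min_run Classifier settings.
#' @return An object of class `sef_factor_track`: `neuron_id`, `grid`,
#'   `raw`, `labels` (persistence-filtered) and the window p-value table.
#' @export
classify_neuron <- function(iisi, trials, alpha_stage1 = 0.005,
                            alpha_stage2 = 0.01, min_run = 3) {
  stopifnot(inherits(iisi, "sef_iisi"),
            identical(iisi$trial_ids, trials$trial_id))
  keep <- trials$task == "choice" & trials$outcome == "success"
  res <- classify_windows(iisi$values[keep, , drop = FALSE],
                          trials[keep, , drop = FALSE],
                          alpha_stage1, alpha_stage2)
  structure(list(neuron_id = iisi$neuron_id, grid = iisi$grid,
                 raw = res$raw, labels = apply_persistence(res$raw, min_run),
                 pvalues = res),
            class = "sef_factor_track")
}

#' Fraction of neurons per category over time
#'
#' @param tracks List of `sef_factor_track` objects on a common grid.
#' @return Windows-by-categories matrix of fractions (categories are mutually
#'   exclusive per neuron-window, so rows sum to at most 1).
#' @export
population_fractions <- function(tracks) {
  if (length(tracks) == 0) stop("empty track list")
  g <- tracks[[1]]$grid
  if (!all(vapply(tracks, function(t) same_grid(t$grid, g), TRUE)))
    stop("tracks have heterogeneous grids")
  cats <- setdiff(.FACTOR_CATEGORIES, "none")
  lab <- vapply(tracks, function(t) as.character(t$labels),
                character(length(g$starts)))
  out <- vapply(cats, function(cat) rowMeans(lab == cat),
                numeric(length(g$starts)))
  rownames(out) <- NULL
  out
}

#' Did a neuron represent each category during each epoch?
#'
#' A category is represented during an epoch if any persistence-filtered
#' window of that category overlaps the epoch (any-overlap rule).
#'
#' @param track A `sef_factor_track`.
#' @param epochs Named list of length-2 numeric vectors `c(start, end)` in
#'   grid-aligned time, e.g.
#'   `list(preselection = c(0, 1.2), determination = c(0, 0.75))`.
#' @return Logical matrix, epochs x categories.
#' @export
summarize_epochs <- function(track, epochs) {
  g <- track$grid
  w_start <- g$starts; w_end <- g$starts + g$width_s
  cats <- setdiff(.FACTOR_CATEGORIES, "none")
  out <- matrix(FALSE, length(epochs), length(cats),
                dimnames = list(names(epochs), cats))
  for (e in seq_along(epochs)) {
    ep <- epochs[[e]]
    if (ep[1] < g$start_s - 1e-9 || ep[2] > g$stop_s + 1e-9)
      stop("epoch '", names(epochs)[e], "' lies outside the grid coverage")
    ov <- w_start < ep[2] & w_end > ep[1]
    for (cat in cats) out[e, cat] <- any(track$labels[ov] == cat)
  }
  out
}
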
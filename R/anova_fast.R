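# Vectorized factorial ANOVA shared by the sliding-window classifiers.
#
# The time-resolved analyses test the same fixed design against hundreds of
# response columns (one per 10-ms window), so the projections are computed
# once per design via QR and reused for every column. Type-II sums of squares:
#   SS_A  = RSS(B) - RSS(A + B)
#   SS_B  = RSS(A) - RSS(A + B)
#   SS_AB = RSS(A + B) - RSS(A * B)
# with the error term from the full model. Equivalent to car::Anova(type = 2)
# for factorial lm fits (cross-checked in the unit tests).

.rss_fun <- function(X) {
  qr_ <- qr(X)
  r <- qr_$rank
  function(Y) {
    qty <- qr.qty(qr_, Y)
    colSums(Y^2) - colSums(qty[seq_len(r), , drop = FALSE]^2)
  }
}

# Y: n x W response matrix; fA, fB: factors of length n.
# Returns per-window p-values (and F, SS) for the A and B main effects and
# the interaction, or all-NA (ok = FALSE) if any design cell has < 2 trials.
fast_anova2 <- function(Y, fA, fB) {
  Y <- as.matrix(Y)
  fA <- droplevels(as.factor(fA)); fB <- droplevels(as.factor(fB))
  W <- ncol(Y); n <- nrow(Y)
  na_out <- list(p_a = rep(NA_real_, W), p_b = rep(NA_real_, W),
                 p_ab = rep(NA_real_, W), ok = FALSE)
  a <- nlevels(fA); b <- nlevels(fB)
  if (a < 2 || b < 2 || any(table(fA, fB) < 2)) return(na_out)
  df_a <- a - 1; df_b <- b - 1; df_ab <- df_a * df_b; df_e <- n - a * b
  if (df_e <= 0) return(na_out)

  rss_full <- .rss_fun(stats::model.matrix(~ fA * fB))(Y)
  rss_add  <- .rss_fun(stats::model.matrix(~ fA + fB))(Y)
  rss_a    <- .rss_fun(stats::model.matrix(~ fA))(Y)
  rss_b    <- .rss_fun(stats::model.matrix(~ fB))(Y)

  ss_a  <- pmax(rss_b - rss_add, 0)
  ss_b  <- pmax(rss_a - rss_add, 0)
  ss_ab <- pmax(rss_add - rss_full, 0)
  mse <- rss_full / df_e
  # a window with zero residual variance (e.g. all-zero iISI) is undefined
  degenerate <- mse <= 1e-300
  p_of <- function(ss, df) {
    p <- stats::pf((ss / df) / mse, df, df_e, lower.tail = FALSE)
    p[degenerate] <- NA_real_
    p
  }
  list(p_a = p_of(ss_a, df_a), p_b = p_of(ss_b, df_b), p_ab = p_of(ss_ab, df_ab),
       f_a = (ss_a / df_a) / mse, f_b = (ss_b / df_b) / mse,
       f_ab = (ss_ab / df_ab) / mse,
       df = c(a = df_a, b = df_b, ab = df_ab, error = df_e), ok = TRUE)
}
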
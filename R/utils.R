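# Shared geometry and small helpers.

# Canonical target directions on the 10-degree circle. Polar angle in degrees,
# 0 = right, counter-clockwise positive; Up (90) and Down (270) are never shown.
.DIR_ANGLE <- c(R = 0, RU = 45, LU = 135, L = 180, LD = 225, RD = 315)
.DIR_LEVELS <- c("LD", "L", "LU", "RU", "R", "RD")
.CUE_LEVELS <- c("L1", "L2", "R1", "R2")
.CUE_HEMIFIELD <- c(L1 = "L", L2 = "L", R1 = "R", R2 = "R")
.FACTOR_CATEGORIES <- c("object", "object_and_choice", "potential_space",
                        "choice_targets", "target_position", "none")

#' Polar angle of a canonical target direction
#'
#' @param dir Character vector of direction codes (`"LD"`, `"L"`, `"LU"`,
#'   `"RU"`, `"R"`, `"RD"`).
#' @return Numeric vector of polar angles in degrees (0 = right, CCW positive).
#' @export
direction_angle <- function(dir) {
  bad <- !dir %in% names(.DIR_ANGLE)
  if (any(bad)) stop("unknown direction: ", paste(unique(dir[bad]), collapse = ", "))
  unname(.DIR_ANGLE[dir])
}

#' Visual hemifield containing a canonical direction
#'
#' @inheritParams direction_angle
#' @return `"L"` or `"R"` for each direction.
#' @export
direction_hemifield <- function(dir) {
  bad <- !dir %in% names(.DIR_ANGLE)
  if (any(bad)) stop("unknown direction: ", paste(unique(dir[bad]), collapse = ", "))
  ifelse(dir %in% c("LD", "L", "LU"), "L", "R")
}

# Direction of the chosen target given the configuration angle of the target
# pair and the hemifield of the choice. The right-side target sits at polar
# angle `angle_deg`, the left-side target at `angle_deg + 180`. Non-regular
# angles are snapped to the nearest canonical direction.
choice_target_direction <- function(angle_deg, hemifield) {
  snap <- c(-45, 0, 45)
  a <- snap[max.col(-abs(outer(angle_deg, snap, "-")))]
  r <- c("-45" = "RD", "0" = "R", "45" = "RU")[as.character(a)]
  l <- c("-45" = "LU", "0" = "L", "45" = "LD")[as.character(a)]
  unname(ifelse(hemifield == "R", r, l))
}

# Evaluate `code` with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched. `seed = NULL` evaluates in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seed derived from a master seed and integer keys;
# stays below 2^31 so it is a valid R integer seed.
derive_seed <- function(master, ...) {
  k <- as.numeric(c(...))
  mults <- c(7919, 104729, 1299709, 15485863)[seq_along(k)]
  as.integer((as.numeric(master) + sum(k * mults)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# significance helper: NA p-values count as not significant
.sig <- function(p, alpha) !is.na(p) & p <= alpha
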
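# Weighted Pattern Generating Potential (w-PGP): a [0, 1] score that
# rewards correctly predicted expression and penalises erroneous
# (over-)prediction, weighting each bin by the real expression level.
#
# Definition used throughout this package (both profiles scaled to
# [0, 1] on a shared grid):
#   reward  = sum_i min(p_i, r_i) * r_i / sum_i r_i^2
#   penalty = sum_i max(p_i - r_i, 0) * (1 - r_i) / sum_i (1 - r_i)^2
#   score   = clamp(reward - penalty, 0, 1)
# Degenerate denominators: an all-zero real profile gives reward 1 iff
# the prediction is also all zero (else 0); an all-one real profile
# gives penalty 0.

# numeric-vector core, shared by the scalar and matrix interfaces
wpgp_terms <- function(p, r) {
  rr <- sum(r * r)
  reward <- if (rr > 0) sum(pmin(p, r) * r) / rr else as.numeric(all(p == 0))
  hh <- sum((1 - r)^2)
  penalty <- if (hh > 0) sum(pmax(p - r, 0) * (1 - r)) / hh else 0
  c(reward = reward, penalty = penalty,
    score = min(max(reward - penalty, 0), 1))
}

wpgp_score <- function(p, r) wpgp_terms(p, r)[["score"]]

#' Weighted Pattern Generating Potential score
#'
#' Compares a predicted against a real spatial expression profile,
#' returning a reward/penalty breakdown and their clamped difference.
#'
#' @param pred Predicted profile: an [axis_profile()] or numeric vector
#'   with values in `[0, 1]`.
#' @param real Real profile on the same grid, values in `[0, 1]`.
#' @return A list of class `wpgp` with elements `reward`, `penalty`,
#'   `score`, each in `[0, 1]`.
#' @export
wpgp <- function(pred, real) {
  p <- if (inherits(pred, "axis_profile")) pred$values else as.numeric(pred)
  r <- if (inherits(real, "axis_profile")) real$values else as.numeric(real)
  if (inherits(pred, "axis_profile") && inherits(real, "axis_profile") &&
      !isTRUE(all.equal(pred$axis, real$axis)))
    stop("profiles are not on the same axis grid")
  if (length(p) != length(r)) stop("profiles differ in length")
  if (any(p < 0 | p > 1) || any(r < 0 | r > 1))
    stop("w-PGP requires values in [0, 1]")
  out <- as.list(wpgp_terms(p, r))
  class(out) <- "wpgp"
  out
}

#' @export
print.wpgp <- function(x, ...) {
  cat(sprintf("w-PGP score %.4f (reward %.4f, penalty %.4f)\n",
              x$score, x$reward, x$penalty))
  invisible(x)
}

#' Mean w-PGP over several profile pairs
#'
#' @param pairs List of `list(pred = , real = )` pairs.
#' @return Arithmetic mean of the per-pair scores.
#' @export
mean_wpgp <- function(pairs) {
  if (!length(pairs)) stop("empty list of profile pairs")
  mean(vapply(pairs, function(pr) wpgp(pr$pred, pr$real)$score, 0))
}

# scores of many predictions (rows of P) against one real profile r
wpgp_rows <- function(P, r) {
  rr <- sum(r * r)
  hh <- sum((1 - r)^2)
  Rm <- matrix(r, nrow(P), ncol(P), byrow = TRUE)
  reward <- if (rr > 0) as.numeric(pmin(P, Rm) %*% r) / rr else
    as.numeric(rowSums(P) == 0)
  penalty <- if (hh > 0) as.numeric(pmax(P - Rm, 0) %*% (1 - r)) / hh else 0
  pmin(pmax(reward - penalty, 0), 1)
}
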
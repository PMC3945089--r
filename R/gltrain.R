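# Two-tiered locus-level training: stripe decomposition, Phase-1 window
# scanning, Phase-2 greedy window inclusion with weight optimisation,
# and the outer loop re-estimating the thermodynamic parameters.

#' Training configuration for the locus-level model
#'
#' Defaults are the standard settings of the method: candidate windows
#' start every 100 bp and range from 500 to 2500 bp in 50 bp length
#' steps, 5 candidates are kept per stripe, and the outer loop runs up
#' to 100 iterations or until the score improves by less than `delta`.
#'
#' @param n_candidates Best windows kept per stripe in Phase 1.
#' @param start_step Window start grid spacing (bp).
#' @param min_len,max_len Window length range (bp).
#' @param len_step Window length grid spacing (bp).
#' @param outer_iters Maximum outer iterations `N_I`.
#' @param delta Minimum score improvement to continue iterating.
#' @param on_threshold Expression level at or above which a bin is ON.
#' @param accessibility_mask Optional data frame of accessible intervals
#'   (`start`, `end`, 0-based half-open); a window must be at least 50%
#'   covered to be considered.
#' @return A list of class `train_config`.
#' @export
train_config <- function(n_candidates = 5L, start_step = 100L,
                         min_len = 500L, max_len = 2500L, len_step = 50L,
                         outer_iters = 100L, delta = 1e-4,
                         on_threshold = 0.5, accessibility_mask = NULL) {
  stopifnot(n_candidates >= 1, start_step >= 1, min_len >= 1,
            max_len >= min_len, len_step >= 1, outer_iters >= 1,
            delta > 0, on_threshold > 0, on_threshold < 1)
  structure(list(n_candidates = as.integer(n_candidates),
                 start_step = as.integer(start_step),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 len_step = as.integer(len_step),
                 outer_iters = as.integer(outer_iters), delta = delta,
                 on_threshold = on_threshold,
                 accessibility_mask = accessibility_mask),
            class = "train_config")
}

#' Decompose an expression profile into stripes
#'
#' Maximal contiguous runs of bins at or above the ON threshold become
#' stripes, ordered anterior to posterior; each stripe profile equals
#' the gene profile inside its extent and 0 elsewhere.
#'
#' @param gene_profile An [axis_profile()] scaled to `[0, 1]`.
#' @param on_threshold ON/OFF threshold (a bin exactly at the threshold
#'   is ON).
#' @return List of stripes, each a list with `index`, `extent` (first
#'   and last bin index) and `profile` (an [axis_profile()]).
#' @export
decompose_stripes <- function(gene_profile, on_threshold = 0.5) {
  stopifnot(inherits(gene_profile, "axis_profile"),
            on_threshold > 0, on_threshold < 1)
  v <- gene_profile$values
  on <- v >= on_threshold
  if (!any(on)) stop("no expression domains at threshold ", on_threshold)
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  lapply(seq_along(runs), function(i) {
    k <- runs[i]
    prof <- numeric(length(v))
    prof[starts[k]:ends[k]] <- v[starts[k]:ends[k]]
    list(index = i, extent = c(starts[k], ends[k]),
         profile = axis_profile(prof, gene_profile$axis))
  })
}

# gene profile limited to the first i stripes: the pattern as if the
# later stripes were absent (their extents zeroed); sub-threshold
# expression elsewhere is kept, so genuinely present flank/valley
# signal is never penalised as over-expression
restrict_to_stripes <- function(gene_profile, stripes, i) {
  out <- gene_profile$values
  for (k in seq_along(stripes)) {
    if (k > i) {
      e <- stripes[[k]]$extent
      out[e[1]:e[2]] <- 0
    }
  }
  out
}

# enumerate the window grid over a locus of length L
enumerate_windows <- function(L, cfg) {
  starts <- seq(0L, max(L - cfg$min_len, 0L), by = cfg$start_step)
  lens <- seq(cfg$min_len, cfg$max_len, by = cfg$len_step)
  g <- expand.grid(start = starts, length = lens)
  g <- g[g$start + g$length <= L, , drop = FALSE]
  if (!nrow(g)) stop("locus shorter than the minimum window length")
  mask <- cfg$accessibility_mask
  if (!is.null(mask)) {
    cov <- vapply(seq_len(nrow(g)), function(i) {
      a <- g$start[i]; b <- a + g$length[i]
      sum(pmax(0, pmin(mask$end, b) - pmax(mask$start, a)))
    }, 0)
    g <- g[cov >= 0.5 * g$length, , drop = FALSE]
    if (!nrow(g)) stop("no window passes the accessibility mask")
  }
  g <- g[order(g$start, g$length), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# readout matrix (windows x bins) for a window grid under theta
window_readouts <- function(annotation, windows, theta, ctx) {
  s <- sites_for(annotation, ctx$tf_names)
  cpp_window_readouts(s$start, s$end, s$tf, s$aff, t(ctx$conc),
                      theta_cpp(theta, ctx$tf_names),
                      as.integer(windows$start),
                      as.integer(windows$start + windows$length))
}

#' Phase 1: scan candidate windows for each stripe
#'
#' Every window on the start/length grid is read out under the current
#' thermodynamic parameters and scored by w-PGP against each stripe's
#' profile; the best `n_candidates` windows per stripe are kept.  Ties
#' break to the leftmost start, then the shortest length.
#'
#' @param annotation A `site_annotation` of the locus.
#' @param locus_length Locus length in bp.
#' @param stripes Output of [decompose_stripes()].
#' @param theta Current [thermo_params()].
#' @param ctx A [tf_context()].
#' @param cfg A [train_config()].
#' @return List with `windows` (the grid), `readouts` (window x bin
#'   matrix, cached for Phase 2) and `candidates` (per-stripe window
#'   indices, best first).
#' @export
phase1_scan <- function(annotation, locus_length, stripes, theta, ctx,
                        cfg) {
  if (locus_length < cfg$min_len)
    stop("locus shorter than the minimum window length")
  windows <- enumerate_windows(locus_length, cfg)
  readouts <- window_readouts(annotation, windows, theta, ctx)
  candidates <- lapply(stripes, function(s) {
    sc <- wpgp_rows(readouts, s$profile$values)
    ord <- order(-sc, windows$start, windows$length)
    head(ord, cfg$n_candidates)
  })
  list(windows = windows, readouts = readouts, candidates = candidates)
}

#' Optimise non-negative window weights against a target profile
#'
#' Maximises the w-PGP of the weighted window-readout sum (clipped at 1
#' before scoring) over non-negative weights.
#'
#' @param readouts Matrix of cached window readouts (windows x bins).
#' @param target Target profile values in `[0, 1]`.
#' @param init_weights Starting weights (warm start).
#' @return List with `weights` and `score`.
#' @export
optimize_weights <- function(readouts, target,
                             init_weights = rep(1, nrow(readouts))) {
  readouts <- rbind(readouts)
  k <- nrow(readouts)
  if (k < 1L) stop("at least one window required")
  if (all(readouts == 0)) {
    warning("all window readouts are zero")
    return(list(weights = rep(0, k), score = 0))
  }
  obj <- function(w) wpgp_score(pmin(as.numeric(w %*% readouts), 1), target)
  r <- optimize_box(obj, pmin(pmax(init_weights, 0), 10),
                    lower = rep(0, k), upper = rep(10, k))
  list(weights = r$par, score = r$value)
}

#' Phase 2: greedy window inclusion
#'
#' Stripes are processed anterior to posterior.  For stripe i, every
#' remaining candidate is evaluated by re-optimising the weights of the
#' current windows plus the candidate against the gene profile
#' restricted to stripes 1..i; the best candidate is accepted iff it
#' strictly improves the running best score, and candidate scanning for
#' the stripe repeats until no candidate improves.
#'
#' @param ph1 Output of [phase1_scan()].
#' @param gene_profile The gene's [axis_profile()].
#' @param stripes Output of [decompose_stripes()].
#' @param cfg A [train_config()].
#' @return List with `window_idx` (indices into `ph1$windows`),
#'   `weights`, `score` (final BESTSCORE) and `trace`.
#' @export
phase2_greedy <- function(ph1, gene_profile, stripes, cfg) {
  sel <- integer(0)
  weights <- numeric(0)
  best <- 0
  trace <- numeric(0)
  cand <- ph1$candidates
  for (i in seq_along(stripes)) {
    target <- restrict_to_stripes(gene_profile, stripes, i)
    # re-baseline: the running best must be comparable to candidate
    # scores, which are computed against the target extended to stripe i
    if (length(sel)) {
      base <- optimize_weights(ph1$readouts[sel, , drop = FALSE], target,
                               init_weights = weights)
      weights <- base$weights
      best <- base$score
    }
    repeat {
      pool <- cand[[i]]
      if (!length(pool)) break
      trial <- lapply(pool, function(w) {
        optimize_weights(ph1$readouts[c(sel, w), , drop = FALSE], target,
                         init_weights = c(weights, 1))
      })
      scores <- vapply(trial, `[[`, 0, "score")
      b <- which.max(scores)
      if (scores[b] > best + cfg$delta) {
        sel <- c(sel, pool[b])
        weights <- trial[[b]]$weights
        best <- scores[b]
        cand[[i]] <- pool[-b]
        trace <- c(trace, best)
      } else break
    }
  }
  list(window_idx = sel, weights = weights, score = best, trace = trace)
}

#' Construct a two-tiered locus model object
#'
#' Usually produced by [fit_locus()]; exposed so that models with known
#' windows and weights (e.g. planted synthetic truths) can be analysed
#' with the same downstream tools.
#'
#' @param windows Data frame with `start`, `length` and `weight`.
#' @param theta A [thermo_params()].
#' @param annotation The locus `site_annotation`.
#' @param ctx A [tf_context()].
#' @param gene_profile The target [axis_profile()] (optional).
#' @param cfg A [train_config()] (optional).
#' @param trace Optional per-iteration score trace.
#' @return An object of class `locus_model`.
#' @export
locus_model <- function(windows, theta, annotation, ctx,
                        gene_profile = NULL, cfg = train_config(),
                        trace = NULL) {
  stopifnot(is.data.frame(windows),
            all(c("start", "length", "weight") %in% names(windows)),
            all(windows$weight >= 0))
  m <- structure(list(windows = windows, theta = theta,
                      annotation = annotation, ctx = ctx,
                      gene_profile = gene_profile, cfg = cfg,
                      trace = trace, call = sys.call(-1)),
                 class = "locus_model")
  m$prediction <- predict_gene_expression(m, ctx)
  m$score <- if (!is.null(gene_profile))
    wpgp_score(m$prediction$values, gene_profile$values) else NA_real_
  m
}

#' Predict gene expression from a fitted locus model
#'
#' The weighted sum of the model windows' thermodynamic readouts,
#' clipped to `[0, 1]`.
#'
#' @param model A `locus_model`.
#' @param ctx A [tf_context()] (defaults to the model's own).
#' @return An [axis_profile()].
#' @export
predict_gene_expression <- function(model, ctx = model$ctx) {
  if (nrow(model$windows) == 0L)
    return(axis_profile(numeric(length(ctx$axis)) , ctx$axis))
  E <- window_readouts(model$annotation, model$windows, model$theta, ctx)
  axis_profile(pmin(pmax(as.numeric(model$windows$weight %*% E), 0), 1),
               ctx$axis)
}

#' Fit the two-tiered locus-level expression model
#'
#' Iterates Phase-1 window scanning, Phase-2 greedy window selection
#' with weight optimisation, and a constrained re-fit of the
#' thermodynamic parameters (each parameter restricted to a two-fold box
#' around its initial value), until `outer_iters` iterations or until
#' the score improves by less than `delta`.  The best model seen is
#' returned.
#'
#' @param locus A [dna_sequence()] (scanned with `pwms`) or `NULL` if
#'   `sites` is supplied.
#' @param gene_profile The gene's expression [axis_profile()], scaled to
#'   `[0, 1]`.
#' @param ctx A [tf_context()].
#' @param init_theta Initial [thermo_params()], typically from
#'   [fit_enhancer_set()] on an external enhancer panel.
#' @param cfg A [train_config()].
#' @param pwms List of [pwm()]s (required with a raw sequence).
#' @param sites Optional pre-computed `site_annotation` (used by the
#'   site-relocation control); overrides scanning.
#' @param locus_length Required with `sites`: locus length in bp.
#' @param rel_affinity_threshold Site-calling threshold.
#' @param constrain_theta If `FALSE` (control experiments), the
#'   parameter re-fit uses wide bounds instead of the two-fold box.
#' @return An object of class `locus_model`.
#' @export
fit_locus <- function(locus, gene_profile, ctx, init_theta,
                      cfg = train_config(), pwms = NULL, sites = NULL,
                      locus_length = NULL, rel_affinity_threshold = 0.01,
                      constrain_theta = TRUE) {
  if (is.null(sites)) {
    stopifnot(inherits(locus, "dna_sequence"))
    locus_length <- nchar(locus$residues)
    sites <- scan_sites(locus, pwms, rel_affinity_threshold)
  } else if (is.null(locus_length)) {
    stop("locus_length required when sites are supplied directly")
  }
  stripes <- decompose_stripes(gene_profile, cfg$on_threshold)
  theta <- init_theta
  best <- NULL
  trace <- numeric(0)
  for (it in seq_len(cfg$outer_iters)) {
    ph1 <- phase1_scan(sites, locus_length, stripes, theta, ctx, cfg)
    ph2 <- phase2_greedy(ph1, gene_profile, stripes, cfg)
    windows <- cbind(ph1$windows[ph2$window_idx, , drop = FALSE],
                     weight = ph2$weights)
    rownames(windows) <- NULL
    # score and theta re-fit use the full (unrestricted) gene profile
    score <- if (nrow(windows)) wpgp_score(
      pmin(as.numeric(ph2$weights %*%
                        ph1$readouts[ph2$window_idx, , drop = FALSE]), 1),
      gene_profile$values) else 0
    if (nrow(windows)) {
      refit <- refit_theta(sites, windows, gene_profile, ctx, theta,
                           init_theta, constrain_theta)
      if (refit$score > score) { theta <- refit$theta; score <- refit$score }
    }
    trace <- c(trace, score)
    improved <- is.null(best) || score > best$score + cfg$delta
    if (is.null(best) || score > best$score)
      best <- list(windows = windows, theta = theta, score = score)
    if (!improved) break
  }
  locus_model(best$windows, best$theta, sites, ctx,
              gene_profile = gene_profile, cfg = cfg, trace = trace)
}

# re-fit theta with windows and weights fixed
refit_theta <- function(sites, windows, gene_profile, ctx, theta,
                        init_theta, constrained) {
  b <- theta_bounds(init_theta, constrained)
  s <- sites_for(sites, ctx$tf_names)
  concT <- t(ctx$conc)
  ws <- as.integer(windows$start)
  we <- as.integer(windows$start + windows$length)
  w <- windows$weight
  obj <- function(par) {
    pl <- theta_cpp(par_to_theta(par, init_theta), ctx$tf_names)
    E <- cpp_window_readouts(s$start, s$end, s$tf, s$aff, concT, pl, ws, we)
    wpgp_score(pmin(as.numeric(w %*% E), 1), gene_profile$values)
  }
  start <- pmin(pmax(theta_to_par(theta), b$lower), b$upper)
  r <- optimize_box(obj, start, b$lower, b$upper, nm_iter = 150L,
                    rounds = 1L)
  list(theta = par_to_theta(r$par, init_theta), score = r$value)
}

# ---- methods ---------------------------------------------------------

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("Two-tiered locus expression model (%s mode)\n",
              x$theta$mode))
  cat(sprintf("  %d window(s), w-PGP score %.4f\n", nrow(x$windows),
              x$score))
  if (nrow(x$windows)) {
    w <- x$windows
    cat(sprintf("  window %d: [%d, %d) weight %.3f\n",
                seq_len(nrow(w)), w$start, w$start + w$length,
                round(w$weight, 3)), sep = "")
  }
  invisible(x)
}

#' @export
#' @method summary locus_model
summary.locus_model <- function(object, ...) {
  print(object)
  cat("\nThermodynamic parameters:\n")
  print(object$theta)
  if (!is.null(object$trace))
    cat("Outer-iteration scores:",
        paste(sprintf("%.4f", object$trace), collapse = " "), "\n")
  invisible(object)
}

#' @export
#' @method coef locus_model
coef.locus_model <- function(object, ...) {
  w <- object$windows$weight
  names(w) <- sprintf("window_%d", seq_along(w))
  attr(w, "theta") <- object$theta
  w
}

#' Predict from a locus model
#'
#' @param object A `locus_model`.
#' @param ctx Optional alternative [tf_context()] (e.g. with a TF
#'   knocked down).
#' @param knockdown Optional TF name whose concentration is zeroed
#'   before predicting.
#' @param ... Unused.
#' @return An [axis_profile()].
#' @export
predict.locus_model <- function(object, ctx = object$ctx,
                                knockdown = NULL, ...) {
  if (!is.null(knockdown)) ctx <- zero_tf(ctx, knockdown)
  predict_gene_expression(object, ctx)
}

#' @export
fitted.locus_model <- function(object, ...) object$prediction$values

#' @export
#' @method residuals locus_model
residuals.locus_model <- function(object, ...) {
  if (is.null(object$gene_profile)) stop("model has no target profile")
  object$prediction$values - object$gene_profile$values
}

#' Plot a locus model fit
#'
#' Real (if available) and predicted expression along the axis, with a
#' rug of selected windows scaled to the locus.
#'
#' @param x A `locus_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
#' @method plot locus_model
plot.locus_model <- function(x, ...) {
  ax <- x$prediction$axis
  graphics::plot(ax, x$prediction$values, type = "l", col = "darkgreen",
                 lwd = 2, ylim = c(0, 1), xlab = "axis position",
                 ylab = "relative expression", ...)
  if (!is.null(x$gene_profile))
    graphics::lines(ax, x$gene_profile$values, col = "red", lwd = 2)
  graphics::legend("topright", legend = c("predicted", "real"),
                   col = c("darkgreen", "red"), lwd = 2, bty = "n")
  invisible(x)
}
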
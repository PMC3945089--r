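# Post-fit analyses: MCMC sampling of regulatory architectures,
# in-silico TF knockdowns and network inference, enhancer cross-talk
# hypergraph, and the two-enhancer promoter-competition utility.

#' Zero one TF's concentration profile (in-silico knockdown)
#'
#' @param ctx A [tf_context()].
#' @param tf TF name.
#' @return A new context with the TF's concentration set to zero at
#'   every axis position.
#' @export
zero_tf <- function(ctx, tf) {
  if (!tf %in% ctx$tf_names) stop("unknown TF: ", tf)
  ctx$conc[, tf] <- 0
  ctx
}

#' Re-evaluate a trained model with one TF knocked down
#'
#' The trained model is re-run, not re-optimised, with the TF's
#' relative concentration set to zero along the whole axis.
#'
#' @param model A `locus_model`.
#' @param ctx A [tf_context()] (defaults to the model's own).
#' @param tf TF name to knock down.
#' @return The knocked-down prediction as an [axis_profile()].
#' @export
knockdown_tf <- function(model, ctx = model$ctx, tf) {
  predict_gene_expression(model, zero_tf(ctx, tf))
}

# ---- architecture MCMC ----------------------------------------------

#' Propose a new architecture bit vector
#'
#' Picks two bit positions at random and toggles each with probability
#' 1/2, so the proposal equals the current vector with probability 1/4,
#' differs in one bit with probability 1/2 and in two bits with
#' probability 1/4.
#'
#' @param bits Logical or 0/1 vector over the window grid.
#' @return The proposed bit vector.
#' @export
propose_architecture_bits <- function(bits) {
  n <- length(bits)
  if (n < 2L) stop("need at least two grid windows")
  pick <- sample.int(n, 2L, replace = FALSE)
  flip <- runif(2L) < 0.5
  bits[pick[flip]] <- !bits[pick[flip]]
  bits
}

#' Sample regulatory architectures by Metropolis-Hastings
#'
#' Each sample is an extended weight vector over the full window grid:
#' the proposal toggles up to two windows in or out, active windows
#' receive Dirichlet(1, ..., 1) weights (summing to 1), and the proposal
#' is accepted with probability `min(1, Score_new / Score_old)` where
#' the score is the w-PGP of the implied weighted-sum model.  The score
#' of the empty architecture is floored at `score_floor` to keep
#' acceptance ratios finite.
#'
#' @param annotation Locus `site_annotation`.
#' @param locus_length Locus length (bp).
#' @param gene_profile Target [axis_profile()].
#' @param theta Fixed [thermo_params()].
#' @param ctx A [tf_context()].
#' @param cfg A [train_config()] defining the window grid.
#' @param n_samples Number of MCMC samples (>= 1).
#' @param rng_seed Integer seed.
#' @param score_fn Optional function(bits, weights) -> score, replacing
#'   the default w-PGP model score (useful for exact toy spaces).
#' @param score_floor Score assigned to the all-zero architecture.
#' @return List with `windows` (the grid), `avg_weight` (mean weight per
#'   grid window over samples), `scores`, `n_active` and `samples`
#'   (per-sample active indices and weights).
#' @export
mcmc_sample <- function(annotation, locus_length, gene_profile, theta,
                        ctx, cfg = train_config(), n_samples,
                        rng_seed = 1L, score_fn = NULL,
                        score_floor = 1e-6) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  windows <- enumerate_windows(locus_length, cfg)
  n <- nrow(windows)
  if (is.null(score_fn)) {
    readouts <- window_readouts(annotation, windows, theta, ctx)
    score_fn <- function(bits, weights) {
      act <- which(bits)
      if (!length(act)) return(score_floor)
      max(wpgp_score(pmin(as.numeric(
        weights %*% readouts[act, , drop = FALSE]), 1),
        gene_profile$values), score_floor)
    }
  }
  set.seed(rng_seed)
  bits <- rep(FALSE, n)
  weights <- numeric(0)
  score <- score_fn(bits, weights)
  avg <- numeric(n)
  scores <- numeric(n_samples)
  n_active <- integer(n_samples)
  samples <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    nb <- propose_architecture_bits(bits)
    act <- which(nb)
    nw <- if (length(act)) {
      g <- rgamma(length(act), 1)  # Dirichlet(1,...,1) over active bits
      g / sum(g)
    } else numeric(0)
    ns <- score_fn(nb, nw)
    if (runif(1) < ns / score) {
      bits <- nb; weights <- nw; score <- ns
    }
    cur <- which(bits)
    avg[cur] <- avg[cur] + weights
    scores[i] <- score
    n_active[i] <- length(cur)
    samples[[i]] <- list(active = cur, weights = weights)
  }
  list(windows = windows, avg_weight = avg / n_samples, scores = scores,
       n_active = n_active, samples = samples)
}

# ---- TF-stripe network inference ------------------------------------

# half-maximum boundary positions of a prediction within/around a
# stripe extent; returns c(anterior, posterior) axis positions (NA if
# the flank never falls below half-maximum)
half_max_boundaries <- function(values, axis, extent) {
  seg <- extent[1]:extent[2]
  pk <- seg[which.max(values[seg])]
  half <- values[pk] / 2
  cross <- function(from, by) {
    i <- pk
    repeat {
      j <- i + by
      if (j < 1 || j > length(values)) return(NA_real_)
      if (values[j] < half) {
        # linear interpolation between bins j and i
        f <- (values[i] - half) / (values[i] - values[j])
        return(axis[i] + f * (axis[j] - axis[i]))
      }
      i <- j
    }
  }
  c(anterior = cross(pk, -1L), posterior = cross(pk, +1L))
}

#' Classify a knockdown's influence on one stripe
#'
#' A knockdown that weakens the stripe's peak by at least 2% (relative)
#' indicates activation; otherwise a strengthening of at least 2%
#' and/or a half-maximum boundary shift of at least 1% of the axis
#' indicates repression.
#'
#' @param level_change_pct Relative change (%) of the stripe peak under
#'   knockdown (negative = weakened).
#' @param boundary_shift_pct Largest half-maximum boundary shift, in %
#'   of the axis.
#' @param level_threshold,shift_threshold Rule thresholds.
#' @return `"activation"`, `"repression"` or `NA`.
#' @export
classify_influence <- function(level_change_pct, boundary_shift_pct,
                               level_threshold = 2, shift_threshold = 1) {
  if (is.finite(level_change_pct) &&
      level_change_pct <= -level_threshold) return("activation")
  if ((is.finite(level_change_pct) &&
       level_change_pct >= level_threshold) ||
      (is.finite(boundary_shift_pct) &&
       boundary_shift_pct >= shift_threshold)) return("repression")
  NA_character_
}

#' Infer a TF-stripe regulatory network by in-silico knockdowns
#'
#' Each TF is knocked down in turn and the model re-evaluated; per
#' stripe, the change of the predicted peak level and the shift of the
#' half-maximum boundaries decide activation/repression edges (see
#' [classify_influence()]).
#'
#' @param model A `locus_model`.
#' @param ctx A [tf_context()] (defaults to the model's own).
#' @param stripes Stripes of the target profile; default decomposes the
#'   model's own gene profile.
#' @return Data frame of edges: `tf`, `stripe`, `sign`,
#'   `level_change_pct`, `boundary_shift_pct`.
#' @export
infer_network <- function(model, ctx = model$ctx,
                          stripes = decompose_stripes(model$gene_profile,
                                                      model$cfg$on_threshold)) {
  base <- predict_gene_expression(model, ctx)
  ax <- base$axis
  edges <- list()
  for (tf in ctx$tf_names) {
    kd <- knockdown_tf(model, ctx, tf)
    for (s in stripes) {
      seg <- s$extent[1]:s$extent[2]
      pk <- seg[which.max(base$values[seg])]
      if (base$values[pk] <= 0) {
        warning("stripe ", s$index, " has zero predicted peak; skipped")
        next
      }
      lvl <- 100 * (kd$values[pk] - base$values[pk]) / base$values[pk]
      b0 <- half_max_boundaries(base$values, ax, s$extent)
      b1 <- half_max_boundaries(kd$values, ax, s$extent)
      d <- abs(b1 - b0)
      d <- d[is.finite(d)]
      shift <- if (length(d)) 100 * max(d) else 0
      sign <- classify_influence(lvl, shift)
      if (!is.na(sign))
        edges[[length(edges) + 1L]] <- data.frame(
          tf = tf, stripe = s$index, sign = sign,
          level_change_pct = lvl, boundary_shift_pct = shift)
    }
  }
  if (!length(edges))
    return(data.frame(tf = character(), stripe = integer(),
                      sign = character(), level_change_pct = numeric(),
                      boundary_shift_pct = numeric()))
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

# ---- enhancer cross-talk --------------------------------------------

# sites of the annotation falling fully inside a window
sites_in_window <- function(annotation, start, length) {
  s <- annotation$sites
  keep <- s$start >= start & (s$start + s$length) <= start + length
  s[keep, , drop = FALSE]
}

# build a site_annotation from a plain site data frame
annotation_from_sites <- function(sites, llr_max, id = "virtual") {
  sites <- sites[order(sites$start, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sequence_id = id, sites = sites, llr_max = llr_max),
            class = "site_annotation")
}

#' Enhancer cross-talk hypergraph
#'
#' For every ordered pair of model windows (enhancers) and every block
#' of 1-5 contiguous donor sites, a new model is optimised in which the
#' acceptor enhancer's site set is augmented by the donor block
#' (repositioned just downstream of the acceptor's sites, so the block
#' is interpreted together with them); the hyperedge weight is the new
#' model's w-PGP score minus the original model's.  Negative weights
#' indicate an avoided interaction.  Within-enhancer hyperedges carry
#' weight zero by construction and are not enumerated.
#'
#' @param model A `locus_model` with at least two windows.
#' @param ctx A [tf_context()] (defaults to the model's own).
#' @param gene_profile Target profile (defaults to the model's own).
#' @param max_block Largest donor block (default 5 contiguous sites).
#' @param refit_theta Re-fit the thermodynamic parameters (two-fold box
#'   around the model's) for each hyperedge, in addition to the weight
#'   re-fit.
#' @return Data frame of hyperedges: `donor`, `acceptor`, `block_start`,
#'   `block_size`, `weight`, plus attribute `original_score`.
#' @export
crosstalk_hypergraph <- function(model, ctx = model$ctx,
                                 gene_profile = model$gene_profile,
                                 max_block = 5L, refit_theta = TRUE) {
  nw <- nrow(model$windows)
  if (nw < 2L) {
    warning("cross-talk analysis needs at least two windows")
    return(data.frame(donor = integer(), acceptor = integer(),
                      block_start = integer(), block_size = integer(),
                      weight = numeric()))
  }
  win_sites <- lapply(seq_len(nw), function(k)
    sites_in_window(model$annotation, model$windows$start[k],
                    model$windows$length[k]))
  orig <- model$score
  concT <- t(ctx$conc)
  edges <- list()
  for (d in seq_len(nw)) for (a in seq_len(nw)) {
    if (d == a) next
    ds <- win_sites[[d]]; as_ <- win_sites[[a]]
    if (!nrow(ds)) next
    for (size in seq_len(min(max_block, nrow(ds)))) {
      for (b0 in seq_len(nrow(ds) - size + 1L)) {
        block <- ds[b0:(b0 + size - 1L), , drop = FALSE]
        # reposition the donor block 100 bp downstream of the acceptor,
        # preserving its internal spacing
        off <- (max(as_$start + as_$length, model$windows$start[a]) +
                  100L) - min(block$start)
        block$start <- block$start + off
        aug <- annotation_from_sites(rbind(as_, block),
                                     model$annotation$llr_max)
        sc <- crosstalk_score(model, aug, a, gene_profile, concT, ctx,
                              refit_theta)
        edges[[length(edges) + 1L]] <- data.frame(
          donor = d, acceptor = a, block_start = b0, block_size = size,
          weight = sc - orig)
      }
    }
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  attr(out, "original_score") <- orig
  out
}

# best score of the model with window `a` replaced by the augmented
# site set: weights (and optionally theta, two-fold box) re-optimised
crosstalk_score <- function(model, aug, a, gene_profile, concT, ctx,
                            refit) {
  saug <- sites_for(aug, ctx$tf_names)
  Laug <- max(saug$end) + 1L
  others <- setdiff(seq_len(nrow(model$windows)), a)
  s <- sites_for(model$annotation, ctx$tf_names)
  ws <- as.integer(model$windows$start[others])
  we <- as.integer(ws + model$windows$length[others])
  readout_all <- function(theta) {
    pl <- theta_cpp(theta, ctx$tf_names)
    Ea <- cpp_window_readouts(saug$start, saug$end, saug$tf, saug$aff,
                              concT, pl, 0L, Laug)
    Eo <- if (length(others))
      cpp_window_readouts(s$start, s$end, s$tf, s$aff, concT, pl, ws, we)
    else NULL
    rbind(Ea, Eo)
  }
  w0 <- model$windows$weight[c(a, others)]
  E <- readout_all(model$theta)
  best <- optimize_weights(E, gene_profile$values, init_weights = w0)
  if (refit) {
    b <- theta_bounds(model$theta, constrained = TRUE)
    obj <- function(par) {
      Ep <- readout_all(par_to_theta(par, model$theta))
      wpgp_score(pmin(as.numeric(best$weights %*% Ep), 1),
                 gene_profile$values)
    }
    r <- optimize_box(obj, b$init, b$lower, b$upper, nm_iter = 60L,
                      rounds = 1L)
    if (r$value > best$score) {
      E2 <- readout_all(par_to_theta(r$par, model$theta))
      best2 <- optimize_weights(E2, gene_profile$values,
                                init_weights = best$weights)
      if (best2$score > best$score) best <- best2
      best$score <- max(best$score, r$value)
    }
  }
  best$score
}

#' Map the cross-talk hypergraph to a site-by-enhancer matrix
#'
#' Rows are binding sites in locus order, columns are enhancers in
#' locus order; the entry for site i and enhancer j averages the weight
#' of every hyperedge in which site i belongs to the donor block and j
#' is the acceptor.  A site's own-enhancer column is 0 (within-enhancer
#' hyperedges).
#'
#' @param hyperedges Output of [crosstalk_hypergraph()].
#' @param model The `locus_model` the hyperedges were computed on.
#' @return Numeric matrix (sites x enhancers) with NA where no
#'   hyperedge was observed.
#' @export
hypergraph_to_graph <- function(hyperedges, model) {
  if (!nrow(hyperedges)) stop("empty hyperedge list")
  nw <- nrow(model$windows)
  win_sites <- lapply(seq_len(nw), function(k)
    sites_in_window(model$annotation, model$windows$start[k],
                    model$windows$length[k]))
  n_per <- vapply(win_sites, nrow, 0L)
  site_enh <- rep(seq_len(nw), n_per)
  n_sites <- sum(n_per)
  offset <- c(0L, cumsum(n_per))
  S <- matrix(0, n_sites, nw)
  Nh <- matrix(0L, n_sites, nw)
  for (i in seq_len(nrow(hyperedges))) {
    h <- hyperedges[i, ]
    rows <- offset[h$donor] + h$block_start:(h$block_start + h$block_size - 1L)
    S[rows, h$acceptor] <- S[rows, h$acceptor] + h$weight
    Nh[rows, h$acceptor] <- Nh[rows, h$acceptor] + 1L
  }
  M <- ifelse(Nh > 0, S / pmax(Nh, 1L), NA_real_)
  # within-enhancer interactions are neutral by construction
  for (j in seq_len(nw)) M[site_enh == j, j] <- 0
  rownames(M) <- sprintf("site_%d", seq_len(n_sites))
  colnames(M) <- sprintf("enhancer_%d", seq_len(nw))
  M
}

#' Combined readout of two independent enhancers
#'
#' If each enhancer alone drives the gene with probability `p` and the
#' two interact with the promoter independently (never simultaneously),
#' the combined expression probability is `2p / (1 + p)`.  For small
#' `p` this approaches the additive `2p`; for large `p` it approaches
#' `1 - (1 - p)^2`.
#'
#' @param p Per-enhancer expression probability in `[0, 1]`.
#' @return `2 * p / (1 + p)`.
#' @export
two_enhancer_combined_readout <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  2 * p / (1 + p)
}
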
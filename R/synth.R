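# Synthetic-data generation: forward-model loci with planted enhancers,
# gradient/bump TF contexts, random motifs, and the four negative
# control generators.

#' Specification of a synthetic locus
#'
#' The defaults define the standard validation condition used by the
#' package's recovery tests: an 8 kb locus with three planted 800 bp
#' enhancers, read out on a 100-bin axis by four TFs (three bump-shaped
#' activators, one bump-shaped repressor positioned between the first
#' two stripes).
#'
#' @param n_tfs Number of TFs (the last one is the repressor when
#'   `roles` is not given).
#' @param motif_length Motif length (bp).
#' @param locus_length Locus length (bp).
#' @param axis_bins Number of axis bins.
#' @param planted_enhancers Data frame with columns `start`, `length`
#'   and `tf` (index of the enhancer's driving activator); an optional
#'   `rep_sites` column overrides `repressor_sites` per enhancer.
#' @param sites_per_enhancer Consensus activator sites planted per
#'   enhancer.
#' @param repressor_sites Consensus repressor sites planted per
#'   enhancer.
#' @param true_theta Ground-truth [thermo_params()]; a default DIRECT
#'   mode parameter set is built when `NULL`.
#' @param true_weights Ground-truth window weights, one per enhancer.
#' @param base_freqs Background base frequencies (A, C, G, T).
#' @param shapes Optional per-TF concentration shape override: list of
#'   `list(type = "bump", center, width, peak)` or `list(type =
#'   "gradient", center, slope, peak)`.
#' @param seed Mandatory integer seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_tfs = 4L, motif_length = 8L,
                       locus_length = 8000L, axis_bins = 100L,
                       planted_enhancers = NULL,
                       sites_per_enhancer = 5L, repressor_sites = 2L,
                       true_theta = NULL, true_weights = NULL,
                       base_freqs = rep(0.25, 4), shapes = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_tfs >= 1, motif_length >= 4, locus_length >= 1,
            axis_bins >= 2)
  tf_names <- c(sprintf("ACT%d", seq_len(max(n_tfs - 1L, 1L))),
                if (n_tfs > 1L) "REP1")
  roles <- c(rep("activator", max(n_tfs - 1L, 1L)),
             if (n_tfs > 1L) "repressor")
  n_act <- sum(roles == "activator")
  if (is.null(planted_enhancers)) {
    planted_enhancers <- data.frame(
      start = c(1200L, 3600L, 6000L), length = 800L,
      tf = pmin(1:3, n_act))
  }
  ne <- nrow(planted_enhancers)
  if (ne) {
    with(planted_enhancers, stopifnot(all(start >= 0),
      all(start + length <= locus_length), all(tf <= n_act)))
  }
  # activator bumps at the intended stripe centres; repressor bump sits
  # between the first two stripes to sharpen their facing borders
  centers <- if (n_act == 1L) 0.5 else
    seq(0.25, 0.75, length.out = n_act)
  if (is.null(shapes)) {
    shapes <- lapply(seq_len(n_tfs), function(i) {
      if (roles[i] == "activator")
        list(type = "bump", center = centers[i], width = 0.05, peak = 1)
      else
        list(type = "bump", center = mean(centers[1:min(2, n_act)]),
             width = 0.05, peak = 1)
    })
  } else stopifnot(length(shapes) == n_tfs)
  if (is.null(true_theta))
    true_theta <- thermo_params(tf_names, roles, K = 2,
                                alpha = ifelse(roles == "activator",
                                               5, 0.2),
                                omega = 1, q_btm = 0.02, mode = "DIRECT")
  if (is.null(true_weights)) true_weights <- rep(1, ne)
  stopifnot(length(true_weights) == ne)
  structure(list(n_tfs = as.integer(n_tfs), tf_names = tf_names,
                 roles = roles, shapes = shapes,
                 motif_length = as.integer(motif_length),
                 locus_length = as.integer(locus_length),
                 axis_bins = as.integer(axis_bins),
                 planted_enhancers = planted_enhancers,
                 sites_per_enhancer = as.integer(sites_per_enhancer),
                 repressor_sites = as.integer(repressor_sites),
                 true_theta = true_theta, true_weights = true_weights,
                 base_freqs = base_freqs, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate random sharp motifs for a synthetic spec
#'
#' Each motif has a random consensus sequence with probability 0.85 on
#' the consensus base and 0.05 elsewhere.
#'
#' @param spec A [synth_spec()].
#' @return List of [pwm()]s, one per TF, with attribute `consensus`.
#' @export
gen_pwms <- function(spec) {
  set.seed(spec$seed)
  lapply(seq_len(spec$n_tfs), function(i) {
    cons <- sample(BASES, spec$motif_length, replace = TRUE)
    counts <- matrix(5, spec$motif_length, 4)
    counts[cbind(seq_len(spec$motif_length), match(cons, BASES))] <- 85
    p <- pwm(counts, tf_name = spec$tf_names[i], pseudocount = 0)
    attr(p, "consensus") <- paste(cons, collapse = "")
    p
  })
}

#' Generate the trans-regulatory context of a synthetic spec
#'
#' Activators get Gaussian-bump concentration profiles centred on the
#' intended stripe positions (or logistic gradients if so specified);
#' the repressor's bump sits between the first two stripes.
#'
#' @param spec A [synth_spec()].
#' @return A [tf_context()] on a uniform axis grid.
#' @export
gen_tf_context <- function(spec) {
  x <- seq(0, 1, length.out = spec$axis_bins)
  conc <- sapply(spec$shapes, function(s) {
    if (s$type == "bump")
      s$peak * exp(-(x - s$center)^2 / (2 * s$width^2))
    else
      s$peak / (1 + exp(-s$slope * (x - s$center)))
  })
  colnames(conc) <- spec$tf_names
  tf_context(conc, spec$roles, axis = x)
}

#' Random i.i.d. DNA sequence
#'
#' @param length Sequence length (bp, >= 1).
#' @param base_freqs Sampling probabilities for A, C, G, T (sum to 1).
#' @param seed Integer seed.
#' @return A [dna_sequence()].
#' @export
gen_random_sequence <- function(length, base_freqs = rep(0.25, 4), seed) {
  if (length < 1L) stop("sequence length must be >= 1")
  if (length(base_freqs) != 4L || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-9)
    stop("base_freqs must be 4 non-negative values summing to 1")
  set.seed(seed)
  dna_sequence(sprintf("random_%d", seed),
               paste(sample(BASES, length, replace = TRUE,
                            prob = base_freqs), collapse = ""))
}

#' Generate a synthetic locus with planted enhancers
#'
#' Background sequence is drawn i.i.d.; consensus sites of each planted
#' enhancer's driving activator (plus repressor sites) are implanted at
#' evenly spaced positions within the enhancer.  The ground-truth
#' expression is the forward-model prediction: the true-weighted sum of
#' the planted windows' thermodynamic readouts, clipped to `[0, 1]`.
#'
#' @param spec A [synth_spec()].
#' @return List with `locus` ([dna_sequence()]), `pwms`, `ctx`
#'   ([tf_context()]), `annotation` (sites of the final sequence),
#'   `expression` (ground-truth [axis_profile()]) and `truth` (planted
#'   windows with weights, the true parameters, per-window readouts).
#' @export
gen_synthetic_locus <- function(spec) {
  pwms <- gen_pwms(spec)  # seeds the RNG with spec$seed
  bases <- sample(BASES, spec$locus_length, replace = TRUE,
                  prob = spec$base_freqs)
  pe <- spec$planted_enhancers
  rep_idx <- which(spec$roles == "repressor")[1]
  for (k in seq_len(NROW(pe))) {
    n_rep <- if (is.na(rep_idx)) 0L else
      if (!is.null(pe$rep_sites)) pe$rep_sites[k] else spec$repressor_sites
    n_site <- spec$sites_per_enhancer + n_rep
    tfs <- rep(pe$tf[k], n_site)
    if (n_rep > 0L) {
      # spread the repressor sites among the activator sites
      rpos <- unique(round(seq(2, n_site, length.out = n_rep)))
      tfs[rpos] <- rep_idx
    }
    slots <- pe$start[k] +
      round((seq_len(n_site) - 0.5) / n_site * pe$length[k])
    for (j in seq_len(n_site)) {
      cons <- strsplit(attr(pwms[[tfs[j]]], "consensus"), "")[[1]]
      if (slots[j] + length(cons) > spec$locus_length)
        stop("planted sites exceed the enhancer length")
      bases[(slots[j] + 1L):(slots[j] + length(cons))] <- cons
    }
  }
  locus <- dna_sequence(sprintf("synthetic_locus_seed%d", spec$seed),
                        paste(bases, collapse = ""))
  ctx <- gen_tf_context(spec)
  annotation <- scan_sites(locus, pwms)
  if (NROW(pe)) {
    windows <- data.frame(start = pe$start, length = pe$length,
                          weight = spec$true_weights)
    E <- window_readouts(annotation, windows, spec$true_theta, ctx)
    expr <- pmin(as.numeric(spec$true_weights %*% E), 1)
  } else {
    windows <- data.frame(start = integer(), length = integer(),
                          weight = numeric())
    E <- NULL
    z <- spec$true_theta$q_btm
    expr <- rep(z / (1 + z), spec$axis_bins)
  }
  list(locus = locus, pwms = pwms, ctx = ctx, annotation = annotation,
       expression = axis_profile(expr, ctx$axis),
       truth = list(windows = windows, theta = spec$true_theta,
                    readouts = E))
}

#' Generate a random expression pattern matched to a real one
#'
#' Emulates the random-expression negative control: given the real
#' profile's stripe count N (at the ON threshold) and ON-bin count K, a
#' stripe count is drawn uniformly between ceiling(N/2) and N, random
#' positive stripe widths summing to K and gap widths summing to the
#' OFF count are laid out alternately from the anterior end (leading
#' and trailing gaps may be empty), and the resulting binary pattern is
#' smoothed with logistic edges.
#'
#' @param real_profile The gene's [axis_profile()].
#' @param on_threshold ON/OFF threshold.
#' @param seed Integer seed.
#' @param slope Logistic edge steepness per axis fraction.
#' @return An [axis_profile()]; attribute `binary` holds the
#'   pre-smoothing ON/OFF pattern and `n_stripes` the drawn count.
#' @export
gen_random_expression <- function(real_profile, on_threshold = 0.5, seed,
                                  slope = 100) {
  stopifnot(inherits(real_profile, "axis_profile"))
  v <- real_profile$values
  on <- v >= on_threshold
  K <- sum(on)
  if (K == 0L) stop("real profile has no ON bins at the threshold")
  r <- rle(on)
  N <- sum(r$values)
  nb <- length(v)
  K0 <- nb - K
  set.seed(seed)
  lo <- ceiling(N / 2)
  s <- if (lo >= N) N else sample(lo:N, 1L)
  # stripe widths: uniform composition of K into s positive parts
  sw <- if (s == 1L) K else
    diff(c(0L, sort(sample(K - 1L, s - 1L)), K))
  # gap widths: s+1 parts, interior >= 1, leading/trailing may be 0
  m <- s + 1L
  interior_min <- max(s - 1L, 0L)
  if (K0 < interior_min) stop("too many stripes for the available OFF bins")
  n0 <- K0 - interior_min
  gw <- if (m == 1L) n0 else
    diff(c(0L, sort(sample.int(n0 + m - 1L, m - 1L)), n0 + m)) - 1L
  gw <- gw + c(0L, rep(1L, interior_min), 0L)[seq_len(m)]
  bin <- logical(0)
  for (i in seq_len(s)) bin <- c(bin, rep(FALSE, gw[i]), rep(TRUE, sw[i]))
  bin <- c(bin, rep(FALSE, gw[m]))
  stopifnot(length(bin) == nb, sum(bin) == K)
  # logistic smoothing of each stripe's edges
  x <- real_profile$axis
  half <- if (nb > 1) mean(diff(x)) / 2 else 0.5
  rb <- rle(bin)
  e2 <- cumsum(rb$lengths); s2 <- e2 - rb$lengths + 1L
  sm <- numeric(nb)
  for (k in which(rb$values)) {
    a <- x[s2[k]] - half
    b <- x[e2[k]] + half
    sm <- sm + 1 / (1 + exp(-slope * (x - a))) /
      (1 + exp(slope * (x - b)))
  }
  out <- axis_profile(pmin(sm, 1), x)
  attr(out, "binary") <- bin
  attr(out, "n_stripes") <- s
  out
}

#' Run a negative-control model fit
#'
#' Repeats the locus-level training on control inputs: another gene's
#' locus (`swap_locus`), a random expression pattern
#' (`random_expression`), a random sequence of the same length
#' (`random_sequence`), or the real locus with its binding sites
#' relocated at random (`shuffled_sites`).  Controls are fitted with an
#' unconstrained parameter strategy.
#'
#' @param locus The gene's [dna_sequence()].
#' @param gene_profile The gene's [axis_profile()].
#' @param ctx A [tf_context()].
#' @param pwms List of [pwm()]s.
#' @param init_theta Initial [thermo_params()].
#' @param cfg A [train_config()].
#' @param mode Control type (see above).
#' @param seed Integer seed; replicate r uses `seed + r - 1`.
#' @param n_reps Number of control replicates.
#' @param alt_locus Required for `swap_locus`: another gene's locus.
#' @return Data frame (`replicate`, `score`) with the fitted models in
#'   attribute `models`.
#' @export
run_negative_controls <- function(locus, gene_profile, ctx, pwms,
                                  init_theta, cfg = train_config(),
                                  mode = c("swap_locus",
                                           "random_expression",
                                           "random_sequence",
                                           "shuffled_sites"),
                                  seed = 1L, n_reps = 1L,
                                  alt_locus = NULL) {
  mode <- match.arg(mode)
  L <- nchar(locus$residues)
  # base composition of the real locus drives the random sequences
  comp <- table(factor(strsplit(locus$residues, "")[[1]], levels = BASES))
  comp <- as.numeric(comp) / sum(comp)
  models <- vector("list", n_reps)
  scores <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sd <- seed + r - 1L
    m <- switch(mode,
      swap_locus = {
        if (is.null(alt_locus)) stop("swap_locus needs alt_locus")
        fit_locus(alt_locus, gene_profile, ctx, init_theta, cfg,
                  pwms = pwms, constrain_theta = FALSE)
      },
      random_expression = {
        target <- gen_random_expression(gene_profile, cfg$on_threshold,
                                        seed = sd)
        fit_locus(locus, target, ctx, init_theta, cfg, pwms = pwms,
                  constrain_theta = FALSE)
      },
      random_sequence = {
        rnd <- gen_random_sequence(L, comp, seed = sd)
        fit_locus(rnd, gene_profile, ctx, init_theta, cfg, pwms = pwms,
                  constrain_theta = FALSE)
      },
      shuffled_sites = {
        ann <- scan_sites(locus, pwms)
        shuf <- shuffle_site_positions(ann, L, rng_seed = sd)
        fit_locus(NULL, gene_profile, ctx, init_theta, cfg,
                  sites = shuf, locus_length = L,
                  constrain_theta = FALSE)
      })
    models[[r]] <- m
    scores[r] <- m$score
  }
  out <- data.frame(replicate = seq_len(n_reps), score = scores)
  attr(out, "models") <- models
  out
}
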
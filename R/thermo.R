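# The statistical-thermodynamics core: ensemble partition sums over
# binding configurations and expression prediction per axis bin.
#
# Model: each configuration sigma is a non-overlapping subset of
# annotated sites.  Its Boltzmann weight W(sigma) is the product of site
# statistical weights q = K * concentration * rel_affinity, times a
# self-cooperativity factor omega for every consecutively bound same-TF
# pair within coop_dist.  Its transcriptional effect Q(sigma) multiplies
# one interaction factor alpha per bound site (DIRECT mode); in SRR mode
# only activators contribute alpha, and an activator bound next to a
# repressor within srr_range is quenched by a factor (1 - beta) per such
# neighbouring repressor.  Expression is the basal-machinery occupancy
#   E = Z_on / (Z_off + Z_on),   Z_on = q_btm * sum W(sigma) Q(sigma),
#   Z_off = sum W(sigma),
# with the empty configuration contributing W = Q = 1.

#' Construct the thermodynamic parameter set
#'
#' One (K, alpha, omega) triple per TF plus the global basal-machinery
#' weight `q_btm`; SRR mode additionally carries a quenching efficiency
#' `srr_beta` per repressor.
#'
#' @param tf_names Character vector of TF names.
#' @param roles `"activator"` or `"repressor"` per TF.  In DIRECT mode
#'   role consistency is enforced: activators need `alpha >= 1`,
#'   repressors `alpha <= 1`.
#' @param K Binding scale per TF (> 0); multiplies concentration and
#'   relative affinity to give a site's statistical weight.
#' @param alpha Interaction strength with the basal machinery per TF
#'   (> 0).
#' @param omega Self-cooperativity factor per TF (>= 1).
#' @param srr_beta Quenching efficiency per TF in `[0, 1]` (used for
#'   repressors in SRR mode only).
#' @param q_btm Global weight of the bound basal machinery (> 0).
#' @param mode `"DIRECT"` or `"SRR"`.
#' @param coop_dist Maximum bp gap for self-cooperativity.
#' @param srr_range Maximum bp gap for short-range quenching.
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(tf_names, roles, K = 1, alpha = 1, omega = 1,
                          srr_beta = 0, q_btm = 0.1,
                          mode = c("DIRECT", "SRR"),
                          coop_dist = 50L, srr_range = 150L) {
  mode <- match.arg(mode)
  n <- length(tf_names)
  if (n < 1L) stop("at least one TF required")
  roles <- match.arg(roles, c("activator", "repressor"), several.ok = TRUE)
  if (length(roles) == 1L) roles <- rep(roles, n)
  stopifnot(length(roles) == n)
  expand <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stop(what, " must have one value per TF")
    if (!all(is.finite(x))) stop(what, " must be finite")
    setNames(as.numeric(x), tf_names)
  }
  K <- expand(K, "K"); alpha <- expand(alpha, "alpha")
  omega <- expand(omega, "omega"); srr_beta <- expand(srr_beta, "srr_beta")
  if (any(K <= 0)) stop("K must be positive")
  if (any(alpha <= 0)) stop("alpha must be positive")
  if (any(omega < 1)) stop("omega must be >= 1")
  if (any(srr_beta < 0 | srr_beta > 1)) stop("srr_beta must be in [0, 1]")
  if (!is.finite(q_btm) || q_btm <= 0) stop("q_btm must be positive")
  if (mode == "DIRECT") {
    act <- roles == "activator"
    if (any(alpha[act] < 1))
      stop("DIRECT mode: activators require alpha >= 1")
    if (any(alpha[!act] > 1))
      stop("DIRECT mode: repressors require alpha <= 1")
  }
  structure(list(tf_names = tf_names, roles = setNames(roles, tf_names),
                 K = K, alpha = alpha, omega = omega, srr_beta = srr_beta,
                 q_btm = q_btm, mode = mode,
                 coop_dist = as.integer(coop_dist),
                 srr_range = as.integer(srr_range)),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params> %s mode, %d TFs, q_btm = %.4g\n",
              x$mode, length(x$tf_names), x$q_btm))
  df <- data.frame(role = substr(x$roles, 1, 3), K = round(x$K, 4),
                   alpha = round(x$alpha, 4), omega = round(x$omega, 4))
  if (x$mode == "SRR") df$srr_beta <- round(x$srr_beta, 4)
  print(df)
  invisible(x)
}

#' Count the free parameters of a thermodynamic model
#'
#' DIRECT mode has three free parameters per TF (K, alpha, omega) plus
#' the global `q_btm`; SRR mode adds one quenching efficiency per
#' repressor, reported separately in the `"srr_extra"` attribute.
#'
#' @param theta A [thermo_params()] object.
#' @param n_tfs Number of TFs (defaults to the number in `theta`).
#' @return Integer count `3 * n_tfs + 1`, with attribute `srr_extra`
#'   (number of per-repressor quenching parameters) in SRR mode.
#' @export
count_free_parameters <- function(theta, n_tfs = length(theta$tf_names)) {
  stopifnot(inherits(theta, "thermo_params"))
  if (n_tfs < 1L) stop("no TFs")
  count <- 3L * as.integer(n_tfs) + 1L
  if (theta$mode == "SRR")
    attr(count, "srr_extra") <- sum(theta$roles == "repressor")
  count
}

#' Statistical weight of one bound site
#'
#' @param rel_affinity Site relative affinity in `(0, 1]`.
#' @param K Binding scale of the site's TF.
#' @param concentration Relative TF concentration (>= 0).
#' @return `K * concentration * rel_affinity`.
#' @export
site_statweight <- function(rel_affinity, K, concentration) {
  if (any(concentration < 0)) stop("negative concentration")
  K * concentration * rel_affinity
}

# pack theta into the list the C++ kernel consumes; tf order = ctx order
theta_cpp <- function(theta, tf_names) {
  m <- match(tf_names, theta$tf_names)
  if (anyNA(m)) stop("TF(s) missing from thermo_params: ",
                     paste(tf_names[is.na(m)], collapse = ", "))
  list(K = unname(theta$K[m]), alpha = unname(theta$alpha[m]),
       omega = unname(theta$omega[m]), beta = unname(theta$srr_beta[m]),
       activ = as.integer(theta$roles[m] == "activator"),
       q_btm = theta$q_btm, mode = if (theta$mode == "SRR") 1L else 0L,
       coop_dist = theta$coop_dist, srr_range = theta$srr_range)
}

# align annotation site TF indices to a tf_names ordering
sites_for <- function(annotation, tf_names) {
  s <- annotation$sites
  m <- match(s$tf, tf_names)
  if (anyNA(m))
    stop("annotated TF(s) absent from context: ",
         paste(unique(s$tf[is.na(m)]), collapse = ", "))
  list(start = as.integer(s$start),
       end = as.integer(s$start + s$length),
       tf = as.integer(m - 1L), aff = as.numeric(s$rel_affinity))
}

#' Partition sums over binding configurations
#'
#' Dynamic program over sites in left-to-right order; linear in the site
#' count up to the local interaction neighbourhood.
#'
#' @param annotation A `site_annotation` (sites sorted by start).
#' @param theta A [thermo_params()].
#' @param concentrations Named (or theta-ordered) per-TF concentrations.
#' @return `c(Z_off, Z_on)`.
#' @seealso [brute_force_partition()] for the enumeration oracle.
#' @export
partition_sums <- function(annotation, theta, concentrations) {
  s <- sites_for(annotation, theta$tf_names)
  if (is.unsorted(s$start)) stop("sites must be sorted by start")
  conc <- align_conc(concentrations, theta$tf_names)
  z <- cpp_partition(s$start, s$end, s$tf, s$aff, conc,
                     theta_cpp(theta, theta$tf_names))
  c(Z_off = z[1], Z_on = z[2])
}

align_conc <- function(concentrations, tf_names) {
  if (!is.null(names(concentrations))) {
    m <- match(tf_names, names(concentrations))
    if (anyNA(m)) stop("concentration missing for TF(s): ",
                       paste(tf_names[is.na(m)], collapse = ", "))
    concentrations <- concentrations[m]
  }
  if (length(concentrations) != length(tf_names))
    stop("one concentration per TF required")
  if (any(concentrations < 0)) stop("negative concentration")
  as.numeric(concentrations)
}

#' Partition sums by exhaustive enumeration (oracle)
#'
#' Enumerates every non-overlapping subset of sites explicitly; intended
#' as an independent check of [partition_sums()] on small instances.
#'
#' @inheritParams partition_sums
#' @return `c(Z_off, Z_on)`.
#' @export
brute_force_partition <- function(annotation, theta, concentrations) {
  s <- annotation$sites
  n <- nrow(s)
  if (n > 20L) stop("brute force limited to 20 sites")
  conc <- align_conc(concentrations, theta$tf_names)
  m <- match(s$tf, theta$tf_names)
  q <- theta$K[m] * conc[m] * s$rel_affinity
  act <- theta$roles[m] == "activator"
  st <- s$start; en <- s$start + s$length
  Zoff <- 0; Zon_sum <- 0
  for (mask in 0:(2^n - 1)) {
    bound <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(bound) > 1L) {
      o <- order(st[bound]); bound <- bound[o]
      if (any(en[head(bound, -1)] > st[bound[-1]])) next  # overlap
    }
    W <- prod(q[bound]); Q <- 1
    if (length(bound) > 1L) {
      for (k in 2:length(bound)) {
        i <- bound[k]; j <- bound[k - 1]
        gap <- st[i] - en[j]
        if (m[i] == m[j] && gap <= theta$coop_dist)
          W <- W * theta$omega[m[i]]
        if (theta$mode == "SRR" && gap <= theta$srr_range &&
            act[i] != act[j]) {
          rep_tf <- if (act[i]) m[j] else m[i]
          Q <- Q * (1 - theta$srr_beta[rep_tf])
        }
      }
    }
    for (i in bound)
      Q <- Q * if (theta$mode == "DIRECT") theta$alpha[m[i]] else
        if (act[i]) theta$alpha[m[i]] else 1
    Zoff <- Zoff + unname(W)
    Zon_sum <- Zon_sum + unname(W * Q)
  }
  c(Z_off = Zoff, Z_on = theta$q_btm * Zon_sum)
}

#' Predict the spatial expression readout of a sequence
#'
#' Evaluates the basal-machinery occupancy `E = Z_on / (Z_off + Z_on)`
#' at every axis bin, using the bin's TF concentrations.
#'
#' @param x A `site_annotation`, or a [dna_sequence()] together with
#'   `pwms`.
#' @param theta A [thermo_params()].
#' @param ctx A [tf_context()].
#' @param pwms Required when `x` is a sequence: list of [pwm()]s.
#' @param rel_affinity_threshold Site-calling threshold used when
#'   scanning a sequence.
#' @return An [axis_profile()] on the context's axis, values in (0, 1).
#' @export
predict_expression <- function(x, theta, ctx, pwms = NULL,
                               rel_affinity_threshold = 0.01) {
  if (inherits(x, "dna_sequence")) {
    if (is.null(pwms)) stop("pwms required to scan a raw sequence")
    x <- scan_sites(x, pwms, rel_affinity_threshold)
  }
  stopifnot(inherits(x, "site_annotation"), inherits(ctx, "tf_context"))
  s <- sites_for(x, ctx$tf_names)
  L <- if (nrow(x$sites)) max(s$end) else 1L
  E <- cpp_window_readouts(s$start, s$end, s$tf, s$aff, t(ctx$conc),
                           theta_cpp(theta, ctx$tf_names),
                           0L, as.integer(L))
  axis_profile(as.numeric(E[1, ]), ctx$axis)
}

# ---- parameter vector transforms for optimisation --------------------

# free parameters are optimised in log space; omega has a log >= 0
# constraint and DIRECT-mode alpha a sign constraint by role
theta_to_par <- function(theta) {
  c(log(theta$K), log(theta$alpha), log(theta$omega), log(theta$q_btm))
}

par_to_theta <- function(par, template) {
  n <- length(template$tf_names)
  thermo_params(template$tf_names, template$roles,
                K = exp(par[1:n]), alpha = exp(par[(n + 1):(2 * n)]),
                omega = exp(par[(2 * n + 1):(3 * n)]),
                srr_beta = template$srr_beta,
                q_btm = exp(par[3 * n + 1]), mode = template$mode,
                coop_dist = template$coop_dist,
                srr_range = template$srr_range)
}

# box bounds in log space for the free parameter vector
theta_bounds <- function(init, constrained) {
  n <- length(init$tf_names)
  p0 <- theta_to_par(init)
  if (constrained) {
    lo <- p0 - log(2); hi <- p0 + log(2)
  } else {
    lo <- c(rep(log(1e-3), n), rep(log(1e-3), n), rep(0, n), log(1e-6))
    hi <- c(rep(log(1e3), n), rep(log(1e3), n), rep(log(100), n), log(10))
  }
  act <- init$roles == "activator"
  # omega >= 1 always
  a <- (2 * n + 1):(3 * n)
  lo[a] <- pmax(lo[a], 0)
  if (init$mode == "DIRECT") {
    # role consistency: activator alpha >= 1, repressor alpha <= 1
    al <- (n + 1):(2 * n)
    lo[al][act] <- pmax(lo[al][act], 0)
    hi[al][!act] <- pmin(hi[al][!act], 0)
  }
  hi <- pmax(hi, lo)
  list(lower = lo, upper = hi, init = pmin(pmax(p0, lo), hi))
}

# maximise f(par) within [lower, upper], alternating Nelder-Mead (with
# projection into the box) and L-BFGS-B; returns the best par found
optimize_box <- function(f, init, lower, upper, nm_iter = 200L,
                         rounds = 2L) {
  proj <- function(p) pmin(pmax(p, lower), upper)
  negf <- function(p) -f(proj(p))
  best_p <- proj(init); best_v <- f(best_p)
  for (r in seq_len(rounds)) {
    if (length(init) > 1L) {
      o <- tryCatch(optim(best_p, negf, method = "Nelder-Mead",
                          control = list(maxit = nm_iter)),
                    error = function(e) NULL)
      if (!is.null(o) && -o$value > best_v) {
        best_p <- proj(o$par); best_v <- -o$value
      }
    }
    o <- tryCatch(optim(best_p, negf, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 100L)),
                  error = function(e) NULL)
    if (!is.null(o) && -o$value > best_v) {
      best_p <- proj(o$par); best_v <- -o$value
    }
  }
  list(par = best_p, value = best_v)
}

#' Fit thermodynamic parameters on a set of enhancers
#'
#' Maximises the mean w-PGP score between predicted and observed
#' readouts of the given enhancers.  In constrained mode every parameter
#' is restricted to a two-fold box around its initial value; in
#' unconstrained mode only a wide plausibility range applies.
#'
#' @param enhancers List of `list(annotation = <site_annotation> or
#'   seq = <dna_sequence>, profile = <axis_profile>)` pairs.
#' @param ctx A [tf_context()] on the shared axis grid.
#' @param init Initial [thermo_params()].
#' @param bounds_mode `"constrained"` (two-fold box) or
#'   `"unconstrained"`.
#' @param pwms PWMs, required if enhancers are given as raw sequences.
#' @param n_restarts Random restarts around the initial point.
#' @param seed Integer seed controlling the restarts.
#' @return A fitted [thermo_params()] with attributes `score` (mean
#'   w-PGP attained) and `trace`.
#' @export
fit_enhancer_set <- function(enhancers, ctx, init,
                             bounds_mode = c("constrained",
                                             "unconstrained"),
                             pwms = NULL, n_restarts = 5L, seed = 1L) {
  bounds_mode <- match.arg(bounds_mode)
  if (!length(enhancers)) stop("at least one enhancer required")
  prep <- lapply(enhancers, function(e) {
    ann <- if (!is.null(e$annotation)) e$annotation else {
      if (is.null(pwms)) stop("pwms required for raw sequences")
      scan_sites(e$seq, pwms)
    }
    if (all(e$profile$values == 0)) stop("all-zero target profile")
    list(sites = sites_for(ann, ctx$tf_names), profile = e$profile)
  })
  concT <- t(ctx$conc)
  objective <- function(par) {
    th <- par_to_theta(par, init)
    pl <- theta_cpp(th, ctx$tf_names)
    mean(vapply(prep, function(e) {
      L <- if (length(e$sites$start)) max(e$sites$end) else 1L
      E <- cpp_window_readouts(e$sites$start, e$sites$end, e$sites$tf,
                               e$sites$aff, concT, pl, 0L, as.integer(L))
      wpgp_score(as.numeric(E[1, ]), e$profile$values)
    }, 0))
  }
  b <- theta_bounds(init, bounds_mode == "constrained")
  set.seed(seed)
  starts <- c(list(b$init), lapply(seq_len(max(n_restarts - 1L, 0L)),
    function(i) pmin(pmax(b$init + runif(length(b$init), -0.5, 0.5),
                          b$lower), b$upper)))
  best <- NULL
  trace <- numeric(0)
  for (s in starts) {
    r <- optimize_box(objective, s, b$lower, b$upper)
    trace <- c(trace, r$value)
    if (is.null(best) || r$value > best$value) best <- r
  }
  out <- par_to_theta(best$par, init)
  attr(out, "score") <- best$value
  attr(out, "trace") <- trace
  out
}
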
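# Shared fixtures, built in code and cached across test files.

fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = fixture_cache))
    assign(name, build(), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

# empty site table with the right columns
empty_sites <- function() {
  data.frame(tf = character(), tf_index = integer(), start = integer(),
             length = integer(), strand = character(), llr = numeric(),
             rel_affinity = numeric())
}

# build a site_annotation from raw columns
make_annotation <- function(tf, start, length, rel_affinity,
                            strand = "+", tf_names = unique(tf),
                            id = "fixture") {
  n <- base::length(tf)
  sites <- if (n == 0) empty_sites() else
    data.frame(tf = tf, tf_index = match(tf, tf_names), start = start,
               length = length, strand = strand, llr = 0,
               rel_affinity = rel_affinity)
  sites <- sites[order(sites$start, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sequence_id = id, sites = sites,
                 llr_max = stats::setNames(rep(1, base::length(tf_names)),
                                           tf_names)),
            class = "site_annotation")
}

# random small thermodynamic instance for the DP-vs-enumeration checks
random_instance <- function(n_sites, n_tf = 3, L = 400, coop = TRUE,
                            mode = c("DIRECT", "SRR")) {
  mode <- match.arg(mode)
  tfn <- paste0("TF", seq_len(n_tf))
  ann <- if (n_sites == 0) make_annotation(character(), integer(),
                                           integer(), numeric(),
                                           tf_names = tfn) else {
    make_annotation(sample(tfn, n_sites, replace = TRUE),
                    sort(sample(0:(L - 12), n_sites)),
                    sample(6:10, n_sites, replace = TRUE),
                    runif(n_sites, 0.05, 1), tf_names = tfn)
  }
  roles <- sample(c("activator", "repressor"), n_tf, replace = TRUE)
  if (!any(roles == "activator")) roles[1] <- "activator"
  alpha <- if (mode == "DIRECT")
    ifelse(roles == "activator", runif(n_tf, 1, 8),
           runif(n_tf, 0.05, 1)) else runif(n_tf, 0.1, 8)
  theta <- thermo_params(tfn, roles, K = runif(n_tf, 0.1, 4),
                         alpha = alpha,
                         omega = if (coop) 1 + runif(n_tf, 0, 4) else 1,
                         srr_beta = runif(n_tf),
                         q_btm = runif(1, 0.01, 2), mode = mode,
                         coop_dist = 50L, srr_range = 150L)
  list(ann = ann, theta = theta,
       conc = stats::setNames(runif(n_tf, 0, 2), tfn))
}

# the standard synthetic validation locus (8 kb, 3 enhancers, 4 TFs)
std_locus <- function(seed) {
  get_fixture(paste0("std_locus_", seed), function() {
    gen_synthetic_locus(synth_spec(seed = seed))
  })
}

# thermodynamic parameters fitted on an external synthetic enhancer
# panel (three independent one-enhancer loci sharing the trans context)
panel_init <- function() {
  get_fixture("panel_init", function() {
    panel <- lapply(1:3, function(k) {
      sp <- synth_spec(locus_length = 1000L,
                       planted_enhancers = data.frame(
                         start = 100L, length = 800L, tf = k),
                       seed = 900L + k)
      d <- gen_synthetic_locus(sp)
      list(annotation = d$annotation, profile = d$expression)
    })
    ctx <- gen_tf_context(synth_spec(seed = 901L))
    neutral <- thermo_params(
      c("ACT1", "ACT2", "ACT3", "REP1"),
      c("activator", "activator", "activator", "repressor"),
      K = 1, alpha = c(2, 2, 2, 0.5), omega = 1, q_btm = 0.1)
    fit_enhancer_set(panel, ctx, neutral, "unconstrained",
                     n_restarts = 3, seed = 11)
  })
}

# reduced training settings used for the recovery/control runs
fast_cfg <- function(outer_iters = 5L) {
  train_config(n_candidates = 3L, start_step = 100L, min_len = 500L,
               max_len = 1500L, len_step = 250L,
               outer_iters = outer_iters)
}

# fraction-of-bp overlap helpers
bp_cover <- function(windows, L) {
  v <- logical(L)
  for (i in seq_len(nrow(windows)))
    v[(windows$start[i] + 1):(windows$start[i] + windows$length[i])] <- TRUE
  v
}

bp_jaccard <- function(w1, w2, L) {
  a <- bp_cover(w1, L); b <- bp_cover(w2, L)
  sum(a & b) / sum(a | b)
}

# 2-stripe planted locus with a repressor shaping stripe 1's posterior
# border (knockdown-network scenario)
kd_locus <- function() {
  get_fixture("kd_locus", function() {
    shapes <- list(
      list(type = "bump", center = 0.30, width = 0.05, peak = 1),
      list(type = "bump", center = 0.70, width = 0.05, peak = 1),
      list(type = "bump", center = 0.42, width = 0.05, peak = 1))
    sp <- synth_spec(n_tfs = 3, locus_length = 6000,
                     planted_enhancers = data.frame(
                       start = c(1000L, 3800L), length = 800L, tf = 1:2),
                     shapes = shapes, seed = 21)
    dat <- gen_synthetic_locus(sp)
    dat$model <- locus_model(dat$truth$windows, sp$true_theta,
                             dat$annotation, dat$ctx,
                             gene_profile = dat$expression)
    dat
  })
}
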
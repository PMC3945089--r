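test_that("architecture proposals stay within Hamming distance two", {
  set.seed(77)
  bits <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  for (i in 1:200) {
    nb <- propose_architecture_bits(bits)
    expect_lte(sum(nb != bits), 2)
  }
  expect_error(propose_architecture_bits(TRUE), "two grid windows")
})

test_that("the architecture sampler is reproducible and validated", {
  cfg <- train_config(n_candidates = 1, start_step = 100, min_len = 500,
                      max_len = 700, len_step = 100, outer_iters = 1)
  ann <- make_annotation(character(), integer(), integer(), numeric(),
                         tf_names = "A")
  ctx <- tf_context(matrix(0.5, 10, 1, dimnames = list(NULL, "A")),
                    "activator")
  th <- thermo_params("A", "activator")
  gp <- axis_profile(rep(0.6, 10))
  sc <- function(bits, weights) 1 + sum(bits)
  r1 <- mcmc_sample(ann, 600, gp, th, ctx, cfg, n_samples = 500,
                    rng_seed = 4, score_fn = sc)
  r2 <- mcmc_sample(ann, 600, gp, th, ctx, cfg, n_samples = 500,
                    rng_seed = 4, score_fn = sc)
  expect_identical(r1$samples, r2$samples)
  expect_equal(sum(r1$avg_weight > 0), 3)
  expect_error(mcmc_sample(ann, 600, gp, th, ctx, cfg, n_samples = 0),
               "n_samples")
})

test_that("average sampled weights concentrate on planted enhancers", {
  dat <- std_locus(1)
  th <- dat$truth$theta
  cfg <- train_config(n_candidates = 1, start_step = 400, min_len = 800,
                      max_len = 800, len_step = 50, outer_iters = 1)
  res <- mcmc_sample(dat$annotation, 8000, dat$expression, th, dat$ctx,
                     cfg, n_samples = 4000, rng_seed = 6)
  # grid windows overlapping a planted enhancer by >= 400 bp should
  # hold the top average weights (top decile)
  planted <- bp_cover(dat$truth$windows, 8000)
  ov <- vapply(seq_len(nrow(res$windows)), function(i) {
    w <- res$windows[i, ]
    sum(planted[(w$start + 1):(w$start + w$length)])
  }, 0)
  top <- order(-res$avg_weight)[1:max(1, nrow(res$windows) %/% 10)]
  expect_gte(mean(ov[top] >= 400), 0.5)
})

test_that("knockdown re-evaluation is pure and monotone for activators", {
  dat <- kd_locus()
  m <- dat$model
  base <- predict_gene_expression(m, dat$ctx)
  kd <- knockdown_tf(m, dat$ctx, "ACT1")
  expect_true(all(kd$values <= base$values + 1e-12))
  expect_lt(kd$values[31], 0.5 * base$values[31])  # stripe 1 collapses
  # restore: baseline reproduced bit-exactly
  again <- predict_gene_expression(m, dat$ctx)
  expect_identical(again$values, base$values)
  expect_error(knockdown_tf(m, dat$ctx, "NOPE"), "unknown TF")
})

test_that("knocking down a TF without sites in the model is a no-op", {
  dat <- kd_locus()
  m <- dat$model
  # add a TF that has no annotated sites anywhere
  ctx2 <- tf_context(cbind(dat$ctx$conc,
                           GHOST = rep(0.8, length(dat$ctx$axis))),
                     c(unname(dat$ctx$roles), "activator"),
                     axis = dat$ctx$axis)
  th2 <- thermo_params(c(m$theta$tf_names, "GHOST"),
                       c(unname(m$theta$roles), "activator"),
                       K = c(m$theta$K, 1), alpha = c(m$theta$alpha, 2),
                       omega = c(m$theta$omega, 1),
                       q_btm = m$theta$q_btm)
  m2 <- locus_model(m$windows, th2, m$annotation, ctx2,
                    gene_profile = dat$expression)
  expect_equal(knockdown_tf(m2, ctx2, "GHOST")$values,
               predict_gene_expression(m2, ctx2)$values,
               tolerance = 1e-12)
})

test_that("knockdown influence classification honours the thresholds", {
  expect_equal(classify_influence(-2.5, 0.2), "activation")
  expect_equal(classify_influence(2.5, 0.2), "repression")
  expect_equal(classify_influence(0.5, 1.4), "repression")
  expect_true(is.na(classify_influence(-1.9, 0.5)))
  expect_true(is.na(classify_influence(1.9, 0.5)))
})

test_that("network inference is invariant to TF order", {
  dat <- kd_locus()
  m <- dat$model
  net <- infer_network(m)
  ctx_r <- tf_context(dat$ctx$conc[, rev(dat$ctx$tf_names)],
                      unname(dat$ctx$roles[rev(dat$ctx$tf_names)]),
                      axis = dat$ctx$axis)
  net_r <- infer_network(m, ctx_r)
  key <- function(n) sort(paste(n$tf, n$stripe, n$sign))
  expect_equal(key(net), key(net_r))
})

test_that("knocking down every TF leaves basal occupancy only", {
  dat <- kd_locus()
  m <- dat$model
  ctx0 <- dat$ctx
  ctx0$conc[] <- 0
  p <- predict_gene_expression(m, ctx0)
  z <- m$theta$q_btm
  # two windows each at basal occupancy, weighted and clipped
  expected <- min(sum(m$windows$weight) * z / (1 + z), 1)
  expect_equal(p$values, rep(expected, 100), tolerance = 1e-12)
})

test_that("cross-talk weights are bounded and inert donors neutral", {
  dat <- kd_locus()
  m <- dat$model
  # single-window model yields an empty warning result
  m1 <- locus_model(m$windows[1, ], m$theta, m$annotation, m$ctx,
                    gene_profile = dat$expression)
  expect_warning(h1 <- crosstalk_hypergraph(m1), "two windows")
  expect_equal(nrow(h1), 0)
  h <- get_fixture("kd_hyperedges", function()
    crosstalk_hypergraph(m, max_block = 2L, refit_theta = FALSE))
  expect_true(all(is.finite(h$weight)))
  expect_true(all(h$weight >= -1 & h$weight <= 1))
  expect_true(all(h$donor != h$acceptor))
  expect_true(all(h$block_size >= 1 & h$block_size <= 2))
})

test_that("inert donor sites (zero concentration) leave the fit alone", {
  dat <- kd_locus()
  m <- dat$model
  # rebuild the model with donor window 1 replaced by sites of a TF
  # whose concentration is zero everywhere
  ctx2 <- tf_context(cbind(dat$ctx$conc,
                           DEAD = rep(0, length(dat$ctx$axis))),
                     c(unname(dat$ctx$roles), "repressor"),
                     axis = dat$ctx$axis)
  th2 <- thermo_params(c(m$theta$tf_names, "DEAD"),
                       c(unname(m$theta$roles), "repressor"),
                       K = c(m$theta$K, 2),
                       alpha = c(m$theta$alpha, 0.2),
                       omega = c(m$theta$omega, 1),
                       q_btm = m$theta$q_btm)
  ann2 <- m$annotation
  dead <- data.frame(tf = "DEAD", tf_index = 4L,
                     start = c(1010L, 1030L), length = 8L, strand = "+",
                     llr = 0, rel_affinity = 1)
  ann2$sites <- rbind(ann2$sites, dead)
  ann2$sites <- ann2$sites[order(ann2$sites$start, ann2$sites$strand), ]
  rownames(ann2$sites) <- NULL
  ann2$llr_max <- c(ann2$llr_max, DEAD = 1)
  m2 <- locus_model(m$windows, th2, ann2, ctx2,
                    gene_profile = dat$expression)
  h <- crosstalk_hypergraph(m2, max_block = 1L, refit_theta = FALSE)
  s1 <- thermolocus:::sites_in_window(ann2, m2$windows$start[1],
                                      m2$windows$length[1])
  dead_blocks <- which(s1$tf == "DEAD")
  hd <- h[h$donor == 1 & h$block_start %in% dead_blocks, ]
  expect_gt(nrow(hd), 0)
  expect_true(all(abs(hd$weight) < 1e-3))
})

test_that("the site-by-enhancer matrix averages hyperedge weights", {
  dat <- kd_locus()
  m <- dat$model
  h <- get_fixture("kd_hyperedges", function()
    crosstalk_hypergraph(m, max_block = 2L, refit_theta = FALSE))
  M <- hypergraph_to_graph(h, m)
  n1 <- nrow(thermolocus:::sites_in_window(m$annotation,
                                           m$windows$start[1],
                                           m$windows$length[1]))
  # own-enhancer columns are zero by construction
  expect_true(all(M[1:n1, 1] == 0))
  expect_true(all(M[(n1 + 1):nrow(M), 2] == 0))
  # a single size-1 hyperedge fixes its matrix entry exactly
  h1 <- h[h$donor == 1 & h$block_size == 1 & h$block_start == 1, ]
  M1 <- hypergraph_to_graph(h1, m)
  expect_equal(M1[1, 2], h1$weight)
  expect_error(hypergraph_to_graph(h[0, ], m), "empty")
})

test_that("independent promoter competition follows 2p/(1+p)", {
  expect_equal(two_enhancer_combined_readout(0), 0)
  expect_equal(two_enhancer_combined_readout(1), 1)
  expect_equal(two_enhancer_combined_readout(0.2), 1 / 3)
  expect_error(two_enhancer_combined_readout(1.2), "\\[0, 1\\]")
})
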
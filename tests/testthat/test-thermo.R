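test_that("free-parameter accounting follows the 3-per-TF + 1 rule", {
  th1 <- thermo_params("A", "activator")
  expect_equal(count_free_parameters(th1, 1), 4L)
  expect_error(count_free_parameters(th1, 0), "no TFs")
  th_srr <- thermo_params(c("A", "R"), c("activator", "repressor"),
                          mode = "SRR")
  n <- count_free_parameters(th_srr)
  expect_equal(as.integer(n), 7L)
  expect_equal(attr(n, "srr_extra"), 1L)
})

test_that("parameter validation enforces role consistency", {
  expect_error(thermo_params("R", "repressor", alpha = 2),
               "repressors require")
  expect_error(thermo_params("A", "activator", alpha = 0.5),
               "activators require")
  expect_error(thermo_params("A", "activator", omega = 0.5), "omega")
  expect_error(thermo_params("A", "activator", q_btm = -1), "q_btm")
  # SRR mode has no alpha sign constraint
  expect_silent(thermo_params("R", "repressor", alpha = 2, mode = "SRR"))
})

test_that("site statistical weight is K * concentration * affinity", {
  expect_equal(site_statweight(1, K = 2, concentration = 0.5), 1)
  expect_equal(site_statweight(0.3, K = 2, concentration = 0), 0)
  w <- site_statweight(0.5, 3, c(0.1, 0.2, 0.9))
  expect_true(all(diff(w) > 0))  # strictly increasing in concentration
  expect_error(site_statweight(1, 1, -0.1), "negative")
})

test_that("partition sums match hand enumeration on tiny ensembles", {
  th <- thermo_params("A", "activator", K = 2, alpha = 3, q_btm = 0.4)
  none <- make_annotation(character(), integer(), integer(), numeric(),
                          tf_names = "A")
  expect_equal(unname(partition_sums(none, th, c(A = 1))), c(1, 0.4))
  # one activator site: Z_off = 1 + q, Z_on = q_btm (1 + q alpha)
  one <- make_annotation("A", 5L, 8L, 0.5)
  q <- 2 * 0.5 * 0.5
  expect_equal(unname(partition_sums(one, th, c(A = 0.5))),
               c(1 + q, 0.4 * (1 + q * 3)), tolerance = 1e-12)
  # two overlapping sites: mutual exclusion leaves 3 configurations
  two <- make_annotation(c("A", "A"), c(0L, 4L), c(8L, 8L), c(1, 1))
  z <- brute_force_partition(two, th, c(A = 1))
  expect_equal(unname(z[1]), 1 + 2 + 2, tolerance = 1e-12)
  # two non-overlapping same-TF sites within coop_dist carry omega
  thc <- thermo_params("A", "activator", K = 2, alpha = 3, omega = 5,
                       q_btm = 0.4, coop_dist = 50L)
  coop <- make_annotation(c("A", "A"), c(0L, 20L), c(8L, 8L), c(1, 1))
  zc <- brute_force_partition(coop, thc, c(A = 1))
  expect_equal(unname(zc[1]), 1 + 2 + 2 + 2 * 2 * 5, tolerance = 1e-12)
  expect_equal(unname(partition_sums(coop, thc, c(A = 1))), unname(zc),
               tolerance = 1e-12)
})

test_that("the DP equals exhaustive enumeration on random ensembles", {
  set.seed(202)
  for (i in 1:60) {
    inst <- random_instance(sample(0:12, 1),
                            coop = i %% 2 == 0,
                            mode = if (i %% 3 == 0) "SRR" else "DIRECT")
    a <- partition_sums(inst$ann, inst$theta, inst$conc)
    b <- brute_force_partition(inst$ann, inst$theta, inst$conc)
    expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("SRR with omega = 1 and beta = 0 reduces to DIRECT Z_off", {
  set.seed(33)
  for (i in 1:10) {
    inst <- random_instance(sample(1:10, 1), mode = "SRR")
    th <- inst$theta
    th0 <- thermo_params(th$tf_names, th$roles, K = th$K,
                         alpha = th$alpha, omega = 1, srr_beta = 0,
                         q_btm = th$q_btm, mode = "SRR",
                         coop_dist = th$coop_dist,
                         srr_range = th$srr_range)
    thd <- thermo_params(th$tf_names, rep("activator", 3), K = th$K,
                         alpha = pmax(th$alpha, 1), omega = 1,
                         q_btm = th$q_btm, mode = "DIRECT",
                         coop_dist = th$coop_dist)
    zs <- partition_sums(inst$ann, th0, inst$conc)
    zd <- partition_sums(inst$ann, thd, inst$conc)
    expect_equal(zs[["Z_off"]], zd[["Z_off"]], tolerance = 1e-12)
  }
})

test_that("expression is invariant to concentration/K rescaling", {
  set.seed(44)
  inst <- random_instance(8)
  th <- inst$theta
  c_scale <- 3.7
  th2 <- thermo_params(th$tf_names, th$roles, K = th$K / c_scale,
                       alpha = th$alpha, omega = th$omega,
                       q_btm = th$q_btm, mode = th$mode,
                       coop_dist = th$coop_dist)
  z1 <- partition_sums(inst$ann, th, inst$conc)
  z2 <- partition_sums(inst$ann, th2, inst$conc * c_scale)
  e1 <- z1[2] / sum(z1); e2 <- z2[2] / sum(z2)
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("expression prediction respects basal occupancy and bounds", {
  ctx <- tf_context(matrix(seq(0, 1, length.out = 20), 20, 1,
                           dimnames = list(NULL, "A")), "activator")
  th <- thermo_params("A", "activator", K = 3, alpha = 6, q_btm = 0.1)
  none <- make_annotation(character(), integer(), integer(), numeric(),
                          tf_names = "A")
  flat <- predict_expression(none, th, ctx)
  expect_equal(flat$values, rep(0.1 / 1.1, 20), tolerance = 1e-12)
  one <- make_annotation("A", 10L, 8L, 1)
  e <- predict_expression(one, th, ctx)
  expect_true(all(e$values > 0 & e$values < 1))
  expect_true(all(diff(e$values) >= 0))  # monotone in the gradient
  # TF absent from the context is an error
  bad <- make_annotation("ZZ", 0L, 8L, 1)
  expect_error(predict_expression(bad, th, ctx), "absent from")
})

test_that("enhancer-set fitting recovers a forward-simulated readout", {
  dat <- std_locus(3)
  truth <- synth_spec(seed = 3)$true_theta
  enh <- list(list(
    annotation = local({
      s <- dat$annotation$sites
      keep <- s$start >= 1200 & s$start + s$length <= 2000
      a <- dat$annotation; a$sites <- s[keep, , drop = FALSE]
      rownames(a$sites) <- NULL
      a
    }),
    profile = predict_expression(local({
      s <- dat$annotation$sites
      keep <- s$start >= 1200 & s$start + s$length <= 2000
      a <- dat$annotation; a$sites <- s[keep, , drop = FALSE]
      a
    }), truth, dat$ctx)))
  init <- thermo_params(truth$tf_names, truth$roles, K = 1,
                        alpha = c(2, 2, 2, 0.5), omega = 1, q_btm = 0.1)
  fit <- fit_enhancer_set(enh, dat$ctx, init, "unconstrained",
                          n_restarts = 2, seed = 5)
  expect_gte(attr(fit, "score"), 0.95)
  # constrained fits never leave the two-fold box
  fitc <- fit_enhancer_set(enh, dat$ctx, init, "constrained",
                           n_restarts = 2, seed = 5)
  for (fld in c("K", "alpha", "omega")) {
    expect_true(all(fitc[[fld]] >= init[[fld]] / 2 - 1e-9))
    expect_true(all(fitc[[fld]] <= init[[fld]] * 2 + 1e-9))
  }
  expect_gte(fitc$q_btm, init$q_btm / 2 - 1e-12)
  expect_lte(fitc$q_btm, init$q_btm * 2 + 1e-12)
  # refitting from the optimum does not lose score
  refit <- fit_enhancer_set(enh, dat$ctx, fit, "unconstrained",
                            n_restarts = 1, seed = 5)
  expect_gte(attr(refit, "score"), attr(fit, "score") - 1e-8)
})
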
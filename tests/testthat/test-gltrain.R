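test_that("stripe decomposition finds maximal ON runs", {
  p <- axis_profile(c(0, 0.8, 0, 0.9, 0.7, 0))
  st <- decompose_stripes(p, 0.5)
  expect_length(st, 2)
  expect_equal(st[[1]]$extent, c(2, 2))
  expect_equal(st[[2]]$extent, c(4, 5))
  expect_equal(st[[1]]$profile$values, c(0, 0.8, 0, 0, 0, 0))
  # a flat high profile is one whole-axis stripe
  flat <- decompose_stripes(axis_profile(rep(0.9, 8)), 0.5)
  expect_length(flat, 1)
  expect_equal(flat[[1]]$extent, c(1, 8))
  # a bin exactly at the threshold is ON
  at <- decompose_stripes(axis_profile(c(0, 0.5, 0)), 0.5)
  expect_equal(at[[1]]$extent, c(2, 2))
  expect_error(decompose_stripes(axis_profile(c(0.1, 0.2)), 0.5),
               "no expression domains")
})

test_that("phase 1 enumerates the configured window grid", {
  dat <- std_locus(1)
  stripes <- decompose_stripes(dat$expression)
  th <- synth_spec(seed = 1)$true_theta
  cfg <- train_config()  # standard settings
  ph1 <- phase1_scan(dat$annotation, 8000, stripes, th, dat$ctx, cfg)
  expect_true(all(ph1$windows$start %% 100 == 0))
  expect_true(all(ph1$windows$length >= 500 & ph1$windows$length <= 2500))
  expect_true(all(ph1$windows$length %% 50 == 0))
  expect_true(all(ph1$windows$start + ph1$windows$length <= 8000))
  expect_true(all(lengths(ph1$candidates) <= cfg$n_candidates))
  expect_length(ph1$candidates, length(stripes))
  # top candidate for each stripe overlaps its planted enhancer by
  # at least half the enhancer's length
  for (i in seq_along(stripes)) {
    w <- ph1$windows[ph1$candidates[[i]][1], ]
    e <- dat$truth$windows[i, ]
    ov <- max(0, min(w$start + w$length, e$start + e$length) -
                   max(w$start, e$start))
    expect_gte(ov, 0.5 * e$length)
  }
  expect_error(phase1_scan(dat$annotation, 300, stripes, th, dat$ctx,
                           cfg), "shorter")
})

test_that("accessibility masks exclude windows with low coverage", {
  mask <- data.frame(start = 0L, end = 1000L)
  cfg <- train_config(min_len = 500L, max_len = 500L, start_step = 250L,
                      accessibility_mask = mask)
  w <- thermolocus:::enumerate_windows(2000L, cfg)
  # windows must be >= 50% covered by [0, 1000)
  expect_true(all(pmin(1000, w$start + w$length) - w$start >=
                    0.5 * w$length))
  expect_lt(max(w$start), 1000)
})

test_that("weight optimisation solves constructed instances", {
  x <- seq(0, 1, length.out = 40)
  r1 <- exp(-(x - 0.3)^2 / 0.01)
  r2 <- exp(-(x - 0.7)^2 / 0.01)
  # identity: one window whose readout equals the target
  o1 <- optimize_weights(rbind(r1), r1)
  expect_equal(o1$weights, 1, tolerance = 0.05)
  expect_gte(o1$score, 0.99)
  # mixture: target is the half-sum of two readouts
  target <- 0.5 * (r1 + r2)
  o2 <- optimize_weights(rbind(r1, r2), target, init_weights = c(1, 1))
  expect_gte(o2$score, 0.99)
  expect_true(all(o2$weights >= 0))
  # all-zero readouts degrade gracefully
  expect_warning(oz <- optimize_weights(rbind(rep(0, 40)), r1), "zero")
  expect_equal(oz$score, 0)
})

test_that("greedy inclusion improves monotonically and recovers windows", {
  dat <- kd_locus()
  th <- dat$truth$theta
  cfg <- fast_cfg()
  stripes <- decompose_stripes(dat$expression)
  ph1 <- phase1_scan(dat$annotation, 6000, stripes, th, dat$ctx, cfg)
  ph2 <- phase2_greedy(ph1, dat$expression, stripes, cfg)
  expect_true(all(diff(ph2$trace) > 0))  # each acceptance strictly improves
  expect_true(all(ph2$weights >= 0))
  # both planted enhancers are hit
  sel <- ph1$windows[ph2$window_idx, ]
  for (i in 1:2) {
    e <- dat$truth$windows[i, ]
    cov <- bp_cover(sel, 6000)
    expect_true(any(cov[(e$start + 1):(e$start + e$length)]))
  }
  # sanity lower bound: final score >= best single-window score vs the
  # full profile
  best_single <- max(thermolocus:::wpgp_rows(ph1$readouts,
                                             dat$expression$values))
  expect_gte(ph2$score, best_single - 1e-9)
})

test_that("the outer training loop keeps the best model and its box", {
  dat <- std_locus(2)
  init <- panel_init()
  cfg <- fast_cfg(outer_iters = 3L)
  m <- fit_locus(dat$locus, dat$expression, dat$ctx, init, cfg,
                 pwms = dat$pwms)
  expect_s3_class(m, "locus_model")
  # best-so-far score equals the maximum of the trace
  expect_equal(m$score, max(m$trace), tolerance = 1e-9)
  # constrained re-fit honours the two-fold box around the init
  for (fld in c("K", "alpha", "omega")) {
    expect_true(all(m$theta[[fld]] >= init[[fld]] / 2 - 1e-9))
    expect_true(all(m$theta[[fld]] <= init[[fld]] * 2 + 1e-9))
  }
  expect_true(all(m$windows$weight >= 0))
  expect_gte(m$score, 0.85)
})

test_that("locus prediction is the clipped weighted window sum", {
  dat <- kd_locus()
  m <- dat$model
  # zero windows: flat zero
  m0 <- locus_model(m$windows[0, ], m$theta, m$annotation, m$ctx)
  expect_equal(m0$prediction$values, rep(0, 100))
  # one window with weight 1 equals that window's readout
  w1 <- m$windows[1, ]; w1$weight <- 1
  m1 <- locus_model(w1, m$theta, m$annotation, m$ctx)
  E <- thermolocus:::window_readouts(m$annotation, w1, m$theta, m$ctx)
  expect_equal(m1$prediction$values, as.numeric(E[1, ]), tolerance = 1e-12)
  # linearity below the clip
  wh <- m$windows; wh$weight <- wh$weight * 0.05
  w2 <- m$windows; w2$weight <- w2$weight * 0.10
  ph <- predict_gene_expression(locus_model(wh, m$theta, m$annotation,
                                            m$ctx))
  p2 <- predict_gene_expression(locus_model(w2, m$theta, m$annotation,
                                            m$ctx))
  expect_equal(p2$values, 2 * ph$values, tolerance = 1e-9)
})

test_that("locus_model methods expose the fit consistently", {
  dat <- kd_locus()
  m <- dat$model
  expect_output(print(m), "window")
  expect_output(summary(m), "Thermodynamic")
  cf <- coef(m)
  expect_named(cf, sprintf("window_%d", seq_len(nrow(m$windows))))
  expect_s3_class(attr(cf, "theta"), "thermo_params")
  expect_length(residuals(m), 100)
  expect_equal(fitted(m), m$prediction$values)
  p <- predict(m, knockdown = "ACT1")
  expect_s3_class(p, "axis_profile")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})
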
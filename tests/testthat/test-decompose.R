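test_that("soft thresholding implements the l1 proximal operator", {
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(-3, 1), -2)
  x <- rnorm(20)
  expect_equal(soft_threshold(x, 0), x)
  expect_equal(soft_threshold(list(c(2, -2), c(0.1)), c(1, 1)),
               list(c(1, -1), 0))
  expect_error(soft_threshold(1, -0.1), ">= 0")
})

test_that("objective matches an independent assembly of the MCA cost", {
  set.seed(4)
  x <- rnorm(256)
  cfg <- dual_q_config(q_high = 4, q_low = 1.2, j_high = 6, j_low = 4,
                       lambda_osc = 0.3, lambda_trn = 0.2)
  w1 <- tqwt(x, 4, 3, 6)
  w2 <- tqwt(x * 0.5, 1.2, 3, 4)
  # zero coefficients give the pure fidelity term ||x||^2
  z1 <- w1; z1$subbands <- lapply(z1$subbands, function(v) v * 0)
  z2 <- w2; z2$subbands <- lapply(z2$subbands, function(v) v * 0)
  expect_equal(mca_objective(x, z1, z2, cfg), sum(x^2))
  # independent brute-force evaluation: fidelity via the inverse transform
  # plus norm-weighted l1 penalties summed by hand
  nh <- tqwt_wavelet_norms(256, 4, 3, 6)
  nl <- tqwt_wavelet_norms(256, 1.2, 3, 4)
  fid <- sum((x - tqwt_inverse(w1) - tqwt_inverse(w2))^2)
  pen <- 0.3 * sum(unlist(mapply(function(v, g) g * abs(v), w1$subbands, nh))) +
         0.2 * sum(unlist(mapply(function(v, g) g * abs(v), w2$subbands, nl)))
  expect_equal(mca_objective(x, w1, w2, cfg), fid + pen, tolerance = 1e-12)
  expect_error(mca_objective(x[-1], w1, w2, cfg), "length")
})

test_that("decomposition degenerate cases behave", {
  d <- resonance_decompose(numeric(128), dual_q_config(j_high = 4, j_low = 3,
                                                       n_iter = 5))
  expect_equal(d$x_osc, numeric(128))
  expect_equal(d$x_trn, numeric(128))

  # l1 dominance: thresholds above every coefficient zero both components
  set.seed(5)
  x <- rnorm(512)
  lam <- 1.1 * sqrt(sum(x^2))
  d <- resonance_decompose(x, dual_q_config(j_high = 6, j_low = 4,
                                            lambda_osc = lam, lambda_trn = lam,
                                            n_iter = 40))
  expect_lt(sqrt(mean(d$x_osc^2)), 1e-8 * sqrt(mean(x^2)))
  expect_lt(sqrt(mean(d$x_trn^2)), 1e-8 * sqrt(mean(x^2)))
  expect_equal(d$residual, x, tolerance = 1e-8)
})

test_that("additivity is exact and the objective decreases", {
  set.seed(6)
  x <- premise_mixture(n = 2048)$x
  d <- resonance_decompose(x, dual_q_config(n_iter = 60))
  expect_equal(d$x_osc + d$x_trn + d$residual, x, tolerance = 1e-12)
  expect_lte(d$objective_trace[d$iterations], d$objective_trace[1])
})

test_that("swapping the dictionary configuration swaps the component roles", {
  pm <- premise_mixture(n = 2048)
  rms <- sqrt(mean(pm$x^2))
  c1 <- dual_q_config(q_high = 6.42, q_low = 1.35,
                      lambda_osc = 0.3 * rms, lambda_trn = 0.3 * rms, n_iter = 50)
  c2 <- dual_q_config(q_high = 1.35, q_low = 6.42,
                      lambda_osc = 0.3 * rms, lambda_trn = 0.3 * rms, n_iter = 50)
  d1 <- resonance_decompose(pm$x, c1)
  d2 <- resonance_decompose(pm$x, c2)
  expect_equal(d1$x_osc, d2$x_trn, tolerance = 1e-10)
  expect_equal(d1$x_trn, d2$x_osc, tolerance = 1e-10)
})

test_that("increasing lambda_osc never increases the oscillatory energy", {
  pm <- premise_mixture(n = 2048)
  rms <- sqrt(mean(pm$x^2))
  en <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(f) {
    d <- resonance_decompose(pm$x, dual_q_config(lambda_osc = f * rms,
                                                 lambda_trn = 0.2 * rms,
                                                 n_iter = 60))
    sqrt(sum(d$x_osc^2))
  }, numeric(1))
  expect_true(all(diff(en) <= 1e-8 * en[1]))
})

test_that("regularisation calibration returns the NMSE-optimal grid pair", {
  # records where extraction works cleanly: F-wave plus attenuated beats
  recs <- lapply(1:2, function(k) {
    fp <- fwave_params("B", "II")
    xf <- gen_fwave(fp, 2048)
    v <- gen_ventricular(4.096, fs = 500, seed = k)
    list(x = xf + 0.25 * v$x, fwave_truth = xf, fs = 500)
  })
  cfg <- dual_q_config(n_iter = 40)
  one <- data.frame(lambda_osc = 5, lambda_trn = 5)
  expect_equal(calibrate_regularization(recs, one, cfg)$lambda_osc, 5)

  rms <- sqrt(mean(recs[[1]]$x^2))
  grid <- data.frame(lambda_osc = c(0.2 * rms, 50 * rms),
                     lambda_trn = c(0.1 * rms, 50 * rms))
  cal <- calibrate_regularization(recs, grid, cfg)
  expect_equal(cal$lambda_osc, 0.2 * rms)   # huge-lambda pair scores NMSE ~ 1
  expect_gt(max(cal$table$mean_nmse), 0.99)
  expect_lt(min(cal$table$mean_nmse), 0.9)
  expect_true(cal$table$degenerate[2])      # the huge pair zeroes the component

  # argmin matches exhaustive re-evaluation
  grid2 <- expand.grid(lambda_osc = c(0.15, 0.4) * rms,
                       lambda_trn = c(0.1, 0.3) * rms)
  cal2 <- calibrate_regularization(recs, grid2, cfg)
  manual <- apply(grid2, 1, function(g) {
    mean(vapply(recs, function(rec) {
      ci <- cfg; ci$lambda_osc <- unname(g[1]); ci$lambda_trn <- unname(g[2])
      d <- resonance_decompose(rec$x - mean(rec$x), ci)
      nmse(rec$fwave_truth, d$x_osc)
    }, numeric(1)))
  })
  expect_equal(cal2$lambda_osc, grid2$lambda_osc[which.min(manual)])
  expect_equal(cal2$lambda_trn, grid2$lambda_trn[which.min(manual)])
  expect_error(calibrate_regularization(recs, grid[0, ], cfg), "empty")

  # epsilon-argmin tie-break: near-tied scores resolve to the lightest
  # oscillatory penalty
  cal3 <- calibrate_regularization(recs, grid2, cfg, tie_tol = 10)
  expect_equal(cal3$lambda_osc, min(grid2$lambda_osc))
  expect_equal(cal3$lambda_trn, min(grid2$lambda_trn[grid2$lambda_osc == cal3$lambda_osc]))
})
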
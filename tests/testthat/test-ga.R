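test_that("kurtosis matches its reference values", {
  set.seed(7)
  expect_equal(kurtosis(rnorm(1e5)), 3, tolerance = 0.1)   # Monte-Carlo
  expect_error(kurtosis(rep(2, 50)), "variance")
  # closed form for a unit spike among zeros: ((n-1)^3 + 1) / (n (n-1))
  x <- c(1, numeric(99))
  expect_equal(kurtosis(x), 98.01010101010101, tolerance = 1e-12)
  # cross-check against an independent implementation when available
  if (requireNamespace("e1071", quietly = TRUE)) {
    y <- rnorm(500)
    expect_equal(kurtosis(y), e1071::kurtosis(y, type = 1) + 3, tolerance = 1e-10)
  }
})

test_that("binary encoding maps range ends and midpoints correctly", {
  cfg <- ga_config()
  b <- cfg$bits_per_gene
  expect_equal(ga_decode(rep(0L, 2 * b), cfg), c(q_high = 2, q_low = 1))
  expect_equal(ga_decode(rep(1L, 2 * b), cfg), c(q_high = 12, q_low = 2))
  mid <- c(ga_encode(7.004887585532747, 1.5004887585532747, cfg))
  expect_equal(ga_decode(mid, cfg),
               c(q_high = 7.004887585532747, q_low = 1.5004887585532747),
               tolerance = 1e-12)
  # round trip within one quantisation step
  step_h <- 10 / (2^b - 1); step_l <- 1 / (2^b - 1)
  for (q in list(c(2.3, 1.02), c(11.7, 1.93), c(6.42, 1.35))) {
    dec <- ga_decode(ga_encode(q[1], q[2], cfg), cfg)
    expect_lte(abs(dec[["q_high"]] - q[1]), step_h)
    expect_lte(abs(dec[["q_low"]] - q[2]), step_l)
  }
  expect_error(ga_encode(13, 1.5, cfg), "range")
  # pair-validity repair swaps a decoded inversion
  cfg2 <- ga_config(q_high_range = c(1, 4), q_low_range = c(1, 4))
  ch <- c(ga_encode(1.2, 1.2, cfg2)[1:cfg2$bits_per_gene],
          ga_encode(3.5, 3.5, cfg2)[(cfg2$bits_per_gene + 1):(2 * cfg2$bits_per_gene)])
  dec <- ga_decode(ch, cfg2)
  expect_gt(dec[["q_high"]], dec[["q_low"]])
})

test_that("fitness is deterministic and favours separating pairs", {
  pm <- premise_mixture(n = 2048)
  dcfg <- dual_q_config(n_iter = 15, tol = 0)
  f1 <- ga_fitness(pm$x, 6.42, 1.35, dcfg)
  f2 <- ga_fitness(pm$x, 6.42, 1.35, dcfg)
  expect_identical(f1, f2)
  # a near-degenerate pair separates the pulse train worse
  f_bad <- ga_fitness(pm$x, 2.1, 2.0, dcfg)
  expect_gt(f1, f_bad)
  # swapped arguments are repaired, not an error
  expect_identical(ga_fitness(pm$x, 1.35, 6.42, dcfg), f1)
})

test_that("GA recovers a known injected-fitness optimum", {
  gcfg <- ga_config(max_generations = 60, seed = 99)
  res <- run_ga(list(), gcfg,
                fitness_fn = function(qh, ql) -(qh - 7)^2 - (ql - 1.5)^2)
  step_h <- 10 / (2^gcfg$bits_per_gene - 1)
  step_l <- 1 / (2^gcfg$bits_per_gene - 1)
  expect_lte(abs(res$q_high - 7), 2 * step_h)
  expect_lte(abs(res$q_low - 1.5), 2 * step_l)
  # elitism: best fitness never decreases
  expect_true(all(diff(res$best_fitness_trace) >= 0))
  # decoded optimum lies inside the configured ranges
  expect_gte(res$q_high, gcfg$q_high_range[1])
  expect_lte(res$q_high, gcfg$q_high_range[2])
  expect_gte(res$q_low, gcfg$q_low_range[1])
  expect_lte(res$q_low, gcfg$q_low_range[2])
})

test_that("GA runs are reproducible for a fixed seed and can stop early", {
  gcfg <- ga_config(pop_size = 10, max_generations = 15, seed = 5)
  f <- function(qh, ql) sin(qh) + cos(3 * ql)
  r1 <- run_ga(list(), gcfg, fitness_fn = f)
  r2 <- run_ga(list(), gcfg, fitness_fn = f)
  expect_identical(r1, r2)
  gcfg$early_stop_stagnation <- 3
  r3 <- run_ga(list(), gcfg, fitness_fn = f)
  expect_lte(r3$generations_run, r1$generations_run)
})

test_that("one-generation GA equals the best of the initial population", {
  gcfg <- ga_config(pop_size = 4, max_generations = 1, seed = 17)
  f <- function(qh, ql) qh - ql
  res <- run_ga(list(), gcfg, fitness_fn = f)
  # replay: regenerate the same initial population and evaluate exhaustively
  pop <- withr::with_seed(17,
    matrix(sample(0:1, 4 * 2 * gcfg$bits_per_gene, replace = TRUE), nrow = 4))
  fits <- apply(pop, 1, function(ch) { q <- ga_decode(ch, gcfg); f(q[1], q[2]) })
  expect_equal(res$best_fitness_trace[1], max(fits))
  best <- ga_decode(pop[which.max(fits), ], gcfg)
  expect_equal(res$q_high, best[["q_high"]])
  expect_equal(res$q_low, best[["q_low"]])
})
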
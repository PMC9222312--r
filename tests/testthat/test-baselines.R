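## identical-beat record: no jitter of any kind, no F-wave, no noise
identical_beat_record <- function(duration_s = 10, pvc_prob = 0, seed = 2) {
  v <- gen_ventricular(duration_s, rr_jitter = 0, pvc_prob = pvc_prob,
                       amp_jitter = 0, seed = seed)
  list(x = v$x, fs = 500, annotations = v$annotations)
}

test_that("beat stacking extracts aligned windows and drops edge beats", {
  rec <- identical_beat_record()
  bm <- stack_beats(rec)
  expect_equal(nrow(bm$beats) + bm$n_dropped, nrow(rec$annotations))
  # interior beats are exact copies (boundary beats miss neighbouring tails)
  interior <- bm$beats[2:(nrow(bm$beats) - 1), ]
  expect_true(all(apply(interior, 2,
                        function(col) diff(range(col)) < 1e-6 * max(rec$x))))

  # annotations at the record edges are excluded and counted
  ann <- rbind(rec$annotations, data.frame(sample = c(3, length(rec$x) - 2),
                                           type = "N"))
  ann <- ann[order(ann$sample), ]
  bm2 <- stack_beats(rec, ann)
  expect_equal(bm2$n_dropped, bm$n_dropped + 2)
  expect_error(stack_beats(list(x = rnorm(100), fs = 500,
                                annotations = data.frame(sample = 50, type = "N"))),
               "fewer than 2")
})

## samples where cancellation can act: away from dropped (edge) beats and
## from the record boundaries, where unannotated neighbouring activity bleeds in
cancelled_region <- function(rec, bm) {
  mask <- rep(TRUE, length(rec$x))
  n <- length(rec$x)
  margin <- round(0.8 * rec$fs)
  mask[c(1:margin, (n - margin):n)] <- FALSE
  dropped <- setdiff(rec$annotations$sample, bm$sample)
  w <- ncol(bm$beats)
  for (s in dropped) {
    idx <- max(1, s - bm$pre - w):min(n, s + w)
    mask[idx] <- FALSE
  }
  mask
}

test_that("ABS cancels identical beats almost exactly", {
  rec <- identical_beat_record()
  # window wide enough to hold the full T wave (periodic beats, no overlap)
  est <- abs_extract(rec, window_post_s = 0.6)
  bm <- stack_beats(rec, window_post_s = 0.6)
  ok <- cancelled_region(rec, bm)
  expect_lt(sqrt(mean(est[ok]^2)), 0.01 * max(rec$x))
  # untouched outside beat windows
  outside <- rep(TRUE, length(rec$x))
  for (s in bm$sample) outside[(s - bm$pre):(s - bm$pre + ncol(bm$beats) - 1)] <- FALSE
  expect_identical(est[outside], rec$x[outside])
})

test_that("ABS recovers the F-wave band on a composite record", {
  fp <- fwave_params("A", "II")
  rec <- compose_record(fp, seed = 9)
  est <- abs_extract(rec)
  ps <- welch_psd(est, rec$fs)
  expect_lte(abs(dominant_frequency(ps$freq, ps$power) - 4), 0.5)
})

test_that("a single shared template fails at PVCs (classic ABS failure)", {
  rec <- identical_beat_record(pvc_prob = 0.12, seed = 4)   # 2 PVCs in 12 beats
  stopifnot(sum(rec$annotations$type == "PVC") == 2)
  est <- abs_extract(rec, per_type = FALSE, window_post_s = 0.6)
  bm <- stack_beats(rec, window_post_s = 0.6)
  w <- ncol(bm$beats)
  res_rms <- vapply(seq_along(bm$sample), function(i) {
    idx <- (bm$sample[i] - bm$pre):(bm$sample[i] - bm$pre + w - 1)
    sqrt(mean(est[idx]^2))
  }, numeric(1))
  pvc <- bm$type == "PVC"
  expect_gt(mean(res_rms[pvc]), 3 * mean(res_rms[!pvc]))
  # with per-type templates the PVC residual collapses
  est2 <- abs_extract(rec, per_type = TRUE, window_post_s = 0.6)
  ok <- cancelled_region(rec, bm)
  expect_lt(sqrt(mean(est2[ok]^2)), sqrt(mean(est[ok]^2)) / 3)
})

test_that("PCA cancellation reconstructs within the leading subspace", {
  rec <- identical_beat_record()
  est <- pca_extract(rec, n_components = 1, window_post_s = 0.6)
  bm0 <- stack_beats(rec, window_post_s = 0.6)
  ok <- cancelled_region(rec, bm0)
  expect_lt(sqrt(mean(est[ok]^2)), 0.01 * max(rec$x))

  # orthogonality: beat reconstructions live in the leading subspace
  v <- gen_ventricular(10, seed = 4)
  rec2 <- list(x = v$x, fs = 500, annotations = v$annotations)
  bm <- stack_beats(rec2)
  mu <- colMeans(bm$beats)
  Bc <- sweep(bm$beats, 2, mu)
  sv <- svd(Bc)
  recon <- Bc %*% sv$v[, 1:2] %*% t(sv$v[, 1:2])
  discarded <- sv$v[, -(1:2), drop = FALSE]
  expect_lt(max(abs(recon %*% discarded)), 1e-9 * max(abs(recon)))

  # untouched outside windows
  est2 <- pca_extract(rec2)
  outside <- rep(TRUE, length(rec2$x))
  for (s in bm$sample) outside[(s - bm$pre):(s - bm$pre + ncol(bm$beats) - 1)] <- FALSE
  expect_identical(est2[outside], rec2$x[outside])
  expect_error(pca_extract(rec2, n_components = 50), "at least")
})

test_that("PCA yields a finite NMSE alongside the other extractors", {
  rec <- compose_record(fwave_params("B", "II"), seed = 13)
  est <- pca_extract(rec)
  expect_true(is.finite(nmse(rec$fwave_truth, est)))
})

test_that("threshold R detector finds the simulated R peaks", {
  v <- gen_ventricular(10, seed = 6)
  det <- detect_r_peaks(v$x, 500)
  expect_equal(nrow(det), nrow(v$annotations))
  expect_true(all(abs(det$sample - v$annotations$sample) <= 3))
})
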
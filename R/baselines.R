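#' Stack beats into a matrix of aligned windows
#'
#' Extracts a fixed window around every annotated R peak (default 0.12 s
#' before to 0.48 s after, covering QRST at normal rates).  Beats whose
#' window would cross the record edges are dropped and counted.
#'
#' @param record an [af_record] or list with `x` (signal) and `fs`.
#' @param annotations data frame with columns `sample` and `type`; defaults
#'   to `record$annotations`.
#' @param window_pre_s,window_post_s window extent around the R peak, s.
#' @return object of class `beat_matrix`: list with `beats` (matrix, one row
#'   per usable beat), `sample`, `type`, `pre` (samples before R),
#'   `n_dropped`.
#' @export
stack_beats <- function(record, annotations = record$annotations,
                        window_pre_s = 0.12, window_post_s = 0.48) {
  x <- record$x; fs <- record$fs
  stopifnot(is.numeric(x), !is.null(fs), !is.null(annotations))
  pre <- round(window_pre_s * fs); post <- round(window_post_s * fs)
  w <- pre + post + 1L
  ok <- annotations$sample - pre >= 1 & annotations$sample + post <= length(x)
  n_dropped <- sum(!ok)
  ann <- annotations[ok, , drop = FALSE]
  if (nrow(ann) < 2) stop("fewer than 2 usable beats")
  beats <- t(vapply(ann$sample,
                    function(s) x[(s - pre):(s + post)], numeric(w)))
  structure(list(beats = beats, sample = ann$sample, type = ann$type,
                 pre = pre, n_dropped = n_dropped),
            class = "beat_matrix")
}

## subtract per-beat reconstructions from the signal (in-window only)
subtract_beats <- function(x, bm, recon) {
  est <- x
  w <- ncol(bm$beats)
  for (i in seq_along(bm$sample)) {
    idx <- (bm$sample[i] - bm$pre):(bm$sample[i] - bm$pre + w - 1L)
    est[idx] <- est[idx] - recon[i, ]
  }
  est
}

#' Average beat subtraction (ABS) F-wave extraction
#'
#' Classic template cancellation: beats are averaged into a QRST template
#' (per beat type, or one shared template when `per_type = FALSE`), each beat
#' window is cancelled by its least-squares-scaled template, and the signal
#' passes through unchanged outside beat windows.  With a single shared
#' template, ectopic (PVC) beats are poorly cancelled — the well-known failure
#' mode of ABS.
#'
#' @inheritParams stack_beats
#' @param per_type build one template per beat type (default TRUE); `FALSE`
#'   forces a single shared template.
#' @param ls_scale least-squares amplitude matching of the template to each
#'   beat (default TRUE).
#' @return numeric F-wave estimate, same length as `record$x`.
#' @export
abs_extract <- function(record, annotations = record$annotations,
                        window_pre_s = 0.12, window_post_s = 0.48,
                        per_type = TRUE, ls_scale = TRUE) {
  bm <- stack_beats(record, annotations, window_pre_s, window_post_s)
  groups <- if (per_type) bm$type else rep("all", length(bm$type))
  recon <- matrix(0, nrow(bm$beats), ncol(bm$beats))
  for (g in unique(groups)) {
    rows <- which(groups == g)
    tmpl <- colMeans(bm$beats[rows, , drop = FALSE])
    tt2 <- sum(tmpl^2)
    for (i in rows) {
      sc <- if (ls_scale && tt2 > 0) sum(bm$beats[i, ] * tmpl) / tt2 else 1
      recon[i, ] <- sc * tmpl
    }
  }
  subtract_beats(record$x, bm, recon)
}

#' Beat-stacking PCA F-wave extraction
#'
#' Single-lead PCA cancellation: the centred beat matrix is decomposed by
#' SVD, the QRST subspace is spanned by the leading `n_components` principal
#' directions, and each beat is cancelled by its projection onto
#' mean + subspace.  Outside beat windows the signal passes through
#' unchanged.
#'
#' @inheritParams stack_beats
#' @param n_components number of principal directions (default 2); requires
#'   at least `n_components + 1` usable beats.
#' @return numeric F-wave estimate, same length as `record$x`.
#' @export
pca_extract <- function(record, annotations = record$annotations,
                        window_pre_s = 0.12, window_post_s = 0.48,
                        n_components = 2) {
  bm <- stack_beats(record, annotations, window_pre_s, window_post_s)
  if (nrow(bm$beats) < n_components + 1) {
    stop(sprintf("need at least %d usable beats for %d components",
                 n_components + 1, n_components))
  }
  mu <- colMeans(bm$beats)
  Bc <- sweep(bm$beats, 2, mu)
  sv <- svd(Bc, nu = 0, nv = n_components)
  proj <- Bc %*% sv$v %*% t(sv$v)
  recon <- sweep(proj, 2, mu, `+`)
  subtract_beats(record$x, bm, recon)
}

#' Simple amplitude-threshold R-peak detector
#'
#' Marks local maxima exceeding `frac` of the global maximum, separated by a
#' refractory period.  Intended for externally supplied records without
#' annotations; simulated records carry ground-truth annotations and should
#' use those (benchmarks isolate extractor quality from detector quality).
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param frac detection threshold as a fraction of `max(x)` (default 0.5).
#' @param refractory_s minimum peak separation, s (default 0.25).
#' @return data frame with columns `sample` and `type` (all "N").
#' @export
detect_r_peaks <- function(x, fs, frac = 0.5, refractory_s = 0.25) {
  thr <- frac * max(x)
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < length(x)]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  keep <- integer(0)
  last <- -Inf
  for (s in cand) {
    if (s - last >= refractory_s * fs) { keep <- c(keep, s); last <- s }
    else if (x[s] > x[keep[length(keep)]]) keep[length(keep)] <- s
  }
  data.frame(sample = keep, type = rep("N", length(keep)),
             stringsAsFactors = FALSE)
}
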
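#' Soft-thresholding (l1 proximal operator)
#'
#' `soft_threshold(w, t) = sign(w) * max(|w| - t, 0)`, elementwise.  This is
#' the shrinkage step of SALSA.
#'
#' @param w numeric vector (or list of numeric vectors) of coefficients.
#' @param t non-negative threshold (scalar, or one scalar per list element
#'   when `w` is a list).
#' @return object of the same shape as `w`.
#' @export
soft_threshold <- function(w, t) {
  if (is.list(w)) {
    if (length(t) == 1L) t <- rep(t, length(w))
    stopifnot(length(t) == length(w))
    return(mapply(soft_threshold, w, t, SIMPLIFY = FALSE))
  }
  stopifnot(is.numeric(t), length(t) == 1L)
  if (!is.finite(t) || t < 0) stop("threshold t must be >= 0")
  sign(w) * pmax(abs(w) - t, 0)
}

#' Configuration for dual-Q resonance decomposition
#'
#' Bundles the two TQWT dictionary settings and the SALSA solver parameters.
#' The high-Q dictionary models the sustained oscillatory component (the
#' F-wave: a continuous narrowband oscillation is sparse under long,
#' frequency-localised atoms); the low-Q dictionary models the transient
#' component (QRST complexes: compact pulses are sparse under short atoms).
#'
#' @param q_high quality factor of the oscillatory dictionary.  Default 6.42,
#'   the genetic-algorithm optimum reported for this method.  The component
#'   roles follow the dictionary slots (`x_osc` is synthesised from the
#'   `q_high` dictionary), so the scientific convention is `q_high > q_low`;
#'   exchanging the two values exchanges the roles of the returned components.
#' @param q_low quality factor of the transient dictionary (`>= 1`).
#'   Default 1.35.
#' @param r redundancy of both dictionaries, default 3.
#' @param j_high,j_low decomposition depths; `NULL` (default) uses the maximum
#'   level count for the signal length at hand.
#' @param lambda_osc,lambda_trn l1 regularisation weights in signal amplitude
#'   units.  `NULL` defaults to `0.1 *` signal RMS at solve time; use
#'   [calibrate_regularization()] to choose them against records with known
#'   ground truth.
#' @param mu SALSA augmented-Lagrangian parameter (`> 0`), default 2.  Larger
#'   values damp the iteration; the default gives monotone objective decay on
#'   ECG-scale problems.
#' @param n_iter maximum iteration count, default 100.
#' @param tol relative objective-change stopping tolerance, default 1e-6.
#' @return an object of class `dual_q_config`.
#' @export
dual_q_config <- function(q_high = 6.42, q_low = 1.35, r = 3,
                          j_high = NULL, j_low = NULL,
                          lambda_osc = NULL, lambda_trn = NULL,
                          mu = 2, n_iter = 100, tol = 1e-6) {
  if (!is.numeric(q_high) || !is.numeric(q_low) || min(q_high, q_low) < 1 ||
      q_high == q_low) {
    stop("need two distinct quality factors >= 1")
  }
  if (!is.null(lambda_osc) && lambda_osc < 0) stop("lambda_osc must be >= 0")
  if (!is.null(lambda_trn) && lambda_trn < 0) stop("lambda_trn must be >= 0")
  if (mu <= 0) stop("mu must be > 0")
  if (n_iter < 1) stop("n_iter must be >= 1")
  structure(list(q_high = q_high, q_low = q_low, r = r,
                 j_high = j_high, j_low = j_low,
                 lambda_osc = lambda_osc, lambda_trn = lambda_trn,
                 mu = mu, n_iter = as.integer(n_iter), tol = tol),
            class = "dual_q_config")
}

#' @export
print.dual_q_config <- function(x, ...) {
  cat(sprintf("dual-Q decomposition config: Q = (%g, %g), r = %g\n",
              x$q_high, x$q_low, x$r))
  cat(sprintf("  lambda = (%s, %s), mu = %g, n_iter = %d, tol = %g\n",
              if (is.null(x$lambda_osc)) "auto" else format(x$lambda_osc),
              if (is.null(x$lambda_trn)) "auto" else format(x$lambda_trn),
              x$mu, x$n_iter, x$tol))
  invisible(x)
}

## resolve dictionary plans + per-subband penalty weights for a signal length
resolve_dictionaries <- function(N, cfg) {
  jh <- if (is.null(cfg$j_high)) tqwt_max_levels(N, cfg$q_high, cfg$r) else cfg$j_high
  jl <- if (is.null(cfg$j_low)) tqwt_max_levels(N, cfg$q_low, cfg$r) else cfg$j_low
  list(ph = get_plan(N, cfg$q_high, cfg$r, jh),
       pl = get_plan(N, cfg$q_low, cfg$r, jl),
       nh = tqwt_wavelet_norms(N, cfg$q_high, cfg$r, jh),
       nl = tqwt_wavelet_norms(N, cfg$q_low, cfg$r, jl))
}

resolve_lambdas <- function(x, cfg) {
  rms <- sqrt(mean(x^2))
  c(osc = if (is.null(cfg$lambda_osc)) 0.1 * rms else as.numeric(cfg$lambda_osc[1]),
    trn = if (is.null(cfg$lambda_trn)) 0.1 * rms else as.numeric(cfg$lambda_trn[1]))
}

#' Morphological component analysis objective
#'
#' Value of the MCA objective
#' `J(W1, W2) = ||x - S1 W1 - S2 W2||_2^2 + lambda_1 ||W1||_1 + lambda_2 ||W2||_1`
#' where `S1`, `S2` are the high-/low-Q TQWT synthesis operators and the l1
#' penalties are weighted per subband by the synthesis wavelet norms (see
#' [tqwt_wavelet_norms()]).
#'
#' @param x observed signal.
#' @param w_osc,w_trn `tqwt_coeffs` for the oscillatory and transient
#'   dictionaries (must match `cfg` and `length(x)`).
#' @param cfg a [dual_q_config()]; `lambda_*` must be set (not `NULL`).
#' @return scalar objective value.
#' @export
mca_objective <- function(x, w_osc, w_trn, cfg) {
  stopifnot(inherits(w_osc, "tqwt_coeffs"), inherits(w_trn, "tqwt_coeffs"),
            inherits(cfg, "dual_q_config"))
  if (w_osc$N != length(x) || w_trn$N != length(x)) {
    stop("coefficient sets do not match length(x)")
  }
  if (w_osc$Q != cfg$q_high || w_trn$Q != cfg$q_low) {
    stop("coefficient sets do not match the configured dictionaries")
  }
  lam <- resolve_lambdas(x, cfg)
  nh <- tqwt_wavelet_norms(length(x), cfg$q_high, cfg$r, w_osc$J)
  nl <- tqwt_wavelet_norms(length(x), cfg$q_low, cfg$r, w_trn$J)
  fid <- sum((x - tqwt_inverse(w_osc) - tqwt_inverse(w_trn))^2)
  pen1 <- sum(mapply(function(v, nw) nw * sum(abs(v)), w_osc$subbands, lam["osc"] * nh))
  pen2 <- sum(mapply(function(v, nw) nw * sum(abs(v)), w_trn$subbands, lam["trn"] * nl))
  fid + pen1 + pen2
}

#' Resonance-based signal decomposition of an ECG trace
#'
#' Splits a single-lead trace into an oscillatory component `x_osc` (the
#' F-wave estimate, sparse in the high-Q dictionary), a transient component
#' `x_trn` (the QRST estimate, sparse in the low-Q dictionary) and a residual,
#' by minimising the MCA objective ([mca_objective()]) with SALSA, an
#' ADMM-type solver.  The data-consistency step is solved exactly in the
#' transform domain using the Parseval-frame identity (`S S^T = I` per
#' dictionary), so each iteration costs four transforms.
#'
#' The returned components are the synthesis of the shrunken (thresholded)
#' coefficient iterate; `x_osc + x_trn + residual == x` holds exactly by
#' construction.
#'
#' @param x numeric signal (`length >= 64`, finite).
#' @param cfg a [dual_q_config()].
#' @return an object of class `resonance_decomposition` with fields `x_osc`,
#'   `x_trn`, `residual`, `objective_trace`, `iterations`, `coeffs_osc`,
#'   `coeffs_trn`, `lambda` and `cfg`.
#' @examples
#' t <- seq(0, 4, by = 1/500)[-1]
#' x <- 50 * sin(2 * pi * 8 * t) + 300 * (abs(t %% 1 - 0.5) < 0.01)
#' d <- resonance_decompose(x, dual_q_config(n_iter = 30))
#' max(abs(d$x_osc + d$x_trn + d$residual - x))
#' @export
resonance_decompose <- function(x, cfg = dual_q_config()) {
  stopifnot(inherits(cfg, "dual_q_config"))
  if (!is.numeric(x) || length(x) < 64) stop("x must be numeric with length >= 64")
  if (any(!is.finite(x))) stop("x contains non-finite samples")
  x <- as.numeric(x)
  N <- length(x)
  dic <- resolve_dictionaries(N, cfg)
  lam <- resolve_lambdas(x, cfg)
  T1 <- lam["osc"] * dic$nh / (2 * cfg$mu)
  T2 <- lam["trn"] * dic$nl / (2 * cfg$mu)

  w1 <- tqwt_forward_plan(x, dic$ph); w2 <- tqwt_forward_plan(x, dic$pl)
  d1 <- tqwt_zero_subbands(dic$ph);   d2 <- tqwt_zero_subbands(dic$pl)
  cprev <- numeric(N)
  obj <- numeric(0)
  s1 <- s2 <- NULL; x1 <- x2 <- numeric(N)
  for (k in seq_len(cfg$n_iter)) {
    s1 <- mapply(function(w, d, t) soft_threshold(w + d, t), w1, d1, T1, SIMPLIFY = FALSE)
    s2 <- mapply(function(w, d, t) soft_threshold(w + d, t), w2, d2, T2, SIMPLIFY = FALSE)
    x1 <- tqwt_inverse_plan(s1, dic$ph)
    x2 <- tqwt_inverse_plan(s2, dic$pl)
    obj[k] <- sum((x - x1 - x2)^2) +
      sum(lam["osc"] * dic$nh * vapply(s1, function(v) sum(abs(v)), numeric(1))) +
      sum(lam["trn"] * dic$nl * vapply(s2, function(v) sum(abs(v)), numeric(1)))
    if (k > 1 && cfg$tol > 0 &&
        abs(obj[k] - obj[k - 1]) < cfg$tol * max(obj[k - 1], .Machine$double.eps)) break
    ## exact data-consistency step: S(u_i) = S(s_i) - c_prev  (perfect
    ## reconstruction of the previous scaled residual under each dictionary)
    cnew <- (x - x1 - x2 + 2 * cprev) / (cfg$mu + 2)
    d1n <- tqwt_forward_plan(cnew, dic$ph)
    d2n <- tqwt_forward_plan(cnew, dic$pl)
    w1 <- mapply(function(s, dn, do) s + dn - do, s1, d1n, d1, SIMPLIFY = FALSE)
    w2 <- mapply(function(s, dn, do) s + dn - do, s2, d2n, d2, SIMPLIFY = FALSE)
    d1 <- d1n; d2 <- d2n; cprev <- cnew
  }
  co <- structure(list(subbands = s1, Q = cfg$q_high, r = cfg$r, J = dic$ph$J,
                       N = N, Np = dic$ph$Np), class = "tqwt_coeffs")
  ct <- structure(list(subbands = s2, Q = cfg$q_low, r = cfg$r, J = dic$pl$J,
                       N = N, Np = dic$pl$Np), class = "tqwt_coeffs")
  structure(list(x_osc = x1, x_trn = x2, residual = x - x1 - x2,
                 objective_trace = obj, iterations = length(obj),
                 coeffs_osc = co, coeffs_trn = ct,
                 lambda = lam, cfg = cfg),
            class = "resonance_decomposition")
}

#' @export
print.resonance_decomposition <- function(x, ...) {
  cat(sprintf("resonance decomposition: Q = (%g, %g), %d iterations\n",
              x$cfg$q_high, x$cfg$q_low, x$iterations))
  cat(sprintf("  RMS: osc %.4g, trn %.4g, residual %.4g\n",
              sqrt(mean(x$x_osc^2)), sqrt(mean(x$x_trn^2)),
              sqrt(mean(x$residual^2))))
  cat(sprintf("  objective: %.6g -> %.6g\n",
              x$objective_trace[1], x$objective_trace[x$iterations]))
  invisible(x)
}

#' Calibrate the regularisation weights on simulated records
#'
#' Evaluates every `(lambda_osc, lambda_trn)` pair of a grid on records with
#' known ground-truth F-waves and returns the pair minimising the mean NMSE of
#' the oscillatory component against the truth (the experimental selection
#' procedure for the regularisation parameters).  Deterministic given inputs.
#'
#' @param records list of [af_record] objects (see [compose_record()]), each
#'   carrying `fwave_truth`.
#' @param grid data frame with columns `lambda_osc` and `lambda_trn`
#'   (absolute, in signal units), or `NULL` for the default grid: the outer
#'   product of `lambda_osc/RMS in {0.1, 0.2, 0.3, 0.5}` and
#'   `lambda_trn/RMS in {0.05, 0.1, 0.2}`, scaled by the mean signal RMS of
#'   the records.  The oscillatory ladder sits higher because the transient
#'   dictionary must stay cheap enough to hold the high-amplitude QRST
#'   complexes.
#' @param cfg base [dual_q_config()]; its `lambda_*` entries are overridden.
#' @param demean remove each record's mean before decomposing (default TRUE,
#'   matching the clean-baseline assumption of the extraction pipeline).
#' @param tie_tol relative NMSE tolerance for tie-breaking (default 0: exact
#'   argmin).  When `> 0`, all pairs scoring within `(1 + tie_tol)` of the
#'   best mean NMSE count as ties and the pair with the smallest
#'   `lambda_osc` (then smallest `lambda_trn`) wins.  On the flat NMSE
#'   plateau typical of low-SNR records this selects the operating point
#'   farthest from the degenerate (zero-component) edge; the benchmark
#'   protocols use 0.05.
#' @return list with `lambda_osc`, `lambda_trn` (the winning pair) and
#'   `table`, the grid with the mean NMSE per pair and a `degenerate` flag.
#'   Pairs whose oscillatory component collapses to zero on any calibration
#'   record are excluded from the argmin (a zero estimate is not an
#'   extraction) unless every pair is degenerate.
#' @export
calibrate_regularization <- function(records, grid = NULL,
                                     cfg = dual_q_config(), demean = TRUE,
                                     tie_tol = 0) {
  stopifnot(length(records) >= 1)
  for (rec in records) {
    if (is.null(rec$fwave_truth)) stop("every record must carry a ground-truth F-wave")
  }
  if (is.null(grid)) {
    rms <- mean(vapply(records, function(r) sqrt(mean(r$x^2)), numeric(1)))
    grid <- expand.grid(lambda_osc = c(0.1, 0.2, 0.3, 0.5) * rms,
                        lambda_trn = c(0.05, 0.1, 0.2) * rms)
  }
  grid <- as.data.frame(grid)
  if (nrow(grid) < 1) stop("empty calibration grid")
  stopifnot(all(c("lambda_osc", "lambda_trn") %in% names(grid)))
  score <- numeric(nrow(grid))
  alive <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ci <- cfg
    ci$lambda_osc <- grid$lambda_osc[i]
    ci$lambda_trn <- grid$lambda_trn[i]
    res <- vapply(records, function(rec) {
      x <- if (demean) rec$x - mean(rec$x) else rec$x
      d <- resonance_decompose(x, ci)
      c(nmse(rec$fwave_truth, d$x_osc), stats::sd(d$x_osc))
    }, numeric(2))
    score[i] <- mean(res[1, ])
    alive[i] <- all(res[2, ] > 0)
  }
  ## a pair whose oscillatory component collapses to zero on some record is
  ## not an extraction; it only competes when every pair is degenerate
  pool <- if (any(alive)) which(alive) else seq_len(nrow(grid))
  cand <- pool[score[pool] <= min(score[pool]) * (1 + tie_tol)]
  best <- cand[order(grid$lambda_osc[cand], grid$lambda_trn[cand])][1]
  grid$mean_nmse <- score
  grid$degenerate <- !alive
  list(lambda_osc = grid$lambda_osc[best], lambda_trn = grid$lambda_trn[best],
       table = grid)
}

#' Extract the F-wave from a record
#'
#' Convenience pipeline: optional demeaning (clean-baseline assumption), dual-Q
#' resonance decomposition, F-wave estimate = oscillatory component.
#'
#' @param record an [af_record] or any list with elements `x` and `fs`.
#' @param cfg a [dual_q_config()].
#' @param demean remove the record mean first (default TRUE).
#' @return the `resonance_decomposition`, with an extra `fwave` field equal to
#'   `x_osc`.
#' @export
fwave_extract <- function(record, cfg = dual_q_config(), demean = TRUE) {
  x <- record$x
  if (demean) x <- x - mean(x)
  d <- resonance_decompose(x, cfg)
  d$fwave <- d$x_osc
  d
}
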
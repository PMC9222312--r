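#' Scale parameters of the tunable Q-factor wavelet transform
#'
#' For a quality factor `Q` and redundancy `r` the two-channel filter bank of
#' the TQWT uses a high-pass scale parameter `beta = 2/(Q+1)` and a low-pass
#' scale parameter `alpha = 1 - beta/r`.  The transform is oversampled
#' (`alpha + beta > 1`), which is what makes perfect reconstruction possible
#' with smooth band-edge filters.
#'
#' @param Q quality factor (dimensionless, `>= 1`).  `Q` is the ratio of a
#'   wavelet's centre frequency to its bandwidth: high `Q` gives sustained
#'   oscillatory atoms, `Q ~ 1` gives transient atoms.
#' @param r redundancy (oversampling) factor, `> 1`.  The default used
#'   throughout this package is 3.
#' @return a list with elements `alpha` and `beta`, both in `(0, 1]`.
#' @examples
#' tqwt_scaling_params(1, 3)      # alpha = 2/3, beta = 1
#' tqwt_scaling_params(6.42, 3)
#' @export
tqwt_scaling_params <- function(Q, r) {
  stopifnot(is.numeric(Q), length(Q) == 1L, is.numeric(r), length(r) == 1L)
  if (!is.finite(Q) || Q < 1) stop("Q must be a finite number >= 1")
  if (!is.finite(r) || r <= 1) stop("r must be a finite number > 1")
  beta <- 2 / (Q + 1)
  alpha <- 1 - beta / r
  list(alpha = alpha, beta = beta)
}

#' Maximum number of TQWT decomposition levels
#'
#' Largest level count `J` such that every subband produced by `J` filter-bank
#' iterations is non-degenerate (the coarsest band keeps at least 8 samples
#' under the geometric `alpha` length schedule):
#' `J_max = floor(log(beta * N / 8) / log(1 / alpha))`.
#'
#' @param N signal length in samples (`>= 8`).
#' @param Q quality factor, see [tqwt_scaling_params()].
#' @param r redundancy, default 3.
#' @return integer level count (`>= 1`); an error is raised when the signal is
#'   too short to support even one level at the requested `Q` and `r`.
#' @examples
#' tqwt_max_levels(512, 1, 3)   # 10
#' @export
tqwt_max_levels <- function(N, Q, r = 3) {
  stopifnot(is.numeric(N), length(N) == 1L)
  if (!is.finite(N) || N < 8) stop("N must be >= 8")
  sp <- tqwt_scaling_params(Q, r)
  L <- floor(log(sp$beta * N / 8) / log(1 / sp$alpha))
  if (L < 1) {
    stop(sprintf("signal too short (N = %d) for one decomposition level at Q = %g, r = %g",
                 as.integer(N), Q, r))
  }
  as.integer(L)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

## Frequency-domain plan for one (N, Q, r, J) configuration.
##
## The iterated analysis bank reduces, in the DFT domain, to a composite map:
## subband j reads the contiguous positive-frequency slice
## [start, start + n_half] of the padded input spectrum with real gains that
## are products of the per-level power-complementary band-edge responses
## theta(w) = (1 + cos w) * sqrt(2 - cos w) / 2 (Daubechies response with two
## vanishing moments).  Band lengths follow the nominal even-rounded schedule
## N0_j = 2*round(alpha^j*Np/2), N1_j = 2*round(beta*alpha^(j-1)*Np/2); each
## subband is stored at the next power of two (radix-2 storage) so every FFT
## in the package is a power-of-two FFT.
tqwt_plan <- function(N, Q, r, J) {
  sp <- tqwt_scaling_params(Q, r)
  alpha <- sp$alpha; beta <- sp$beta
  Np <- next_pow2(max(N, 16L))
  Jmax <- floor(log(beta * Np / 8) / log(1 / alpha))
  if (J > Jmax) {
    stop(sprintf("J = %d exceeds the maximum of %d levels for N = %d, Q = %g, r = %g",
                 J, Jmax, as.integer(N), Q, r))
  }
  if (J < 1) stop("J must be >= 1")
  L <- Np
  chain <- rep(1, Np / 2 + 1)          # cumulative low-pass gain on bins 0..Np/2
  sub <- vector("list", J + 1L)
  for (j in seq_len(J)) {
    N0 <- 2L * round(alpha^j * Np / 2)
    N1 <- 2L * round(beta * alpha^(j - 1) * Np / 2)
    P <- (L - N1) %/% 2L
    Tt <- (N0 + N1 - L) %/% 2L - 1L
    if (P < 0 || Tt < 0) {
      stop(sprintf("degenerate filter bank at level %d (Q = %g, r = %g, N = %d)",
                   j, Q, r, as.integer(N)))
    }
    v <- seq_len(Tt) * pi / (Tt + 1)
    t0 <- (1 + cos(v)) * sqrt(2 - cos(v)) / 2
    t1 <- (1 - cos(v)) * sqrt(2 + cos(v)) / 2
    g1 <- c(0, t1, rep(1, N1 / 2 - Tt))              # high-pass gains, bins P..L/2
    sub[[j]] <- list(start = P, n_half = N1 %/% 2L,
                     gains = chain[(P + 1):(L / 2 + 1)] * g1,
                     M = as.integer(max(8, next_pow2(N1))), N1 = N1)
    g0 <- c(rep(1, P + 1L), t0, rep(0, L / 2 - P - Tt))
    chain <- (chain[1:(L / 2 + 1)] * g0)[1:(N0 / 2 + 1)]
    chain[N0 / 2 + 1] <- 0                            # nominal Nyquist zeroed
    L <- N0
  }
  sub[[J + 1L]] <- list(start = 0L, n_half = L %/% 2L, gains = chain,
                        M = as.integer(max(8, next_pow2(L))), N1 = L)
  structure(list(N = as.integer(N), Np = as.integer(Np), Q = Q, r = r,
                 J = as.integer(J), alpha = alpha, beta = beta, sub = sub),
            class = "tqwt_plan")
}

.plan_cache <- new.env(parent = emptyenv())

get_plan <- function(N, Q, r, J) {
  key <- paste(N, Q, r, J, sep = "|")
  p <- .plan_cache[[key]]
  if (is.null(p)) {
    p <- tqwt_plan(N, Q, r, J)
    .plan_cache[[key]] <- p
  }
  p
}

## Hermitian completion: build a length-M complex spectrum from positive bins
## 0..nh (values `pos`).  When storage is oversampled (M > 2*nh) the nominal
## Nyquist value is split across the +/- bins with 1/sqrt(2) so that both the
## time signal is real and the unitary energy bookkeeping stays exact.
herm_full <- function(pos, M) {
  nh <- length(pos) - 1L
  V <- complex(M)
  V[1:(nh + 1)] <- pos
  if (M == 2L * nh) {
    V[nh + 1] <- Re(pos[nh + 1])
    if (nh > 1) V[M:(nh + 2)] <- Conj(pos[2:nh])
  } else {
    ny <- pos[nh + 1] / sqrt(2)
    V[nh + 1] <- ny
    V[M - nh + 1] <- Conj(ny)
    if (nh > 1) V[M:(M - nh + 2)] <- Conj(pos[2:nh])
  }
  V
}

tqwt_forward_plan <- function(x, plan) {
  xp <- c(x, numeric(plan$Np - length(x)))
  X <- stats::fft(xp) / sqrt(plan$Np)
  lapply(plan$sub, function(s) {
    pos <- X[(s$start + 1):(s$start + s$n_half + 1)] * s$gains
    Re(stats::fft(herm_full(pos, s$M), inverse = TRUE)) / sqrt(s$M)
  })
}

tqwt_inverse_plan <- function(subbands, plan) {
  half <- plan$Np %/% 2L
  acc <- complex(half + 1L)
  for (j in seq_along(plan$sub)) {
    s <- plan$sub[[j]]
    U <- stats::fft(subbands[[j]]) / sqrt(s$M)
    pos <- U[1:(s$n_half + 1)]
    if (s$M != 2L * s$n_half) pos[s$n_half + 1] <- pos[s$n_half + 1] * sqrt(2)
    idx <- (s$start + 1):(s$start + s$n_half + 1)
    acc[idx] <- acc[idx] + pos * s$gains
  }
  V <- complex(plan$Np)
  V[1:(half + 1)] <- acc
  V[half + 1] <- Re(acc[half + 1])
  V[plan$Np:(half + 2)] <- Conj(acc[2:half])
  Re(stats::fft(V, inverse = TRUE))[1:plan$N] / sqrt(plan$Np)
}

#' Forward tunable Q-factor wavelet transform
#'
#' Decomposes a real signal into `J + 1` subbands (levels `1..J` high-pass
#' outputs, coarsest low-pass last) with an iterated oversampled two-channel
#' filter bank realised in the DFT domain.  The transform is a Parseval frame:
#' subband energies sum to the signal energy, and [tqwt_inverse()] restores
#' the signal to floating-point accuracy.
#'
#' Signals are zero-padded internally to the next power of two (the padding is
#' recorded and removed on inversion); subbands are stored at power-of-two
#' lengths (radix-2 storage convention).
#'
#' @param x real numeric signal, all finite, `length(x) >= 16`.
#' @param Q quality factor (`>= 1`).
#' @param r redundancy, default 3.
#' @param J number of levels; default [tqwt_max_levels()] of `length(x)`.
#' @return an object of class `tqwt_coeffs`: list with `subbands` (list of
#'   `J + 1` numeric vectors), `Q`, `r`, `J`, `N` (original length) and `Np`
#'   (padded length).
#' @seealso [tqwt_inverse()], [tqwt_wavelet_norms()]
#' @examples
#' x <- sin(2 * pi * 8 * seq(0, 2, by = 1/500))
#' w <- tqwt(x, Q = 3, r = 3, J = 8)
#' max(abs(tqwt_inverse(w) - x))
#' @export
tqwt <- function(x, Q, r = 3, J = NULL) {
  if (!is.numeric(x) || length(x) < 16) stop("x must be numeric with length >= 16")
  if (any(!is.finite(x))) stop("x contains non-finite samples")
  if (is.null(J)) J <- tqwt_max_levels(length(x), Q, r)
  plan <- get_plan(length(x), Q, r, J)
  structure(list(subbands = tqwt_forward_plan(as.numeric(x), plan),
                 Q = Q, r = r, J = plan$J, N = plan$N, Np = plan$Np),
            class = "tqwt_coeffs")
}

#' Inverse tunable Q-factor wavelet transform
#'
#' Exact inverse of [tqwt()] (synthesis bank run in reverse); the output has
#' the original signal length.
#'
#' @param coeffs a `tqwt_coeffs` object (possibly with modified subbands, e.g.
#'   after thresholding); subband lengths must match the configuration.
#' @return numeric signal of length `coeffs$N`.
#' @export
tqwt_inverse <- function(coeffs) {
  stopifnot(inherits(coeffs, "tqwt_coeffs"))
  plan <- get_plan(coeffs$N, coeffs$Q, coeffs$r, coeffs$J)
  lens <- vapply(plan$sub, function(s) s$M, integer(1))
  got <- vapply(coeffs$subbands, length, integer(1))
  if (length(got) != length(lens) || any(got != lens)) {
    stop("subband lengths are inconsistent with the transform configuration")
  }
  tqwt_inverse_plan(coeffs$subbands, plan)
}

#' @export
print.tqwt_coeffs <- function(x, ...) {
  cat(sprintf("TQWT coefficients: Q = %g, r = %g, J = %d, N = %d (padded %d)\n",
              x$Q, x$r, x$J, x$N, x$Np))
  en <- vapply(x$subbands, function(v) sum(v^2), numeric(1))
  cat(sprintf("  %d subbands, total energy %.6g\n", length(x$subbands), sum(en)))
  invisible(x)
}

#' Synthesis wavelet norms per subband
#'
#' The l2 norm of the synthesis wavelet of each subband, obtained by inverting
#' a unit impulse placed at the centre of that subband.  Used to scale
#' per-subband l1 penalties so that regularisation is uniform in signal units
#' across scales (a coefficient of size `lambda / norm_j` contributes the same
#' signal amplitude in every band).
#'
#' @inheritParams tqwt
#' @param N signal length the transform will be applied to.
#' @return numeric vector of `J + 1` strictly positive norms.
#' @export
tqwt_wavelet_norms <- function(N, Q, r = 3, J = NULL) {
  if (is.null(J)) J <- tqwt_max_levels(N, Q, r)
  plan <- get_plan(N, Q, r, J)
  if (is.null(plan$norms)) {
    norms <- vapply(seq_along(plan$sub), function(j) {
      w <- lapply(plan$sub, function(s) numeric(s$M))
      w[[j]][plan$sub[[j]]$M %/% 2L] <- 1
      sqrt(sum(tqwt_inverse_plan(w, plan)^2))
    }, numeric(1))
    plan$norms <- norms
    .plan_cache[[paste(N, Q, r, J, sep = "|")]] <- plan
  }
  plan$norms
}

## zero coefficient set shaped like the given plan
tqwt_zero_subbands <- function(plan) lapply(plan$sub, function(s) numeric(s$M))
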
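## shared fixtures, built in code

fs_std <- 500

## separation-premise mixture: amplitude-modulated 8 Hz tone plus a sparse
## train of narrow biphasic pulses (about 3:1 peak ratio)
premise_mixture <- function(n = 5000, fs = fs_std, seed = 42) {
  tt <- (seq_len(n) - 1) / fs
  osc <- (50 + 15 * sin(2 * pi * 0.4 * tt)) * sin(2 * pi * 8 * tt)
  pul <- numeric(n)
  centers <- withr::with_seed(seed,
    seq(0.5, n / fs - 0.5, by = 0.8) + stats::rnorm(length(seq(0.5, n / fs - 0.5, by = 0.8)), 0, 0.08))
  for (t0 in centers) {
    pul <- pul + 150 * exp(-((tt - t0)^2) / (2 * 0.02^2)) -
                  90 * exp(-((tt - t0 - 0.05)^2) / (2 * 0.025^2))
  }
  list(x = osc + pul, osc = osc, pul = pul, fs = fs)
}

## small ensemble of simulated AF records with derived per-record seeds
make_ensemble <- function(type, n_records, noise_uV = 0, pvc_prob = 0,
                          duration_s = 10, seed = 1) {
  fp <- fwave_params(type, "II")
  lapply(seq_len(n_records), function(k) {
    compose_record(fp, vent_cfg = list(pvc_prob = pvc_prob),
                   noise_uV = noise_uV, duration_s = duration_s,
                   seed = derive_seed(seed, k))
  })
}
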
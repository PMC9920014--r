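# shared fixtures, built in code

# small phantom for fast FDTD unit tests: 60 x 40 mm, 4 antennas
tiny_config <- function(...) {
  phantom_config(width = 60, depth = 40, array_span = 30, n_antennas = 4,
                 alns = list(aln(depth = 15, long_axis = 8)), ...)
}

tiny_sim <- function(time_window = 1.6e-9) sim_config(time_window = time_window)

# bare channel_data for beamformer/metric tests
make_channels <- function(signals, dt, antennas, t0 = 0) {
  structure(list(signals = signals, dt = dt, t0 = t0,
                 antennas = antennas, provenance = list()),
            class = "channel_data")
}

# bare energy_map on a pitch-aligned grid
make_map <- function(energy, pitch = 0.5, depth0 = pitch, lateral0 = pitch) {
  structure(list(energy = energy,
                 depth = depth0 + (seq_len(nrow(energy)) - 1) * pitch,
                 lateral = lateral0 + (seq_len(ncol(energy)) - 1) * pitch,
                 pitch = pitch, method = "test", provenance = list()),
            class = "energy_map")
}

# analytic point-target channels: one pulse per channel at its round-trip
# delay from `target`, on the antennas of `antennas` (data.frame x, depth)
point_target_channels <- function(target, antennas, speed = 1.5e8,
                                  dt = 2e-12, Tlen = 1500,
                                  pulse = pulse_spec()) {
  M <- nrow(antennas)
  tt <- (seq_len(Tlen) - 1) * dt
  sig <- matrix(0, M, Tlen)
  for (m in seq_len(M)) {
    d <- sqrt((antennas$x[m] - target[1])^2 + (antennas$depth[m] - target[2])^2)
    tau <- 2 * d * 1e-3 / speed
    sig[m, ] <- differentiated_gaussian(tt - tau, pulse)
  }
  make_channels(sig, dt, antennas, t0 = pulse$t0)
}

# Hilbert envelope via FFT (analytic-signal magnitude)
hilbert_env <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# naive DAS / DMAS reference: explicit loops over pixels, window and channels
naive_beamform <- function(signals, start, wt, W, dmas) {
  P <- nrow(start); M <- ncol(start); Tn <- ncol(signals)
  out <- numeric(P)
  for (p in seq_len(P)) {
    acc <- 0
    for (w in 0:(W - 1)) {
      a <- numeric(M)
      for (m in seq_len(M)) {
        idx <- round(start[p, m]) + w + 1
        a[m] <- if (idx >= 1 && idx <= Tn) wt[p, m] * signals[m, idx] else 0
      }
      v <- if (dmas) {
        s <- 0
        for (i in seq_len(M - 1)) for (j in (i + 1):M) s <- s + a[i] * a[j]
        s
      } else sum(a)
      acc <- acc + v^2
    }
    out[p] <- acc
  }
  out
}
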
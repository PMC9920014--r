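#' Imaging grid over the phantom interior
#'
#' Pixel centers in the phantom's mm frame, covering the region below the
#' skin by default.
#'
#' @param phantom a [build_phantom()] result.
#' @param pitch pixel pitch in mm (defaults to the phantom `dx`).
#' @param depth_range `c(min, max)` depth in mm; defaults to just below the
#'   deepest point of the skin down to the bottom of the region.
#' @return An object of class `imaging_grid` with pixel-center coordinate
#'   vectors `depth` and `lateral` and the pitch.
#' @export
imaging_grid <- function(phantom, pitch = phantom$dx, depth_range = NULL) {
  cfg <- phantom$config
  if (is.null(depth_range)) {
    skin_bottom <- max(phantom$eta) + cfg$skin_thickness
    depth_range <- c(skin_bottom + pitch, cfg$depth - pitch)
  }
  # pixels on the plain mm lattice (integer multiples of the pitch) so that
  # grid-aligned anatomy can be localized exactly
  d1 <- ceiling(depth_range[1] / pitch) * pitch
  structure(list(
    depth = seq(d1, depth_range[2], by = pitch),
    lateral = seq(pitch, cfg$width - pitch, by = pitch),
    pitch = pitch), class = "imaging_grid")
}

#' Round-trip focusing delays
#'
#' Monostatic round-trip delay from each antenna to each pixel,
#' `2 * distance / speed`, optionally corrected for the extra transit through
#' the skin layer (the vertical-path approximation
#' \eqn{2 t_{skin} (\sqrt{\varepsilon_{skin}} - \sqrt{\varepsilon_{bg}})/c_0}
#' added to every channel).
#'
#' @param grid an [imaging_grid()].
#' @param antennas data.frame with mm columns `x` and `depth`.
#' @param speed propagation speed in m/s (see [effective_speed()]).
#' @param skin_delay per-channel extra delay in seconds (scalar or length-M).
#' @return List of class `delay_table`: `delay` (P x M seconds, pixels in
#'   depth-major order), `dist` (P x M mm), `speed`, and the grid.
#' @export
compute_delays <- function(grid, antennas, speed, skin_delay = 0) {
  stopifnot(inherits(grid, "imaging_grid"), speed > 0)
  nd <- length(grid$depth); nl <- length(grid$lateral)
  pd <- rep(grid$depth, times = nl)
  px <- rep(grid$lateral, each = nd)
  M <- nrow(antennas)
  dist <- matrix(0, nd * nl, M)
  for (m in seq_len(M))
    dist[, m] <- sqrt((px - antennas$x[m])^2 + (pd - antennas$depth[m])^2)
  delay <- 2 * dist * 1e-3 / speed +
    matrix(skin_delay, nd * nl, M, byrow = TRUE)
  structure(list(delay = delay, dist = dist, speed = speed, grid = grid),
            class = "delay_table")
}

#' Channel-rank weights
#'
#' Weights channels by the rank of their propagation distance: the shortest
#' path gets the largest weight. Linear rank weights `M - rank + 1` are
#' normalized to sum to M, so equal distances give unit weights; ties share
#' the averaged rank.
#'
#' @param distances numeric vector (one pixel) or P x M matrix of
#'   antenna-pixel distances.
#' @param M number of channels (defaults from the input).
#' @return Weights with the shape of `distances`, each row summing to M.
#' @export
rank_weights <- function(distances, M = NULL) {
  if (is.matrix(distances)) {
    M <- if (is.null(M)) ncol(distances) else M
    # row-wise average ranks via pairwise column comparisons (M^2 vector
    # ops) instead of a per-row apply over tens of thousands of pixels
    P <- nrow(distances)
    rk <- matrix(1, P, M)
    for (a in seq_len(M)) for (b in seq_len(M)) {
      if (a == b) next
      rk[, a] <- rk[, a] + (distances[, b] < distances[, a]) +
        0.5 * (distances[, b] == distances[, a])
    }
    w <- M - rk + 1
    w * (M / rowSums(w))
  } else {
    M <- if (is.null(M)) length(distances) else M
    w <- M - rank(distances, ties.method = "average") + 1
    w * (M / sum(w))
  }
}

# shared lookup-index preparation: first window sample per (pixel, channel),
# 0-based. With "arrival" alignment the integration window starts at the
# round-trip arrival time; with "centered" it is centered on the expected
# envelope peak (arrival + pulse peak time), the unbiased matched choice for
# an isolated point echo.
window_start <- function(channels, delays, window, align = "arrival") {
  W <- if (is.null(window)) max(1L, round(150e-12 / channels$dt)) else as.integer(window)
  start <- switch(align,
    arrival = delays$delay / channels$dt,
    centered = (delays$delay + channels$t0) / channels$dt - W / 2,
    stop("unknown window alignment '", align, "'"))
  list(start = start, W = W)
}

finish_map <- function(vals, grid, method, channels) {
  structure(list(
    energy = matrix(vals, length(grid$depth), length(grid$lateral)),
    depth = grid$depth, lateral = grid$lateral, pitch = grid$pitch,
    method = method, provenance = channels$provenance),
    class = "energy_map")
}

#' Delay-and-sum beamformer
#'
#' For each pixel the channels are time-shifted by their round-trip delays,
#' optionally weighted, summed, squared, and accumulated over an integration
#' window the length of the incident pulse:
#' \deqn{I(p) = \sum_{t \in W} \Big[\sum_m w_m\, s_m(t + \tau_{p,m})\Big]^2.}
#' Unit weights give plain DAS; [rank_weights()] give CR-DAS.
#'
#' @param channels a `channel_data` after artifact removal.
#' @param delays a [compute_delays()] table.
#' @param weights optional P x M weight matrix.
#' @param window integration window length in samples; `NULL` uses the
#'   number of samples in 150 ps.
#' @param interp linear interpolation of fractional delays instead of
#'   nearest-sample lookup.
#' @param align `"arrival"` anchors the integration window at the round-trip
#'   arrival time (standard confocal practice); `"centered"` centers it on
#'   the expected pulse envelope peak, which localizes an isolated point
#'   echo without bias.
#' @return An `energy_map`.
#' @export
das <- function(channels, delays, weights = NULL, window = NULL,
                interp = FALSE, align = "arrival") {
  stopifnot(inherits(channels, "channel_data"), inherits(delays, "delay_table"))
  ws <- window_start(channels, delays, window, align)
  M <- nrow(channels$signals)
  wt <- if (is.null(weights)) matrix(1, nrow(delays$delay), M) else weights
  vals <- beamform_core_cpp(t(channels$signals), ws$start, wt, ws$W, FALSE,
                            interp)
  finish_map(vals, delays$grid, if (is.null(weights)) "DAS" else "CR-DAS",
             channels)
}

#' Delay-multiply-and-sum beamformer
#'
#' After delaying (and, for the channel-ranked variant, rank-weighting) the
#' channels, all unordered pairs are multiplied, the pair products are
#' summed, the pair-sum is squared and accumulated over the window:
#' \deqn{I(p) = \sum_{t \in W} \Big[\sum_{i<j} \hat s_i(t)\, \hat s_j(t)\Big]^2.}
#' The pair multiplication suppresses clutter that is not coherent across
#' channels. Computed through the identity
#' \eqn{\sum_{i<j} a_i a_j = ((\sum_i a_i)^2 - \sum_i a_i^2)/2}.
#'
#' @inheritParams das
#' @return An `energy_map`.
#' @export
dmas <- function(channels, delays, weights = NULL, window = NULL,
                 interp = FALSE, align = "arrival") {
  stopifnot(inherits(channels, "channel_data"), inherits(delays, "delay_table"))
  if (nrow(channels$signals) < 2) stop("DMAS needs M >= 2 channels")
  ws <- window_start(channels, delays, window, align)
  M <- nrow(channels$signals)
  wt <- if (is.null(weights)) matrix(1, nrow(delays$delay), M) else weights
  vals <- beamform_core_cpp(t(channels$signals), ws$start, wt, ws$W, TRUE,
                            interp)
  finish_map(vals, delays$grid, if (is.null(weights)) "DMAS" else "CR-DMAS",
             channels)
}

#' Reconstruct a backscattered-energy image
#'
#' Dispatches the delay table, channel-rank weights (for the CR variants)
#' and the beamformer. The propagation speed defaults to the effective speed
#' of the healthy background at the pulse center frequency, and the delay
#' model adds the skin transit correction computed from the phantom's skin
#' thickness.
#'
#' @param channels a `channel_data` after artifact removal.
#' @param phantom the phantom the channels were acquired from.
#' @param method one of `"DAS"`, `"DMAS"`, `"CR-DAS"`, `"CR-DMAS"`
#'   (case-insensitive).
#' @param grid an [imaging_grid()]; built from the phantom when `NULL`.
#' @param speed propagation speed in m/s; `NULL` computes it from the
#'   background tissue.
#' @param skin_correction apply the skin transit delay correction.
#' @param window integration window in samples (`NULL`: 150 ps worth).
#' @param interp linear interpolation of fractional delays.
#' @param align window alignment, `"arrival"` or `"centered"` (see [das()]).
#' @return An `energy_map`.
#' @export
reconstruct <- function(channels, phantom, method = "CR-DMAS", grid = NULL,
                        speed = NULL, skin_correction = TRUE, window = NULL,
                        interp = FALSE, align = "arrival") {
  method <- toupper(method)
  if (!method %in% c("DAS", "DMAS", "CR-DAS", "CR-DMAS"))
    stop("unknown beamformer '", method, "'")
  if (is.null(grid)) grid <- imaging_grid(phantom)
  f0 <- pulse_frequency(channels)
  bg <- phantom$tissues$background_healthy
  if (is.null(speed)) speed <- effective_speed(bg, f0)
  skin_delay <- if (skin_correction) {
    sk <- phantom$tissues$skin
    2 * phantom$config$skin_thickness * 1e-3 *
      (sqrt(Re(debye_permittivity(sk, f0))) -
       sqrt(Re(debye_permittivity(bg, f0)))) / C0
  } else 0
  delays <- compute_delays(grid, phantom$antennas, speed, skin_delay)
  weights <- if (startsWith(method, "CR")) rank_weights(delays$dist) else NULL
  if (endsWith(method, "DMAS"))
    dmas(channels, delays, weights, window, interp, align)
  else das(channels, delays, weights, window, interp, align)
}

pulse_frequency <- function(channels) {
  f0 <- channels$provenance$pulse$center_frequency
  if (is.null(f0)) 7.5e9 else f0
}

#' @export
print.energy_map <- function(x, ...) {
  cat(sprintf("energy_map (%s): %d x %d pixels at %.2g mm pitch, peak %.3g\n",
              x$method, nrow(x$energy), ncol(x$energy), x$pitch,
              max(x$energy)))
  invisible(x)
}
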
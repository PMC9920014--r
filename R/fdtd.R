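C0 <- 299792458

# session cache for incident-reference runs (keyed on pulse/time axis)
.axmwi_cache <- new.env(parent = emptyenv())

#' FDTD simulation configuration
#'
#' @param courant Courant factor; must be below the 2D stability limit
#'   \eqn{1/\sqrt{2}}. The time step is `courant * dx / c0`.
#' @param time_window total simulated time in seconds. The 4-ns default
#'   covers the round trip to the bottom of the 100-mm region in the
#'   healthy-background medium with margin.
#' @param npml thickness of the convolutional-PML absorbing boundary in
#'   cells.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(courant = 0.95 / sqrt(2), time_window = 4e-9,
                       npml = 10L) {
  if (courant >= 1 / sqrt(2)) stop("courant must be < 1/sqrt(2) for 2D stability")
  if (courant <= 0) stop("courant must be > 0")
  if (time_window <= 0) stop("time_window must be > 0")
  structure(list(courant = courant, time_window = time_window,
                 npml = as.integer(npml)),
            class = "sim_config")
}

pad_edges <- function(m, n) {
  m <- m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), , drop = FALSE]
  m[, c(rep(1, n), seq_len(ncol(m)), rep(ncol(m), n)), drop = FALSE]
}

#' Run a single-channel FDTD simulation
#'
#' TM-polarized 2D update with single-pole Debye plus static-conductivity
#' media (auxiliary-differential-equation scheme) and convolutional-PML
#' boundaries on all four sides. A soft point source injects the pulse at the
#' given cell and the field at that cell (or at `receiver`) is recorded over
#' the full time window. The phantom grids are edge-replicated into the PML
#' so the boundary is matched to the adjacent medium.
#'
#' @param phantom a [build_phantom()] result.
#' @param source integer `c(i, j)` grid cell of the source.
#' @param pulse a [pulse_spec()].
#' @param sim a [sim_config()].
#' @param receiver optional `c(i, j)` cell to record instead of the source.
#' @return Numeric vector of the recorded field, one sample per time step;
#'   attributes `dt` (seconds) and `t0` (pulse envelope-peak time).
#' @export
run_fdtd <- function(phantom, source, pulse = pulse_spec(),
                     sim = sim_config(), receiver = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(sim, "sim_config"))
  dxm <- phantom$dx * 1e-3
  dt <- sim$courant * dxm / C0
  nsteps <- ceiling(sim$time_window / dt)
  tt <- (seq_len(nsteps) - 1) * dt
  s <- differentiated_gaussian(tt, pulse)
  n <- sim$npml
  if (source[1] < 1 || source[1] > nrow(phantom$tissue) ||
      source[2] < 1 || source[2] > ncol(phantom$tissue))
    stop("source cell outside the grid")
  ri <- if (is.null(receiver)) -1L else as.integer(receiver[1] - 1L + n)
  rj <- if (is.null(receiver)) -1L else as.integer(receiver[2] - 1L + n)
  rec <- fdtd_run_cpp(pad_edges(phantom$eps_inf, n),
                      pad_edges(phantom$delta_eps, n),
                      pad_edges(phantom$sigma_s, n),
                      pad_edges(phantom$tau, n),
                      dxm, dt, nsteps, n,
                      as.integer(source[1] - 1L + n),
                      as.integer(source[2] - 1L + n),
                      s, ri, rj)
  structure(rec, dt = dt, t0 = pulse$t0)
}

# incident field at the source cell of an all-air domain; independent of the
# source position (absorbing boundaries), so one run per time axis suffices
incident_reference <- function(pulse, sim, dx) {
  dxm <- dx * 1e-3
  dt <- sim$courant * dxm / C0
  nsteps <- ceiling(sim$time_window / dt)
  key <- paste(signif(dt, 12), nsteps, signif(pulse$sigma, 12), sim$npml)
  if (!is.null(.axmwi_cache[[key]])) return(.axmwi_cache[[key]])
  side <- 120L
  air <- matrix(1, side, side)
  zero <- matrix(0, side, side)
  tt <- (seq_len(nsteps) - 1) * dt
  s <- differentiated_gaussian(tt, pulse)
  n <- sim$npml
  rec <- fdtd_run_cpp(pad_edges(air, n), pad_edges(zero, n),
                      pad_edges(zero, n), pad_edges(matrix(13e-12, side, side), n),
                      dxm, dt, nsteps, n, n + side %/% 2L, n + side %/% 2L,
                      s, -1L, -1L)
  .axmwi_cache[[key]] <- rec
  rec
}

#' Acquire monostatic channel data
#'
#' Runs one FDTD simulation per antenna, recording the backscatter at the
#' transmitting antenna (monostatic acquisition). By default the incident
#' field -- the signal the antenna would record in free space with no
#' phantom -- is subtracted from every channel, so the output contains the
#' skin response and the interior scatterers only.
#'
#' @param phantom a [build_phantom()] result with antenna positions.
#' @param pulse a [pulse_spec()].
#' @param sim a [sim_config()].
#' @param subtract_incident subtract the free-space incident reference.
#' @param progress print one line per channel.
#' @return An object of class `channel_data`: `signals` (M x T matrix, one
#'   row per antenna), `dt`, `t0`, `antennas`, and provenance.
#' @export
run_monostatic <- function(phantom, pulse = pulse_spec(), sim = sim_config(),
                           subtract_incident = TRUE, progress = FALSE) {
  ants <- phantom$antennas
  if (is.null(ants) || nrow(ants) == 0) stop("phantom has no antenna positions")
  inc <- if (subtract_incident) incident_reference(pulse, sim, phantom$dx) else NULL
  sig <- NULL
  for (m in seq_len(nrow(ants))) {
    r <- tryCatch(
      run_fdtd(phantom, c(ants$i[m], ants$j[m]), pulse, sim),
      error = function(e) stop("FDTD failed for antenna ", m, ": ",
                               conditionMessage(e)))
    if (is.null(sig)) sig <- matrix(0, nrow(ants), length(r))
    sig[m, ] <- if (subtract_incident) r - inc else r
    if (progress) message("antenna ", m, "/", nrow(ants))
  }
  dt <- sim$courant * phantom$dx * 1e-3 / C0
  structure(list(signals = sig, dt = dt, t0 = pulse$t0,
                 antennas = ants,
                 provenance = list(pulse = unclass(pulse), sim = unclass(sim),
                                   config = phantom$config)),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  cat(sprintf("channel_data: M = %d channels x T = %d samples, dt = %.4g ps\n",
              nrow(x$signals), ncol(x$signals), x$dt * 1e12))
  invisible(x)
}
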
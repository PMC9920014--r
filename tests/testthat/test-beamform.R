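test_that("delays follow the monostatic round-trip rule", {
  g <- structure(list(depth = seq(1, 30, by = 0.5),
                      lateral = seq(0.5, 40, by = 0.5), pitch = 0.5),
                 class = "imaging_grid")
  ants <- data.frame(x = c(10, 20), depth = c(0, 0))
  spd <- 299792458 / sqrt(4.3)
  dl <- compute_delays(g, ants, spd)
  # pixel 20 mm below antenna 1
  p <- which(rep(g$lateral, each = length(g$depth)) == 10 &
             rep(g$depth, times = length(g$lateral)) == 20)
  expect_equal(dl$delay[p, 1], 2 * 0.020 * sqrt(4.3) / 299792458,
               tolerance = 1e-12)
  # zero-distance pixel
  p0 <- which(rep(g$lateral, each = length(g$depth)) == 10 &
              rep(g$depth, times = length(g$lateral)) == min(g$depth))
  expect_lt(dl$delay[p0, 1], 2 * 0.0011 * sqrt(4.3) / 299792458)
  # monotone in depth under an antenna
  col <- which(rep(g$lateral, each = length(g$depth)) == 20)
  expect_true(all(diff(dl$delay[col, 2]) > 0))
  # per-channel skin correction is additive
  dl2 <- compute_delays(g, ants, spd, skin_delay = 5e-11)
  expect_equal(dl2$delay, dl$delay + 5e-11, tolerance = 1e-15)
})

test_that("rank weights follow the linear-rank rule, normalized to M", {
  expect_equal(rank_weights(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(rank_weights(c(10, 20, 30)), c(1.5, 1.0, 0.5))
  w <- rank_weights(c(30, 10, 20))
  expect_equal(w, c(0.5, 1.5, 1.0))                       # equivariance
  set.seed(6)
  d <- matrix(runif(12 * 16), 12, 16)
  W <- rank_weights(d)
  expect_equal(rowSums(W), rep(16, 12))
  # shortest distance gets the largest weight in every row
  expect_true(all(W[cbind(1:12, apply(d, 1, which.min))] ==
                  apply(W, 1, max)))
})

test_that("DMAS pair-sum identity matches the brute-force double loop", {
  set.seed(7)
  for (rep in 1:20) {
    a <- rnorm(16)
    brute <- 0
    for (i in 1:15) for (j in (i + 1):16) brute <- brute + a[i] * a[j]
    expect_equal((sum(a)^2 - sum(a^2)) / 2, brute, tolerance = 1e-12)
  }
})

test_that("beamformer kernels match the naive reference implementation", {
  set.seed(8)
  M <- 4; Tn <- 300; P <- 60; W <- 12
  sig <- matrix(rnorm(M * Tn), M, Tn)
  start <- matrix(sample(0:(Tn - W - 1), P * M, replace = TRUE), P, M)
  wt <- matrix(runif(P * M, 0.5, 1.5), P, M)
  ch <- make_channels(sig, 1e-12, data.frame(x = 1:M, depth = 0))
  for (dm in c(FALSE, TRUE)) {
    ref <- naive_beamform(sig, start, wt, W, dm)
    got <- beamform_core_cpp(t(sig), start * 1.0, wt, W, dm, FALSE)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("all four beamformers localize an analytic point target", {
  ants <- data.frame(x = seq(10, 50, length.out = 8), depth = 0)
  target <- c(31, 17)
  spd <- 1.5e8
  ch <- point_target_channels(target, ants, speed = spd)
  g <- structure(list(depth = seq(5, 30, by = 0.5),
                      lateral = seq(15, 45, by = 0.5), pitch = 0.5),
                 class = "imaging_grid")
  dl <- compute_delays(g, ants, spd)
  wts <- rank_weights(dl$dist)
  # the peak-centered window is the unbiased matched choice for a point echo
  maps <- list(DAS = das(ch, dl, align = "centered"),
               DMAS = dmas(ch, dl, align = "centered"),
               `CR-DAS` = das(ch, dl, wts, align = "centered"),
               `CR-DMAS` = dmas(ch, dl, wts, align = "centered"))
  off_peak_mean <- numeric(0)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    ij <- arrayInd(which.max(m$energy), dim(m$energy))
    pk <- c(m$lateral[ij[2]], m$depth[ij[1]])
    expect_lt(sqrt(sum((pk - target)^2)), sqrt(2) * m$pitch + 1e-9,
              label = paste(nm, "peak distance"))
    e <- m$energy / max(m$energy)
    e[ij[1], ij[2]] <- NA
    off_peak_mean[nm] <- mean(e, na.rm = TRUE)
  }
  # pair multiplication rejects clutter: DMAS-family maps are cleaner
  expect_lt(off_peak_mean["DMAS"], off_peak_mean["DAS"])
  expect_lt(off_peak_mean["CR-DMAS"], off_peak_mean["CR-DAS"])
})

test_that("beamformers are homogeneous and CR reduces to plain with flat weights", {
  ants <- data.frame(x = c(10, 20, 30), depth = 0)
  ch <- point_target_channels(c(20, 12), ants)
  g <- structure(list(depth = seq(8, 16, by = 0.5),
                      lateral = seq(16, 24, by = 0.5), pitch = 0.5),
                 class = "imaging_grid")
  dl <- compute_delays(g, ants, 1.5e8)
  m1 <- dmas(ch, dl)
  flat <- matrix(1, nrow(dl$delay), 3)
  expect_identical(dmas(ch, dl, flat)$energy, m1$energy)
  ch2 <- ch; ch2$signals <- 2 * ch2$signals
  expect_equal(das(ch2, dl)$energy, 4 * das(ch, dl)$energy, tolerance = 1e-12)
  # DMAS is quartic in the signals
  expect_equal(dmas(ch2, dl)$energy, 16 * m1$energy, tolerance = 1e-12)
  expect_error(dmas(make_channels(matrix(1, 1, 50), 1e-12,
                                  data.frame(x = 0, depth = 0)), dl), "M >= 2")
})

test_that("reconstruct dispatches methods case-insensitively and deterministically", {
  ph <- build_phantom(tiny_config())
  ch <- run_monostatic(ph, sim = tiny_sim())
  cl <- average_subtraction(ch)
  m1 <- reconstruct(cl, ph, "cr-dmas")
  m2 <- reconstruct(cl, ph, "CR-DMAS")
  expect_identical(m1$energy, m2$energy)
  expect_equal(m1$method, "CR-DMAS")
  expect_error(reconstruct(cl, ph, "MUSIC"), "unknown beamformer")
  expect_true(all(is.finite(m1$energy)) && all(m1$energy >= 0))
})
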
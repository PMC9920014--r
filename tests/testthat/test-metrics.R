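blob_truth <- function(center, map, radius = 2) {
  nd <- nrow(map$energy); nl <- ncol(map$energy)
  mask <- matrix(FALSE, nd, nl)
  for (j in seq_len(nl)) for (i in seq_len(nd))
    if ((map$lateral[j] - center[1])^2 + (map$depth[i] - center[2])^2 <= radius^2)
      mask[i, j] <- TRUE
  target_truth(center, mask, origin = c(map$lateral[1] - map$pitch,
                                        map$depth[1] - map$pitch),
               dx = map$pitch)
}

gauss_map <- function(center, sigma, n = 80, pitch = 0.5, amp = 1) {
  e <- matrix(0, n, n)
  m <- make_map(e, pitch)
  for (j in seq_len(n)) for (i in seq_len(n)) {
    r2 <- (m$lateral[j] - center[1])^2 + (m$depth[i] - center[2])^2
    e[i, j] <- amp * exp(-r2 / (2 * sigma^2))
  }
  m$energy <- e
  m
}

test_that("SCR compares the target peak against the strongest clutter", {
  m <- make_map(matrix(1e-9, 60, 60))
  tr <- blob_truth(c(15, 15), m)
  m$energy[30, 30] <- 1e-9        # inside target region? no: (15,15) in mm
  # single hot pixel inside the target, clutter at epsilon
  ij <- c(which.min(abs(m$depth - 15)), which.min(abs(m$lateral - 15)))
  m$energy[ij[1], ij[2]] <- 2e-9
  expect_equal(scr(m, tr), 10 * log10(2), tolerance = 1e-9)
  # flat map: 0 dB
  expect_equal(scr(make_map(matrix(1, 60, 60)), tr), 0)
})

test_that("SMR uses the mean clutter energy and dominates SCR", {
  m <- make_map(matrix(1, 40, 40))
  tr <- blob_truth(c(10, 10), m)
  ij <- c(which.min(abs(m$depth - 10)), which.min(abs(m$lateral - 10)))
  m$energy[ij[1], ij[2]] <- 100
  expect_equal(smr(m, tr), 20, tolerance = 1e-9)
  expect_equal(smr(make_map(matrix(3, 40, 40)), tr), 0)
  set.seed(9)
  m$energy <- matrix(runif(1600), 40, 40)
  expect_gte(smr(m, tr), scr(m, tr))
})

test_that("MMR contrasts the two target peaks and is antisymmetric", {
  m <- make_map(matrix(1e-6, 60, 60))
  ta <- blob_truth(c(10, 15), m)
  tb <- blob_truth(c(25, 15), m)
  ia <- c(which.min(abs(m$depth - 15)), which.min(abs(m$lateral - 10)))
  ib <- c(which.min(abs(m$depth - 15)), which.min(abs(m$lateral - 25)))
  m$energy[ia[1], ia[2]] <- 10
  m$energy[ib[1], ib[2]] <- 1
  expect_equal(mmr(m, ta, tb), 10, tolerance = 1e-9)
  expect_equal(mmr(m, tb, ta), -mmr(m, ta, tb))
  m$energy[ib[1], ib[2]] <- 10
  expect_equal(mmr(m, ta, tb), 0)
  expect_error(mmr(m, ta, blob_truth(c(11, 15), m)), "overlap")
})

test_that("FWHM of a Gaussian blob matches the closed form", {
  sigma <- 3
  m <- gauss_map(c(20, 20), sigma)
  expect_equal(fwhm(m, c(20, 20)), 2 * sigma * sqrt(2 * log(2)),
               tolerance = m$pitch / (2 * sigma * sqrt(2 * log(2))))
  # amplitude invariance
  m2 <- gauss_map(c(20, 20), sigma, amp = 7)
  expect_equal(fwhm(m2, c(20, 20)), fwhm(m, c(20, 20)))
  # single-pixel spike: width bounded by two pixels
  sp <- make_map(matrix(0, 40, 40))
  sp$energy[20, 20] <- 1
  expect_lte(fwhm(sp, c(sp$lateral[20], sp$depth[20])), 2 * sp$pitch)
  # never-crossing half level warns and truncates
  expect_warning(fwhm(make_map(matrix(1, 20, 20) + 1e-9 * diag(20)),
                      c(5, 5)), "truncated")
})

test_that("localization error is the peak-to-center distance", {
  m <- make_map(matrix(0, 40, 40))
  tr <- blob_truth(c(10, 10), m)
  ij <- c(which.min(abs(m$depth - 10)), which.min(abs(m$lateral - 10)))
  m$energy[ij[1], ij[2]] <- 1
  expect_equal(localization_error(m, tr), 0)
  m$energy[ij[1], ij[2]] <- 0
  m$energy[ij[1], ij[2] + 1] <- 1          # one pixel lateral
  expect_equal(localization_error(m, tr), 0.5)
  m$energy <- m$energy * 1e6               # scale invariance
  expect_equal(localization_error(m, tr), 0.5)
  expect_error(localization_error(m, tr, search = matrix(FALSE, 40, 40)),
               "empty")
})

test_that("find_map_peaks separates two blobs and flags merged ridges", {
  m1 <- gauss_map(c(12, 20), 2)
  m2 <- gauss_map(c(28, 20), 2)
  m <- m1; m$energy <- m1$energy + 0.8 * m2$energy
  pk <- find_map_peaks(m, 2, min_separation = 8)
  expect_equal(nrow(pk), 2)
  expect_false(attr(pk, "incomplete"))
  ord <- order(pk$x)
  expect_lt(abs(pk$x[ord[1]] - 12) + abs(pk$d[ord[1]] - 20), 1)
  expect_lt(abs(pk$x[ord[2]] - 28) + abs(pk$d[ord[2]] - 20), 1)
  # n = 1 returns the global maximum
  pk1 <- find_map_peaks(m, 1)
  expect_equal(c(pk1$x, pk1$d), c(12, 20), tolerance = 0.5)
  # merged ridge: only one peak, flagged incomplete
  mm <- gauss_map(c(19, 20), 6); mm2 <- gauss_map(c(21, 20), 6)
  mm$energy <- mm$energy + mm2$energy
  pkm <- find_map_peaks(mm, 2, min_separation = 8)
  expect_lt(nrow(pkm), 2)
  expect_true(attr(pkm, "incomplete"))
})

test_that("all metrics are invariant to global map scaling", {
  set.seed(10)
  m <- gauss_map(c(20, 18), 3)
  m$energy <- m$energy + 0.01 * matrix(runif(80 * 80), 80, 80)
  tr <- blob_truth(c(20, 18), m)
  for (alpha in c(1e-6, 1, 1e6)) {
    ms <- m; ms$energy <- alpha * m$energy
    expect_equal(scr(ms, tr), scr(m, tr), tolerance = 1e-9)
    expect_equal(smr(ms, tr), smr(m, tr), tolerance = 1e-9)
    expect_equal(fwhm(ms, c(20, 18)), fwhm(m, c(20, 18)), tolerance = 1e-9)
    expect_equal(localization_error(ms, tr), localization_error(m, tr))
  }
})

test_that("detection_report summarizes single and double targets", {
  m <- gauss_map(c(15, 20), 2)
  tr <- blob_truth(c(15, 20), m)
  rep1 <- detection_report(m, list(tr))
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$le_mm, 0, tolerance = 0.5)
  expect_true(is.na(rep1$mmr_db))
  m2 <- gauss_map(c(30, 20), 2)
  m$energy <- m$energy + 0.5 * m2$energy
  trb <- blob_truth(c(30, 20), m)
  trb$status <- "healthy"
  rep2 <- detection_report(m, list(tr, trb))
  expect_equal(nrow(rep2), 2)
  expect_equal(rep2$mmr_db[1], 10 * log10(2), tolerance = 0.2)
  expect_lt(max(rep2$le_mm), 1)
})
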
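test_that("default phantom has a 2-mm skin band at the top of the region", {
  ph <- build_phantom(phantom_config())
  skin_rows <- which(ph$depth >= 0 & ph$depth < 2)
  expect_true(all(ph$tissue[skin_rows, ] == 1L))
  # band conservation: skin cell count = thickness/dx * width cells
  expect_equal(sum(ph$tissue == 1L), round(2 / 0.5) * ncol(ph$tissue))
  # nothing above the surface but air
  expect_true(all(ph$tissue[ph$depth < 0, ] == 0L))
})

test_that("muscle band occupies depths [37, 62) outside the ALN", {
  ph <- build_phantom(phantom_config(muscle = TRUE,
                                     alns = list(aln(depth = 20))))
  rows <- which(ph$depth >= 37 & ph$depth < 62)
  expect_true(all(ph$tissue[rows, ] == 3L))
  expect_equal(sum(ph$tissue == 3L), round(25 / 0.5) * ncol(ph$tissue))
})

test_that("an ALN on the muscle surface overrides the muscle cells", {
  ph <- build_phantom(phantom_config(muscle = TRUE,
                                     alns = list(aln(depth = 37))))
  expect_gt(sum(ph$tissue %in% c(7L, 8L)), 0)
  inside <- ph$truth[[1]]$mask
  expect_false(any(ph$tissue[inside] == 3L))
})

test_that("a phantom without ALNs has empty ground truth", {
  ph <- build_phantom(phantom_config(alns = list()))
  expect_length(ph$truth, 0)
  expect_true(all(ph$tissue %in% c(0L, 1L, 4L)))
})

test_that("out-of-domain or skin-touching ALNs are rejected", {
  expect_error(phantom_config(alns = list(aln(depth = 98))), "below the domain")
  expect_error(phantom_config(alns = list(aln(depth = 5))), "skin")
  expect_error(phantom_config(alns = list(aln(depth = 20, offset = 58))),
               "leaves the domain")
  expect_error(build_phantom(phantom_config(alns = list(
    aln(depth = 20, offset = -3), aln(depth = 20, offset = 3)))), "overlap")
})

test_that("bean mask has the requested long axis and a surface ring", {
  m <- bean_mask(c(30, 20), long_axis = 12, orientation = 0, dx = 0.5)
  idx <- which(m > 0, arr.ind = TRUE)
  lat_extent <- diff(range(idx[, 2]) + c(-0.5, 0.5)) * 0.5
  expect_equal(lat_extent, 12, tolerance = 0.5 / 12)
  expect_true(any(m == 1L))  # interior
  expect_true(any(m == 2L))  # ring
  # the ring surrounds the interior: every boundary cell of the bean is ring
  expect_error(bean_mask(c(30, 20), long_axis = 0.8, dx = 0.5), "degenerate")
})

test_that("rotating the bean by pi point-reflects the mask about the center", {
  dim <- c(100, 100); org <- c(0, 0)
  m0 <- bean_mask(c(25, 25), 12, 0, 0.5, dim = dim, origin = org)
  m1 <- bean_mask(c(25, 25), 12, pi, 0.5, dim = dim, origin = org)
  # point reflection about the center (cell 50.5, 50.5 in index space)
  flipped <- (m1 > 0)[rev(seq_len(100)), rev(seq_len(100))]
  agree <- sum((m0 > 0) == flipped)
  expect_gt(agree / length(m0), 0.999)  # rasterization can differ at edges
})

test_that("bean mask area matches the analytic curve area", {
  # 1/2 integral of r^2 over the closed branch, scaled to a 12-mm long axis,
  # evaluated with fine quadrature: 58.32 mm^2
  m <- bean_mask(c(30, 30), 12, 0.7, dx = 0.25)
  expect_equal(sum(m > 0) * 0.25^2, 58.32, tolerance = 0.03)
})

test_that("ALN centroid coincides with the declared center within dx", {
  ph <- build_phantom(phantom_config())
  t <- ph$truth[[1]]
  idx <- which(t$mask, arr.ind = TRUE)
  centroid <- c(mean(ph$lateral[idx[, 2]]), mean(ph$depth[idx[, 1]]))
  expect_lt(sqrt(sum((centroid - t$center)^2)), ph$dx)
})

test_that("heterogeneity scales tiles jointly, deterministically, labels intact", {
  cfg <- phantom_config(het_amplitude = 0)
  ph0 <- build_phantom(cfg)
  ph1 <- apply_heterogeneity(ph0, 0.05, 4, seed = 7)
  ph2 <- apply_heterogeneity(ph0, 0.05, 4, seed = 7)
  expect_identical(ph1$eps_inf, ph2$eps_inf)          # same seed, bit identical
  expect_identical(ph1$tissue, ph0$tissue)            # labels unchanged
  expect_identical(ph1$tau, ph0$tau)                  # tau untouched
  expect_identical(apply_heterogeneity(ph0, 0, 4, 1), ph0)  # amplitude 0
  fac <- ph1$eps_inf / ph0$eps_inf
  bg <- ph0$tissue == 4L
  expect_true(all(fac[bg] >= 0.95 & fac[bg] <= 1.05))
  expect_true(all(fac[!bg] == 1))
  # all three magnitudes share one factor per cell
  expect_equal((ph1$delta_eps / ph0$delta_eps)[bg], fac[bg], tolerance = 1e-12)
  expect_equal((ph1$sigma_s / ph0$sigma_s)[bg], fac[bg], tolerance = 1e-12)
  # cells within one 4-mm tile share a single factor
  rows <- which(ph0$depth >= 24, arr.ind = TRUE)[1] + 0:7
  cols <- which(ph0$lateral >= 24)[1] + 0:7
  expect_length(unique(round(as.vector(fac[rows, cols]), 12)), 1)
})

test_that("heterogeneity does not touch a different RNG stream", {
  set.seed(42); before <- runif(3)
  set.seed(42); invisible(build_phantom(phantom_config())); after <- runif(3)
  expect_identical(before, after)
})

test_that("antennas are equally spaced on the skin surface", {
  ph <- build_phantom(phantom_config())
  a <- ph$antennas
  expect_equal(nrow(a), 16)
  expect_equal(diff(a$x), rep(80 / 15, 15), tolerance = 1e-12)
  expect_true(all(a$depth == 0))                      # uniform skin: surface
  expect_equal(mean(a$x), 60)                         # centered
  a2 <- antenna_positions(2, 80, ph)
  expect_equal(a2$x, c(20, 100))
  # antennas sit in the air cell immediately above the skin
  expect_true(all(ph$tissue[cbind(a$i, a$j)] == 0L))
  expect_true(all(ph$tissue[cbind(a$i + 1L, a$j)] == 1L))
  expect_error(antenna_positions(8, 500, ph), "span")
})

test_that("planar placement on sinusoidal skin leaves varying air gaps", {
  ph <- build_phantom(phantom_config(skin_profile = "sinusoidal",
                                     antenna_placement = "planar"))
  a <- ph$antennas
  expect_length(unique(a$depth), 1)                   # rigid plane
  eta_a <- ph$eta[a$j]
  gaps <- eta_a - a$depth[1]
  expect_gt(max(gaps) - min(gaps), 1)                 # gaps vary by > 1 mm
  ph2 <- build_phantom(phantom_config(skin_profile = "sinusoidal"))
  expect_gt(length(unique(ph2$antennas$depth)), 1)    # surface placement follows
})
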
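test_that("sector asymmetry: symmetry, extremes and an exhaustive sweep oracle", {
  set.seed(31)
  # rotationally symmetric points: index near 0
  th <- runif(4000, 0, 2 * pi); r <- sqrt(runif(4000))
  pts <- cbind(r * cos(th), r * sin(th))
  expect_lt(sector_asymmetry(pts, c(0, 0), 1)$index, 0.05)
  # all intensity in one quadrant: index near 1
  thq <- runif(300, 0, pi / 2)
  ptsq <- cbind(sqrt(runif(300)) * cos(thq), sqrt(runif(300)) * sin(thq))
  expect_gt(sector_asymmetry(ptsq, c(0, 0), 1)$index, 0.9)
  # random pattern equals a brute-force sweep oracle exactly
  pts2 <- cbind(runif(120, -1, 1), runif(120, -1, 1))
  got <- sector_asymmetry(pts2, c(0, 0), 1, step = 5)
  ang <- (atan2(pts2[, 2], pts2[, 1]) * 180 / pi) %% 360
  keep <- rowSums(pts2^2) <= 1
  starts <- seq(0, 355, by = 5)
  cnt <- vapply(starts, function(a)
    sum(keep & ((ang - a) %% 360) < 90), 0)
  imax <- which.max(cnt)
  iopp <- cnt[match((starts[imax] + 180) %% 360, starts)]
  expect_identical(got$index, (cnt[imax] - iopp) / (cnt[imax] + iopp))
  expect_identical(got$max_sector_angle, starts[imax])
  # empty disc flagged
  expect_identical(sector_asymmetry(pts2, c(50, 50), 1)$flag, "empty")
})

test_that("sector asymmetry is rotation-equivariant", {
  set.seed(32)
  # clearly asymmetric: a dense 60-degree wedge plus sparse background
  th <- c(runif(300, 0.2, 0.2 + pi / 3), runif(60, 0, 2 * pi))
  r <- sqrt(runif(360))
  pts <- cbind(r * cos(th), r * sin(th))
  a0 <- sector_asymmetry(pts, c(0, 0), 2, step = 1)
  phi <- 73 * pi / 180
  # counter-clockwise rotation of row-vector points by phi
  rot <- pts %*% matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2)
  a1 <- sector_asymmetry(rot, c(0, 0), 2, step = 1)
  expect_equal(a1$index, a0$index, tolerance = 1e-9)
  dd <- (a1$max_sector_angle - a0$max_sector_angle - 73) %% 360
  expect_true(min(dd, 360 - dd) <= 1)
})

test_that("quadrant distribution: arithmetic, extremes, and expectation", {
  # explicit counts 50/30/10/10
  mk_quad <- function(n, lo) {
    th <- runif(n, lo, lo + 89.9) * pi / 180
    cbind(cos(th), sin(th))
  }
  set.seed(33)
  pts <- rbind(mk_quad(50, 90), mk_quad(30, 180), mk_quad(10, 270),
               mk_quad(10, 0))   # relative to dorsal at 90 deg
  qd <- quadrant_distribution(pts, c(0, 0), dorsal_angle = 90)
  expect_equal(sum(qd$percentages), 100, tolerance = 1e-9)
  expect_equal(unname(qd$percentages), c(50, 30, 10, 10))
  # all points in one quadrant: 100% and densest window overlapping it
  r1 <- simulate_retina(weights = c(0, 0, 1, 0), n_cells = 80, seed = 5)
  q1 <- quadrant_distribution(r1$points, r1$disc_centre,
                              dorsal_angle = r1$dorsal_angle,
                              retina_area = r1$retina_area)
  expect_equal(unname(q1$percentages[["ventrotemporal"]]), 100)
  expect_equal(q1$densest_window_count, 80)
  # uniform weights: mean percentage 25% over seeded draws
  set.seed(34)
  pcts <- replicate(200, {
    r <- simulate_retina(n_cells = 100, seed = sample.int(1e6, 1))
    quadrant_distribution(r$points, r$disc_centre,
                          dorsal_angle = r$dorsal_angle)$percentages
  })
  expect_true(all(abs(rowMeans(pcts) - 25) < 2))
  expect_error(quadrant_distribution(pts[0, , drop = FALSE], c(0, 0)),
               "no labelled")
})

test_that("colocalization: identity channels, signal, and exclusions", {
  v <- simulate_volume(coloc_fraction = 0.4, seed = 11)
  ident <- two_channel_stack(v$stack$label, v$stack$label, c(5, 5, 5))
  ct <- colocalization_test(ident)
  expect_true(all(ct$subfields$original == 1))
  expect_equal(ct$mean_original, 1)
  # strong off-axis colocalization beats the rotation null
  v2 <- simulate_volume(coloc_fraction = 0.9, marker_density = 0.02,
                        seed = 12)
  ct2 <- colocalization_test(v2$stack)
  expect_gt(ct2$mean_original, 3 * ct2$mean_rotated)
  expect_lt(ct2$p, 0.05)
  # too-small stack flagged
  tiny <- simulate_volume(dims = c(14, 14, 8), n_puncta = 100, seed = 13)
  expect_warning(ct3 <- colocalization_test(tiny$stack), "subfields")
  expect_true(is.na(ct3$p))
})

test_that("colocalization fractions are invariant to a joint rigid transform", {
  # square-in-xy stack so a whole-volume 90-degree rotation is lossless
  v <- simulate_volume(dims = c(56, 56, 8), coloc_fraction = 0.5, seed = 14)
  ct <- colocalization_test(v$stack)
  rot_all <- function(a) {
    out <- array(0, dim(a))
    for (z in seq_len(dim(a)[3])) out[, , z] <- hypovis:::rot90_mat(a[, , z])
    out
  }
  st2 <- two_channel_stack(rot_all(v$stack$label), rot_all(v$stack$marker),
                           c(5, 5, 5))
  ct2 <- colocalization_test(st2)
  expect_equal(sort(ct2$subfields$original), sort(ct$subfields$original),
               tolerance = 1e-12)
})

test_that("label density: counts, boundary rule and a point-in-polygon oracle", {
  sq <- data.frame(x_mm = c(0, 1, 1, 0), y_mm = c(0, 0, 1, 1))
  pts <- data.frame(x_mm = runif(10), y_mm = runif(10))
  d <- label_density(pts, list(roi = sq))
  expect_equal(d$density, 10)
  expect_equal(d$area_mm2, 1)
  # half-open rule: left/bottom boundary inside, right/top outside
  bpts <- data.frame(x_mm = c(0, 1, 0.5, 0.5), y_mm = c(0.5, 0.5, 0, 1))
  db <- label_density(bpts, list(roi = sq))
  expect_equal(db$total_count, 2)
  expect_error(label_density(pts, list(bad = sq[c(1, 1, 1), ])), "zero-area")
  # interior points agree with the mgcv point-in-polygon oracle
  skip_if_not_installed("mgcv")
  set.seed(35)
  poly <- data.frame(x_mm = c(0, 2, 2.5, 1, -0.5), y_mm = c(0, -0.5, 1.5, 2.2, 1))
  qq <- data.frame(x_mm = runif(400, -1, 3), y_mm = runif(400, -1, 3))
  mine <- hypovis:::point_in_polygon(qq$x_mm, qq$y_mm, poly)
  oracle <- mgcv::in.out(as.matrix(rbind(poly, poly[1, ])),
                         as.matrix(qq))
  expect_equal(mine, as.logical(oracle))
})

test_that("two-channel TIFF stacks round-trip through the reader", {
  v <- simulate_volume(dims = c(16, 16, 4), n_puncta = 100, seed = 15)
  f1 <- tempfile(fileext = ".tif"); f2 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(seq_len(4), function(z) v$stack$label[, , z]), f1,
                  bits.per.sample = 16)
  tiff::writeTIFF(lapply(seq_len(4), function(z) v$stack$marker[, , z]), f2,
                  bits.per.sample = 16)
  st <- read_two_channel_tiff(f1, f2, c(5, 5, 5))
  expect_equal(dim(st$label), c(16, 16, 4))
  expect_lt(max(abs(st$label - v$stack$label)), 1e-4)
})
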
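# Fluorescence quantification: projection, ratios, thresholding,
# colocalization and puncta counting.

test_that("maximum projection is the pixel-wise max over z", {
  a <- array(runif(4 * 5 * 3), c(4, 5, 3))
  pr <- max_project(a)
  for (z in 1:3) expect_true(all(pr >= a[, , z]))
  expect_equal(pr, pmax(a[, , 1], a[, , 2], a[, , 3]))
  # single plane is the identity; an all-zero plane never wins
  expect_identical(max_project(a[, , 1]), a[, , 1])
  b <- array(0, c(4, 5, 2)); b[, , 2] <- a[, , 1]
  expect_equal(max_project(b), a[, , 1])
})

test_that("surface-to-intracellular ratio with exact background subtraction", {
  img <- matrix(50, 20, 20)
  roi <- matrix(FALSE, 20, 20); roi[5:15, 5:15] <- TRUE
  expect_equal(surface_ratio(img, img, roi, 0, 0), 1.0)
  expect_equal(surface_ratio(2 * img, img, roi, 0, 0), 2.0)
  # gain invariance
  r1 <- surface_ratio(2 * img, img, roi, 0, 0)
  r2 <- surface_ratio(2 * img * 3.7, img * 3.7, roi, 0, 0)
  expect_equal(r1, r2)
  # non-positive denominator is flagged, not an error
  expect_warning(r3 <- surface_ratio(img, matrix(1, 20, 20), roi,
                                     0, 10), "excluded")
  expect_true(is.na(r3))
  expect_identical(attr(r3, "flag"), "nonpositive_denominator")
})

test_that("synthetic HEK image returns its planted ratio", {
  g <- gen_hek_image(0.7, cell_count = 3, noise_sd = 0, seed = 5)
  st <- g$stack
  r <- surface_ratio(st$channels$surface, st$channels$intracellular,
                     st$rois$cell01, background_roi = st$rois$background)
  expect_equal(r, 0.7, tolerance = 0.7 * 0.01)
  # with noise and a gradient, still within 5 %
  g2 <- gen_hek_image(0.7, noise_sd = 1.5, seed = 6)
  st2 <- g2$stack
  r2 <- surface_ratio(st2$channels$surface, st2$channels$intracellular,
                      st2$rois$cell01,
                      background_roi = st2$rois$background)
  expect_equal(r2, 0.7, tolerance = 0.7 * 0.05)
})

test_that("colorimetric arithmetic averages replicates before the ratio", {
  expect_equal(colorimetric_ratio(0.4, 0.8, 0.2), 0.5)
  expect_equal(colorimetric_ratio(0.2, 0.9, 0.2), 0)   # surface == background
  expect_warning(rr <- colorimetric_ratio(0.95, 0.9, 0.2), "not positive")
  expect_true(is.na(rr))
  # with unequal replicates the mean-then-ratio differs from ratio means:
  s <- c(0.3, 0.6); tt <- c(0.8, 1.0); b <- c(0.1, 0.1)
  pooled <- colorimetric_ratio(s, tt, b)
  per_rep <- mean(mapply(colorimetric_ratio, s, tt, b))
  expect_equal(pooled,
               (mean(s) - mean(b)) / ((mean(tt) - mean(b)) - (mean(s) - mean(b))))
  expect_false(isTRUE(all.equal(pooled, per_rep)))
})

test_that("adaptive thresholding tracks uneven illumination where Otsu fails", {
  expect_equal(sum(adaptive_threshold(matrix(7, 60, 60), 11, offset = 1)), 0)
  one <- matrix(0, 60, 60); one[30, 30] <- 10
  expect_true(adaptive_threshold(one, 11, offset = 1)[30, 30])
  expect_error(adaptive_threshold(matrix(0, 10, 10), 11), "exceeds")
  expect_error(adaptive_threshold(matrix(0, 30, 30), 10), "odd")

  # gradient-lit field with dim puncta: adaptive recovers all, a global
  # Otsu threshold misses at least one
  set.seed(3)
  img <- matrix(rep(seq(0, 100, length.out = 120), each = 60), 60, 120)
  centers <- cbind(r = seq(10, 50, length.out = 5),
                   c = seq(10, 110, length.out = 5))
  for (i in 1:5) {
    rr <- centers[i, 1] + (-1:1); cc <- centers[i, 2] + (-1:1)
    img[rr, cc] <- img[rr, cc] + 30
  }
  m_ad <- adaptive_threshold(img, 15, offset = 10)
  hit_ad <- vapply(1:5, function(i)
    any(m_ad[centers[i, 1] + (-1:1), centers[i, 2] + (-1:1)]), logical(1))
  expect_true(all(hit_ad))
  thr <- EBImage::otsu(img / max(img)) * max(img)
  m_otsu <- img > thr
  hit_otsu <- vapply(1:5, function(i)
    any(m_otsu[centers[i, 1] + (-1:1), centers[i, 2] + (-1:1)]), logical(1))
  expect_true(sum(hit_otsu) < 5)
})

test_that("percent overlap is directional and bounded", {
  a <- matrix(FALSE, 8, 8); a[2:3, 2:6] <- TRUE      # 10 px
  b <- matrix(FALSE, 8, 8); b[2:3, 2:3] <- TRUE; b[6:8, 6:8] <- TRUE
  expect_equal(percent_overlap(a, a), 100)
  expect_equal(percent_overlap(a, !a), 0)
  expect_equal(as.numeric(percent_overlap(a, b)), 100 * 4 / 10)
  # asymmetric by construction
  expect_false(isTRUE(all.equal(as.numeric(percent_overlap(a, b)),
                                as.numeric(percent_overlap(b, a)))))
  expect_warning(z <- percent_overlap(matrix(FALSE, 8, 8), b), "empty")
  expect_equal(as.numeric(z), 0)
  expect_error(percent_overlap(a, matrix(TRUE, 3, 3)), "shapes")
})

test_that("puncta are counted with 8-connectivity and an area floor", {
  expect_equal(count_puncta(matrix(FALSE, 10, 10)), 0L)
  m <- matrix(FALSE, 20, 20)
  m[2:4, 2:4] <- TRUE; m[2:4, 10:12] <- TRUE; m[12:14, 12:14] <- TRUE
  expect_equal(count_puncta(m, min_area_px = 4), 3L)
  expect_equal(count_puncta(m, min_area_px = 10), 0L)
  # two squares touching only at a corner merge under 8-connectivity;
  # oracle: EBImage::bwlabel (4-connectivity) keeps them apart
  d <- matrix(FALSE, 12, 12); d[2:4, 2:4] <- TRUE; d[5:7, 5:7] <- TRUE
  expect_equal(count_puncta(d, min_area_px = 4), 1L)
  expect_equal(max(EBImage::bwlabel(d)), 2)
})

test_that("image stacks survive a TIFF round trip", {
  g <- gen_dendrite_image(seed = 4)
  dir <- withr::local_tempdir()
  write_image_stack(g$stack, dir)
  rt <- read_image_stack(
    c(surface = file.path(dir, "surface.tif"),
      psd95 = file.path(dir, "psd95.tif")),
    pixel_size = g$stack$pixel_size)
  # stored scaled to [0,1]; shape and relative structure preserved
  expect_equal(dim(rt$channels$surface), dim(g$stack$channels$surface))
  s0 <- g$stack$channels$surface / max(g$stack$channels$surface)
  expect_equal(max(abs(rt$channels$surface - s0)), 0, tolerance = 1e-6)
})
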
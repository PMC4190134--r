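test_that("alternate sequential filter: identity, flat invariance, speck removal", {
  set.seed(11)
  img <- matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24)
  expect_identical(alternate_sequential_filter(img, 0), img)
  flat <- matrix(120, 16, 16)
  expect_equal(alternate_sequential_filter(flat, 3), flat)
  expect_error(alternate_sequential_filter(img, -1), "order")

  speck <- matrix(10, 15, 15)
  speck[8, 8] <- 200
  got <- alternate_sequential_filter(speck, 1)
  # oracle: closing-then-opening with the radius-1 disk by brute force
  k <- se_disk(1)
  oracle <- bf_dilate(bf_erode(bf_erode(bf_dilate(speck, k), k), k), k)
  expect_equal(got, oracle)
  expect_equal(got[8, 8], 10)
})

test_that("opening <= identity <= closing and ASF is increasing", {
  set.seed(12)
  for (i in 1:3) {
    img <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20, 20)
    k <- se_disk(sample(1:2, 1))
    expect_true(all(endoseg:::mm_open(img, k) <= img + 1e-9))
    expect_true(all(endoseg:::mm_close(img, k) >= img - 1e-9))

    lo <- img
    hi <- img + matrix(sample(0:30, length(img), replace = TRUE), nrow(img))
    expect_true(all(alternate_sequential_filter(lo, 2) <=
                      alternate_sequential_filter(hi, 2) + 1e-9))
  }
})

test_that("grayscale erosion/dilation agree with the brute-force window filter", {
  set.seed(13)
  img <- matrix(sample(0:255, 18 * 18, replace = TRUE), 18, 18)
  for (k in list(se_disk(1), se_disk(2), se_segment(5, 0), se_segment(5, 45))) {
    expect_equal(endoseg:::mm_erode(img, k), bf_erode(img, k))
    expect_equal(endoseg:::mm_dilate(img, k), bf_dilate(img, k))
  }
})

test_that("h-maxima markers keep only peaks of sufficient prominence", {
  img <- matrix(0, 20, 20)
  img[5:7, 5:7] <- 10     # prominence 10
  img[14:16, 14:16] <- 3  # prominence 3
  mk <- h_maxima_markers(img, 5)
  expect_true(all(mk[5:7, 5:7]))
  expect_false(any(mk[14:16, 14:16]))
  # oracle: reconstruction by iterated geodesic dilation
  rec <- bf_reconstruct(img - 5, img)
  expect_equal(endoseg:::cpp_reconstruct_dilate(img - 5, img), rec)

  # h = 0: plain regional maxima
  set.seed(14)
  r <- matrix(sample(0:50, 15 * 15, replace = TRUE), 15, 15)
  expect_identical(h_maxima_markers(r, 0), regional_maxima(r))

  # single plateau maximum, h below its prominence: one connected marker
  plateau <- matrix(1, 12, 12)
  plateau[4:6, 4:8] <- 9
  mk2 <- h_maxima_markers(plateau, 5)
  expect_equal(max(label_components(mk2)), 1)
  expect_true(all(which(mk2) %in% which(plateau == 9)))
})

test_that("reconstruction matches the iterative oracle on random images", {
  set.seed(15)
  for (i in 1:5) {
    mask <- matrix(sample(0:40, 12 * 12, replace = TRUE), 12, 12)
    marker <- pmax(mask - sample(1:10, 1), 0)
    expect_equal(endoseg:::cpp_reconstruct_dilate(marker, mask),
                 bf_reconstruct(marker, mask))
  }
})

test_that("top-hat extracts thin dark structures and is nonnegative", {
  flat <- matrix(77, 14, 14)
  expect_equal(top_hat(flat, 2), matrix(0, 14, 14))
  expect_equal(top_hat(flat, 2, dark = FALSE), matrix(0, 14, 14))

  line <- matrix(200, 15, 15)
  line[8, ] <- 40
  th <- top_hat(line, 2, dark = TRUE)
  oracle <- bf_erode(bf_dilate(line, se_disk(2)), se_disk(2)) - line
  expect_equal(th, oracle)
  expect_true(all(th[8, ] > 100))
  expect_true(all(th >= 0))

  set.seed(16)
  rnd <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  expect_true(all(top_hat(rnd, 1) >= -1e-9))
  expect_true(all(top_hat(rnd, 1, dark = FALSE) >= -1e-9))
})

test_that("distance map is the exact Euclidean distance to the set", {
  b <- matrix(FALSE, 9, 9)
  b[5, 5] <- TRUE
  d <- distance_map(b)
  expect_equal(d[5, 5], 0)
  expect_equal(d[5, 6], 1)
  expect_equal(d[4, 4], sqrt(2))

  set.seed(17)
  for (i in 1:4) {
    m <- random_contour_map(32, 32, p = 0.04)
    expect_equal(distance_map(m), bf_distance_map(m), tolerance = 1e-12)
  }
  expect_error(distance_map(matrix(FALSE, 5, 5)), "empty")
})

test_that("marker-controlled watershed partitions the domain deterministically", {
  relief <- matrix(0, 11, 16)
  mk <- matrix(FALSE, 11, 16)
  mk[6, 4] <- TRUE
  mk[6, 13] <- TRUE
  ws <- watershed_lines(relief, mk)
  expect_setequal(unique(as.vector(ws$labels)), 1:2)
  # on a flat relief regions are the nearest-marker (Voronoi) cells;
  # the interface is the equidistant column between the two markers
  near <- ifelse(abs(col(relief) - 4) <= abs(col(relief) - 13), 1L, 2L)
  expect_gte(mean(ws$labels == near), 0.99)
  expect_true(all(which(ws$lines, arr.ind = TRUE)[, 2] == 9))

  # one marker: one region, no lines
  one <- watershed_lines(relief, mk & (col(mk) == 4))
  expect_equal(unique(as.vector(one$labels)), 1L)
  expect_false(any(one$lines))

  # label count equals connected-component count of the markers
  set.seed(18)
  r2 <- matrix(runif(400), 20, 20)
  mk2 <- matrix(FALSE, 20, 20)
  mk2[cbind(c(3, 10, 17, 5), c(3, 15, 8, 18))] <- TRUE
  ws2 <- watershed_lines(r2, mk2)
  expect_equal(max(ws2$labels), max(label_components(mk2)))
  expect_true(all(ws2$labels >= 1))
  expect_identical(ws2$labels, watershed_lines(r2, mk2)$labels)
  expect_error(watershed_lines(relief, matrix(FALSE, 11, 16)), "marker")
})

test_that("supremum of openings by segments keeps linear bright structures", {
  img <- matrix(0, 15, 15)
  img[8, 3:13] <- 100
  out <- sup_open_segments(img, 7)
  expect_equal(out[8, 5:11], rep(100, 7))

  speck <- matrix(0, 11, 11)
  speck[6, 6] <- 100
  expect_equal(sup_open_segments(speck, 3)[6, 6], 0)
  # oracle for a single orientation
  expect_equal(endoseg:::mm_open(speck, se_segment(3, 0)),
               bf_dilate(bf_erode(speck, se_segment(3, 0)), se_segment(3, 0)))

  set.seed(19)
  rnd <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
  expect_true(all(sup_open_segments(rnd, 5) <= rnd + 1e-9))
})

test_that("skeleton pruning keeps straight arms and drops blobs", {
  line <- matrix(FALSE, 13, 13)
  line[7, 2:12] <- TRUE
  expect_identical(prune_nonlinear_skeleton(line, 7), line)

  blob <- matrix(FALSE, 15, 15)
  blob[7:9, 7:9] <- TRUE
  expect_false(any(prune_nonlinear_skeleton(blob, 9)))

  ell <- matrix(FALSE, 21, 21)
  ell[3:18, 4] <- TRUE
  ell[18, 4:18] <- TRUE
  out <- prune_nonlinear_skeleton(ell, 7)
  # both arms retained away from the corner
  expect_true(all(out[4:12, 4]))
  expect_true(all(out[18, 9:16]))
})
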
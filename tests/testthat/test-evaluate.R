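test_that("symmetric difference follows its set definition", {
  set.seed(21)
  R <- random_contour_map(10, 10, 0.2)
  expect_false(any(symmetric_difference(R, R)))
  empty <- matrix(FALSE, 10, 10)
  expect_identical(symmetric_difference(R, empty), R)

  a <- matrix(FALSE, 3, 3); a[1, 1] <- TRUE
  b <- matrix(FALSE, 3, 3); b[1, 2] <- TRUE
  expect_identical(which(symmetric_difference(a, b)),
                   sort(c(which(a), which(b))))
  expect_error(symmetric_difference(R, matrix(FALSE, 5, 5)), "dimensions")
})

test_that("Minkowski dilation is the Euclidean tolerance tube", {
  X <- matrix(FALSE, 7, 7)
  X[4, 4] <- TRUE
  expect_identical(minkowski_dilate(X, 0), X)
  cross <- minkowski_dilate(X, 1)
  expect_identical(which(cross), which(distance_map(X) <= 1))
  expect_equal(sum(cross), 5)

  set.seed(22)
  for (i in 1:3) {
    m <- random_contour_map(32, 32, 0.03)
    rho <- sample(1:4, 1)
    expect_identical(minkowski_dilate(m, rho),
                     bf_distance_map(m) <= rho + 1e-9)
  }
})

test_that("epsilon: identity, shifted-column values, saturation", {
  set.seed(23)
  for (i in 1:5) {
    R <- random_contour_map(24, 24, 0.05)
    for (rho in c(0, 1, 2, 5)) expect_identical(epsilon(R, R, rho), 0)
  }

  R <- column_map(8, 8, 4)
  X <- column_map(8, 8, 5)
  expect_equal(epsilon(R, X, 0), 2.0)   # 16 mismatches over #R = 8
  expect_equal(epsilon(R, X, 1), 0)

  # tolerance at least the diagonal: tube covers the whole domain
  A <- random_contour_map(16, 16, 0.05)
  B <- random_contour_map(16, 16, 0.05)
  expect_identical(epsilon(A, B, 32), 0)

  expect_error(epsilon(matrix(FALSE, 8, 8), X, 1), "nonempty")
  # empty candidate: total miss, #R / #(R dilated)
  expect_equal(epsilon(R, matrix(FALSE, 8, 8), 0), 1)
})

test_that("epsilon is non-increasing in rho and matches the distance oracle", {
  set.seed(24)
  for (i in 1:4) {
    R <- random_contour_map(20, 20, 0.06)
    X <- random_contour_map(20, 20, 0.06)
    vals <- vapply(0:6, function(rho) epsilon(R, X, rho), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
    for (rho in c(0, 1, 3)) {
      expect_equal(epsilon(R, X, rho), bf_epsilon(R, X, rho))
    }
  }
})

test_that("epsilon is not a metric: asymmetry and triangle-inequality witnesses", {
  R <- matrix(FALSE, 10, 10); R[, c(3, 7)] <- TRUE
  X <- matrix(FALSE, 10, 10); X[, 3] <- TRUE
  expect_false(isTRUE(all.equal(epsilon(R, X, 0), epsilon(X, R, 0))))

  A <- column_map(10, 10, 3)
  B <- column_map(10, 10, 4)
  C <- column_map(10, 10, 5)
  expect_gt(epsilon(A, C, 1), epsilon(A, B, 1) + epsilon(B, C, 1))
})

test_that("figure of merit: bounds and worked values", {
  set.seed(25)
  R <- random_contour_map(16, 16, 0.08)
  expect_equal(fom(R, R), 0)

  a <- matrix(FALSE, 9, 9); a[5, 5] <- TRUE
  b <- matrix(FALSE, 9, 9); b[5, 6] <- TRUE
  expect_equal(fom(a, b), 0.5)

  # X = R plus one remote extra pixel: approaches 1/(#R + 1)
  R2 <- matrix(FALSE, 40, 40); R2[20, 1:5] <- TRUE
  X2 <- R2; X2[40, 40] <- TRUE
  d <- sqrt(min((20 - 40)^2 + (1:5 - 40)^2))
  expect_equal(fom(R2, X2), 1 - (5 + 1 / (1 + d^2)) / 6)
  expect_lt(abs(fom(R2, X2) - 1 / 6), 0.005)

  for (i in 1:5) {
    A <- random_contour_map(16, 16, 0.1)
    B <- random_contour_map(16, 16, 0.1)
    v <- fom(A, B)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_equal(fom(R, matrix(FALSE, 16, 16)), 1)
  expect_error(fom(matrix(FALSE, 4, 4), a[1:4, 1:4]), "nonempty")
})

test_that("tolerance selection finds the expert agreement radius", {
  base <- column_map(32, 32, 10)
  experts <- list(base, base, base)
  sel <- select_tolerance(experts, 0)
  expect_equal(sel$rho, 0)

  shifted <- list(column_map(32, 32, 10), column_map(32, 32, 11))
  sel2 <- select_tolerance(shifted, 0.05)
  expect_equal(sel2$rho, 1)
  expect_true(all(diff(sel2$curve$mean_epsilon) <= 1e-12))

  err <- tryCatch(select_tolerance(shifted, 0.05, rho_range = 0),
                  error = function(e) e)
  expect_s3_class(err, "endoseg_tolerance_error")
  expect_s3_class(err$curve, "data.frame")
})
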
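test_that("trimmed mean discards the worst floor(k*n) values", {
  x <- c(0.1, 0.9, 0.2, 0.5)
  expect_equal(trimmed_mean(x, 0), mean(x))
  expect_equal(trimmed_mean(x, 0.25), mean(c(0.1, 0.2, 0.5)))
  expect_equal(trimmed_mean(x, 0.5), mean(c(0.1, 0.2)))
})

test_that("k = 0 trimming reproduces the mean optimum exactly", {
  set.seed(31)
  for (i in 1:100) {
    v <- matrix(runif(5 * 7), 5, 7)
    tab <- fake_table(v)
    res <- grid_search(tab, k = 0)
    expect_identical(res$p_hat_k, res$p_hat)
    expect_identical(res$Q_hat_k, res$Q_hat)
  }
})

test_that("the three aggregators minimise what they claim to", {
  # hand-worked example: mean prefers the stable set, median the
  # usually-better one
  v <- matrix(c(0.1, 0.1, 0.9, 0.2, 0.2, 0.2), nrow = 3)
  tab <- fake_table(v)
  res <- grid_search(tab)
  expect_equal(res$p_hat$o, 2)        # mean: 0.2 < 0.3667
  expect_equal(res$Q_hat, 0.2)
  expect_equal(res$p_tilde$o, 1)      # median: 0.1 < 0.2
  expect_equal(res$Q_tilde, 0.1)

  single <- fake_table(matrix(c(0.3, 0.2, 0.4), 1))
  res1 <- grid_search(single)
  expect_identical(res1$p_hat, res1$p_hat_k)
  expect_identical(res1$p_hat, res1$p_tilde)
  expect_equal(res1$Q_hat, 0.2)

  # argmin correctness against an explicit scan, with lexicographic ties
  set.seed(32)
  for (i in 1:20) {
    v2 <- matrix(sample(seq(0, 1, 0.1), 4 * 6, replace = TRUE), 4, 6)
    t2 <- fake_table(v2)
    r2 <- grid_search(t2, k = 0.25)
    expect_equal(r2$Q_hat, min(colMeans(v2)))
    expect_equal(r2$p_hat$o, min(which(colMeans(v2) == min(colMeans(v2)))))
  }
})

test_that("quality scores a pipeline and penalises failures", {
  fx <- fixture_mini()
  q1 <- quality("vm", tuned_params("vm"), fx$img, fx$truth$contours)
  q2 <- quality("vm", tuned_params("vm"), fx$img, fx$truth$contours)
  expect_identical(q1, q2)
  expect_lt(q1, 0.3)
  expect_equal(quality("vm", tuned_params("vm"), fx$img, fx$truth$contours,
                       "fom"),
               fom(fx$truth$contours,
                   segment(fx$img, "vm", tuned_params("vm"))$contours))
  # the reference compared with itself is a perfect segmentation
  expect_equal(epsilon(fx$truth$contours, fx$truth$contours, 2), 0)
  expect_equal(fom(fx$truth$contours, fx$truth$contours), 0)
  # failure penalties
  expect_equal(quality("am", params_am(t = 255), fx$img, fx$truth$contours),
               2)
  expect_equal(quality("am", params_am(t = 255), fx$img, fx$truth$contours,
                       "fom"), 1)
})

test_that("projection sweeps one axis with the others anchored", {
  set.seed(33)
  grid <- parameter_grid("vm", o = 1:3, h = c(5, 10))
  v <- matrix(runif(4 * 6), 4, 6)
  tab <- structure(list(images = sprintf("i%d", 1:4), params = grid$params,
                        method = "vm", criterion = "epsilon", rho = 2,
                        values = v),
                   class = "endo_quality_table")
  res <- grid_search(tab, k = 0.25)
  pr <- projection(tab, res$p_hat_k, "o", k = 0.25)
  expect_equal(nrow(pr), 3)
  expect_equal(min(pr$Q), res$Q_hat_k)
  expect_equal(pr$value[which.min(pr$Q)], res$p_hat_k$o)
  pr_h <- projection(tab, res$p_hat_k, "h", k = 0.25)
  expect_equal(nrow(pr_h), 2)
  expect_error(projection(tab, res$p_hat_k, "zz", 0.25), "unknown")

  flat <- tab; flat$values <- matrix(0.4, 4, 6)
  expect_equal(unique(projection(flat, res$p_hat_k, "o", 0)$Q), 0.4)

  one <- parameter_grid("vm", o = 2, h = c(5, 10))
  tab1 <- structure(list(images = "i1", params = one$params, method = "vm",
                         criterion = "epsilon", rho = 2,
                         values = matrix(c(0.2, 0.3), 1)),
                    class = "endo_quality_table")
  expect_equal(nrow(projection(tab1, one$params[[1]], "o", 0)), 1)
})

test_that("k-fold bookkeeping: one test fold each, learned never beats test-best", {
  set.seed(34)
  # synthetic quality table standing in for a database of 11 images
  v <- matrix(runif(11 * 6, 0, 0.5), 11, 6)
  tab <- fake_table(v)
  db <- lapply(seq_len(11), function(i) list(id = tab$images[i]))
  grid <- parameter_grid("vm", o = 1:6, h = 1)
  cv <- kfold_cv(db, grid, K = 4, seed = 9L, table = tab)
  expect_equal(sort(unique(cv$fold_of)), 1:4)
  expect_equal(length(cv$fold_of), 11)
  expect_true(all(table(cv$fold_of) %in% 2:3))
  for (f in cv$folds) expect_lte(f$Q_tilde_i_CV, f$Q_i_CV + 1e-12)
  expect_equal(cv$Q_CV, mean(sapply(cv$folds, `[[`, "Q_i_CV")))

  expect_error(kfold_cv(db, grid, K = 12, table = tab), "exceeds")
  expect_error(kfold_cv(db, grid, K = 1, table = tab), "K must")

  # determinism of the fold shuffle
  cv2 <- kfold_cv(db, grid, K = 4, seed = 9L, table = tab)
  expect_identical(cv$fold_of, cv2$fold_of)
})

test_that("an end-to-end learning run recovers a stable optimum", {
  db <- synthetic_database(synthetic_spec(width = 128L, height = 128L,
                                          seed = 31L), 6)
  grid <- parameter_grid("vm", o = c(1, 2), h = c(8, 15))
  tab <- quality_table(db, grid)
  expect_equal(dim(tab$values), c(6L, 4L))
  expect_true(all(is.finite(tab$values)))
  cv <- kfold_cv(db, grid, K = 3, seed = 2L, table = tab)
  for (f in cv$folds) expect_lte(f$Q_tilde_i_CV, f$Q_i_CV + 1e-12)
  # homogeneous database: every fold learns the same tuple
  tuples <- sapply(cv$folds, function(f) endoseg:::param_label(f$p))
  expect_equal(length(unique(tuples)), 1)
})
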
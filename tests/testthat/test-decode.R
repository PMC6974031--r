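test_that("voxel ranking follows |t| with the index tie rule", {
  set.seed(1)
  n <- 6
  X <- matrix(rnorm(n * 4, sd = 0.1), n, 4)
  X[, 3] <- c(5, 5, 5, -5, -5, -5) + rnorm(n, sd = 0.1)  # all the signal
  y <- c(1, 1, 1, -1, -1, -1)
  rk <- rank_voxels(X, y)
  expect_equal(rk[1], 3)

  # hand-computed two-voxel t on a 6-exemplar fixture
  X2 <- cbind(c(1.2, 0.8, 1.1, -0.9, -1.0, -1.3),
              c(0.2, -0.1, 0.05, 0.1, -0.2, 0.15))
  t_hand <- apply(X2, 2, function(v) {
    a <- v[y > 0]; b <- v[y < 0]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  })
  expect_equal(rank_voxels(X2, y), order(-abs(t_hand)))

  # exact ties (duplicated voxel) break toward the lower index
  X3 <- cbind(X2[, 1], X2[, 1], X2[, 2])
  expect_equal(rank_voxels(X3, y), c(1, 2, 3))

  # zero-variance voxel is ranked by t = 0, not NaN
  X4 <- cbind(X2[, 1], rep(2, n))
  expect_equal(rank_voxels(X4, y), c(1, 2))
})

make_decode_subject <- function(n_vox = 100, signal_vox = integer(0),
                                gain = 3, n_train = 6, n_test = 8,
                                seed = 1) {
  set.seed(seed)
  mk <- function(n) {
    y <- rep(c(1, -1), length.out = n)
    x <- matrix(rnorm(n * n_vox), n, n_vox)
    x[, signal_vox] <- x[, signal_vox] + gain * y
    list(x = x, y = y)
  }
  tr <- mk(n_train); te <- mk(n_test)
  list(train_x = tr$x, train_y = tr$y, test_x = te$x, test_y = te$y)
}

test_that("nested voxel-count selection honors ties, finds signal, and never reads the left-out subject", {
  spec <- decode_spec(feature_step = 20, n_permutations = 10)
  # pure noise: accuracy flat in expectation is not guaranteed per draw, so
  # force exact flatness with a single informative voxel in every count
  subs <- lapply(1:4, function(s)
    make_decode_subject(100, signal_vox = 1, gain = 50, seed = s))
  expect_equal(select_voxel_count(subs, spec, left_out = 4), 20)

  # signal confined to 10 top-ranked voxels, step 20 in a 100-voxel ROI
  subs2 <- lapply(1:4, function(s)
    make_decode_subject(100, signal_vox = 1:10, gain = 2, seed = 10 + s))
  expect_equal(select_voxel_count(subs2, spec, left_out = 4), 20)

  # corruption of the left-out subject cannot change the choice
  subs3 <- subs2
  subs3[[4]]$train_x[] <- 1e6
  subs3[[4]]$test_x[] <- -1e6
  expect_equal(select_voxel_count(subs3, spec, left_out = 4),
               select_voxel_count(subs2, spec, left_out = 4))

  # degenerate ROI smaller than one step uses the whole ROI
  expect_equal(preconmvpa:::voxel_count_grid(40, 25), 25)
  expect_equal(preconmvpa:::voxel_count_grid(20, 100), c(20, 40, 60, 80, 100))
})

test_that("empirical chance matches exhaustive enumeration and tends to 50%", {
  preds <- c(1, 1, -1, -1)
  labels <- c(1, -1, 1, -1)
  exact <- oracle_chance(preds, labels)        # all C(4,2) arrangements
  mc <- empirical_chance(preds, labels, n_perm = 40000, seed = 2)
  expect_equal(mc, exact, tolerance = 0.02)
  expect_equal(exact, 50)                      # balanced two-class labels

  # unbalanced labels: expectation is no longer 50, enumeration still exact
  preds2 <- c(1, 1, 1, -1)
  labels2 <- c(1, 1, 1, -1)
  exact2 <- oracle_chance(preds2, labels2)
  mc2 <- empirical_chance(preds2, labels2, n_perm = 40000, seed = 3)
  expect_equal(mc2, exact2, tolerance = 1)

  # the reference default of 10,000 permutations is wired in
  expect_equal(decode_spec()$n_permutations, 10000L)
  expect_error(empirical_chance(preds, labels, n_perm = 0),
               class = "precon_validation_error")
})

test_that("cross-set decoding recovers a shared value axis and stays at chance without one", {
  set.seed(8)
  n_vox <- 60; n_sets <- 8
  v <- rnorm(n_vox); v <- v / sqrt(sum(v^2))
  mk_sub <- function(value_amp) {
    # per-set cue-identity patterns plus (optionally) a shared value axis
    ids <- lapply(seq_len(2 * n_sets), function(i) rnorm(n_vox))
    train_set <- rep(seq_len(n_sets), each = 6)
    train_y <- rep(rep(c(1, -1), each = 3), n_sets)
    train_x <- t(sapply(seq_along(train_set), function(i) {
      id <- ids[[(train_set[i] - 1) * 2 + (3 - train_y[i]) / 2]]
      id + value_amp * train_y[i] * v * 3 + rnorm(n_vox, sd = 0.5)
    }))
    test_set <- rep(seq_len(n_sets), each = 2)
    test_y <- rep(c(1, -1), n_sets)
    test_x <- t(sapply(seq_along(test_set), function(i) {
      rnorm(n_vox) + value_amp * test_y[i] * v * 3 +
        rnorm(n_vox, sd = 0.5)    # different cues: no identity transfer
    }))
    list(train_x = train_x, train_y = train_y, train_set = train_set,
         test_x = test_x, test_y = test_y, test_set = test_set)
  }
  spec <- decode_spec(scheme = "cross_set")
  with_val <- cross_set_decode(mk_sub(1), spec)
  expect_length(with_val$fold_accuracies, 8)   # exactly 8 folds
  expect_gt(with_val$accuracy, 75)
  no_val <- sapply(1:12, function(i) cross_set_decode(mk_sub(0), spec)$accuracy)
  expect_lt(abs(mean(no_val) - 50), 15)        # at chance without a shared axis
})

test_that("searchlight spheres have the documented geometry", {
  m <- roi_mask("lattice", dims = c(11, 11, 11), voxel_size_mm = c(2, 2, 2),
                indices = seq_len(11^3))
  center <- preconmvpa:::ijk_to_linear(cbind(6, 6, 6), m$dims)
  expect_length(sphere_indices(center, m, 8), 251)    # 8 mm on 2 mm lattice
  expect_length(sphere_indices(center, m, 2.1), 7)    # center + 6 face neighbors
  expect_length(sphere_indices(center, m, 1.9), 1)    # radius < voxel size
  # oracle: brute-force enumeration over the whole lattice
  ijk <- preconmvpa:::linear_to_ijk(seq_len(11^3), m$dims)
  d2 <- colSums((t(ijk) - c(6, 6, 6))^2) * 4
  expect_equal(sphere_indices(center, m, 8), which(d2 < 64))
  # truncation at the lattice edge
  corner <- preconmvpa:::ijk_to_linear(cbind(1, 1, 1), m$dims)
  expect_lt(length(sphere_indices(corner, m, 8)), 251)
  expect_error(sphere_indices(center, m, 0), class = "precon_validation_error")
})

test_that("searchlight maps localize planted signal and respect locality", {
  set.seed(12)
  m <- roi_mask("sl", dims = c(8, 8, 8), voxel_size_mm = c(2, 2, 2),
                indices = seq_len(512))
  n_ex <- 10
  y <- rep(c(1, -1), 5)
  blob <- preconmvpa:::ijk_to_linear(rbind(c(4, 4, 4), c(5, 4, 4),
                                           c(4, 5, 4), c(4, 4, 5)), m$dims)
  X <- matrix(rnorm(n_ex * 512), n_ex, 512)
  X[, blob] <- X[, blob] + 4 * y
  stat <- function(sub) {
    # mean class separation projected on the first axis of difference
    d <- colMeans(sub[y > 0, , drop = FALSE]) - colMeans(sub[y < 0, , drop = FALSE])
    sqrt(mean(d^2))
  }
  map <- searchlight_map(X, m, stat, radius_mm = 4)
  top <- m$indices[which.max(map)]
  dist_mm <- sqrt(sum((preconmvpa:::linear_to_ijk(top, m$dims) -
                         preconmvpa:::linear_to_ijk(blob[1], m$dims))^2)) * 2
  expect_lte(dist_mm, 4)
  # locality: changing data far from a sphere leaves its value untouched
  X2 <- X
  far <- preconmvpa:::ijk_to_linear(cbind(8, 8, 8), m$dims)
  X2[, far] <- 1e3
  map2 <- searchlight_map(X2, m, stat, radius_mm = 4)
  expect_equal(map2[which.max(map)], map[which.max(map)])
})

test_that("full ROI decoding pipeline returns coherent per-subject results", {
  subs <- lapply(1:4, function(s)
    make_decode_subject(40, signal_vox = 1:5, gain = 3, seed = 20 + s))
  spec <- decode_spec(feature_step = 10, n_permutations = 200, seed = 5)
  res <- decode_roi(subs, spec)
  expect_equal(nrow(res$table), 4)
  expect_true(all(res$table$accuracy >= 0 & res$table$accuracy <= 100))
  expect_true(all(res$table$n_voxels %in% c(10, 20, 30, 40)))
  expect_true(all(abs(res$table$chance - 50) < 10))
  expect_gt(res$group$statistic, 0)
})
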
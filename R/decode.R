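#' Decoding specification
#'
#' Bundles the classifier and cross-validation settings for the
#' cross-phase decoding analyses. Labels are coded +1 for the
#' reward-associated class (cues B in training; B or A in testing) and -1
#' for the nonreward class (D; D or C), so the B->A(reward) / D->C(nonreward)
#' mapping is implicit in the coding.
#'
#' @param scheme `"bd"` (train conditioning B/D, test probe B/D), `"ac"`
#'   (test probe A/C) or `"cross_set"` (leave-one-cue-set-out).
#' @param cost SVM soft-margin cost (default 1, linear kernel).
#' @param feature_step voxel-count increment for nested feature selection
#'   (40 for OFC, 20 for HPC in the reference design).
#' @param n_permutations label permutations for empirical chance
#'   (default 10000).
#' @param seed RNG seed for the permutations.
#' @param tail group-test tail (`"greater"`: directed above-chance test).
#' @export
decode_spec <- function(scheme = "bd", cost = 1, feature_step = 40,
                        n_permutations = 10000, seed = 1, tail = "greater") {
  if (!is_count(n_permutations)) abort_validation("permutation count must be >= 1")
  if (!is_count(feature_step)) abort_validation("feature step must be >= 1")
  if (!scheme %in% c("bd", "ac", "cross_set"))
    abort_validation("unknown decode scheme '%s'", scheme)
  structure(list(scheme = scheme, cost = cost,
                 feature_step = as.integer(feature_step),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), tail = tail),
            class = "decode_spec")
}

#' Rank voxels by absolute discriminative t-value
#'
#' Two-sample (pooled-variance) t of class +1 versus class -1 per voxel,
#' ordered by descending `|t|`; zero-variance voxels get t = 0; ties are
#' broken by ascending voxel index.
#'
#' @param x exemplars x voxels matrix.
#' @param y labels in \{-1, +1\}.
#' @return integer vector of voxel indices, best first.
#' @export
rank_voxels <- function(x, y) {
  x <- as.matrix(x)
  g1 <- x[y > 0, , drop = FALSE]
  g0 <- x[y < 0, , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g0) < 2)
    abort_validation("need >= 2 exemplars per class to rank voxels")
  n1 <- nrow(g1); n0 <- nrow(g0)
  v1 <- apply(g1, 2, var); v0 <- apply(g0, 2, var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t <- (colMeans(g1) - colMeans(g0)) / se
  t[!is.finite(t)] <- 0
  order(-abs(t), seq_along(t))
}

#' Train-on-one-phase, test-on-another SVM decoding accuracy
#'
#' Linear C-SVM (no feature rescaling) trained on `train_x`/`train_y`,
#' evaluated on `test_x`/`test_y`, optionally restricted to a voxel subset.
#' A decision value of exactly 0 predicts the reward (+1) class.
#'
#' @param train_x,test_x exemplars x voxels matrices on the same voxel set.
#' @param train_y,test_y labels in \{-1, +1\}.
#' @param voxels optional voxel index subset.
#' @param cost SVM cost.
#' @return list with `accuracy` (percent), `predictions`, `decisions`.
#' @export
svm_decode <- function(train_x, train_y, test_x, test_y, voxels = NULL,
                       cost = 1) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (!is.null(voxels)) {
    if (length(voxels) == 0) abort_validation("empty voxel subset")
    train_x <- train_x[, voxels, drop = FALSE]
    test_x <- test_x[, voxels, drop = FALSE]
  }
  model <- svm_train(train_x, train_y, cost = cost)
  pred <- svm_predict(model, test_x)
  list(accuracy = 100 * mean(pred == test_y), predictions = pred,
       decisions = svm_decision(model, test_x))
}

#' Empirical chance level by test-label permutation
#'
#' Holds the classifier's predictions fixed and permutes the test labels
#' uniformly `n_perm` times (training labels are never permuted); the mean
#' permuted accuracy is the per-subject empirical chance level.
#'
#' @param predictions fixed predicted labels.
#' @param labels true test labels.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return chance level in percent.
#' @export
empirical_chance <- function(predictions, labels, n_perm = 10000, seed = 1) {
  if (!is_count(n_perm)) abort_validation("n_perm must be >= 1")
  n <- length(labels)
  with_seed(seed, {
    acc <- vapply(seq_len(n_perm), function(i)
      mean(predictions == labels[sample.int(n)]), 0)
    100 * mean(acc)
  })
}

#' Leave-one-subject-out cross-validated voxel-count selection
#'
#' For every voxel count in `step, 2*step, ...` (capped at the ROI size;
#' if the ROI is smaller than one step the whole ROI is the only
#' candidate), trains on each retained subject's training patterns (their
#' own voxel ranking) and tests on that subject's test patterns, then
#' returns the count with the highest mean accuracy over retained
#' subjects; ties go to the smallest count. The left-out subject's data
#' never influence the choice.
#'
#' @param subjects list of per-subject decode data (see
#'   [decode_roi()]); each element has `train_x`, `train_y`, `test_x`,
#'   `test_y` and optionally `train_set`/`test_set`.
#' @param spec a [decode_spec()].
#' @param left_out index of the held-out subject.
#' @return optimal voxel count (integer).
#' @export
select_voxel_count <- function(subjects, spec, left_out) {
  retained <- setdiff(seq_along(subjects), left_out)
  if (length(retained) < 2)
    abort_validation("need >= 3 subjects for nested feature selection")
  n_vox <- ncol(subjects[[retained[1]]]$train_x)
  counts <- voxel_count_grid(spec$feature_step, n_vox)
  mean_acc <- vapply(counts, function(k) {
    mean(vapply(retained, function(s)
      eval_subject_accuracy(subjects[[s]], spec, k), 0))
  }, 0)
  counts[which.max(mean_acc)]   # which.max takes the first (smallest) on ties
}

voxel_count_grid <- function(step, n_vox) {
  if (step > n_vox) return(n_vox)
  grid <- seq(step, n_vox, by = step)
  if (tail(grid, 1) < n_vox) grid <- c(grid, n_vox)
  as.integer(grid)
}

# Accuracy of one subject at a fixed voxel count, using that subject's own
# t-based ranking of training voxels.
eval_subject_accuracy <- function(sub, spec, count) {
  if (spec$scheme == "cross_set") {
    cross_set_decode(sub, spec, count)$accuracy
  } else {
    rk <- sub$ranking %||% rank_voxels(sub$train_x, sub$train_y)
    svm_decode(sub$train_x, sub$train_y, sub$test_x, sub$test_y,
               voxels = rk[seq_len(count)], cost = spec$cost)$accuracy
  }
}

#' Leave-one-cue-set-out decoding
#'
#' Trains on all but one cue set's training exemplars and tests on the
#' held-out set's test exemplars; repeats over all sets and averages the
#' fold accuracies (8 folds in the reference design).
#'
#' @param sub per-subject decode data with `train_set` and `test_set`
#'   labels.
#' @param spec a [decode_spec()].
#' @param count optional voxel count (subset via the subject's ranking);
#'   `NULL` uses all voxels.
#' @return list with `accuracy` (mean over folds), `fold_accuracies`,
#'   `predictions`, `labels`.
#' @export
cross_set_decode <- function(sub, spec, count = NULL) {
  sets <- sort(unique(sub$test_set))
  if (is.null(sub$train_set) || is.null(sub$test_set))
    abort_validation("cross-set decoding needs cue-set labels")
  voxels <- NULL
  if (!is.null(count)) {
    rk <- sub$ranking %||% rank_voxels(sub$train_x, sub$train_y)
    voxels <- rk[seq_len(count)]
  }
  preds <- c(); labs <- c()
  fold_acc <- vapply(sets, function(k) {
    tr <- sub$train_set != k
    te <- sub$test_set == k
    if (!any(tr) || !any(te)) abort_validation("cue set %s missing", k)
    fit <- svm_decode(sub$train_x[tr, , drop = FALSE], sub$train_y[tr],
                      sub$test_x[te, , drop = FALSE], sub$test_y[te],
                      voxels = voxels, cost = spec$cost)
    preds <<- c(preds, fit$predictions); labs <<- c(labs, sub$test_y[te])
    fit$accuracy
  }, 0)
  list(accuracy = mean(fold_acc), fold_accuracies = fold_acc,
       predictions = preds, labels = labs)
}

#' ROI decoding with nested feature selection and empirical chance
#'
#' The full per-ROI analysis: for each held-out subject, the optimal voxel
#' count is chosen by [select_voxel_count()] on the remaining subjects,
#' the classifier is then trained and tested on the held-out subject at
#' that count, and the subject's empirical chance level is estimated by
#' permuting their test labels. Group inference is a one-sample t-test of
#' accuracy minus empirical chance (one-tailed by default).
#'
#' @param subjects list of per-subject decode data: `train_x`, `train_y`,
#'   `test_x`, `test_y` (+1 = reward class), optional `train_set`/`test_set`
#'   for the cross-set scheme.
#' @param spec a [decode_spec()].
#' @param feature_selection logical; searchlight callers disable it.
#' @return list with `table` (per-subject accuracy, chance, n_voxels),
#'   `group` (t-test vs empirical chance).
#' @export
decode_roi <- function(subjects, spec, feature_selection = TRUE) {
  for (i in seq_along(subjects))
    subjects[[i]]$ranking <- rank_voxels(subjects[[i]]$train_x,
                                         subjects[[i]]$train_y)
  n_vox <- ncol(subjects[[1]]$train_x)
  rows <- lapply(seq_along(subjects), function(s) {
    count <- if (feature_selection)
      select_voxel_count(subjects, spec, s) else n_vox
    sub <- subjects[[s]]
    if (spec$scheme == "cross_set") {
      fit <- cross_set_decode(sub, spec, if (feature_selection) count else NULL)
      preds <- fit$predictions; labs <- fit$labels
    } else {
      rk <- sub$ranking
      fit <- svm_decode(sub$train_x, sub$train_y, sub$test_x, sub$test_y,
                        voxels = rk[seq_len(count)], cost = spec$cost)
      preds <- fit$predictions; labs <- sub$test_y
    }
    chance <- empirical_chance(preds, labs, spec$n_permutations,
                               seed = derive_seed(spec$seed, "perm", s))
    data.frame(subject = s, accuracy = fit$accuracy, chance = chance,
               n_voxels = count)
  })
  table <- do.call(rbind, rows)
  group <- group_t(table$accuracy - table$chance, mu0 = 0, tail = spec$tail)
  list(table = table, group = group)
}

#' Searchlight sphere membership
#'
#' All lattice voxels whose center-to-center Euclidean distance from the
#' center voxel is strictly less than `radius_mm`, intersected with the
#' mask (spheres are truncated at mask and lattice edges). With an 8 mm
#' radius on a 2 mm isotropic lattice a fully interior sphere contains 251
#' voxels.
#'
#' @param center 1-based linear index of the center voxel (must be in the
#'   mask lattice).
#' @param mask an `roi_mask`.
#' @param radius_mm sphere radius in mm (> 0).
#' @return integer vector of 1-based linear voxel indices.
#' @export
sphere_indices <- function(center, mask, radius_mm) {
  if (radius_mm <= 0) abort_validation("radius must be > 0")
  dims <- mask$dims; vs <- mask$voxel_size_mm
  cijk <- linear_to_ijk(center, dims)
  ranges <- lapply(1:3, function(d) {
    m <- floor((radius_mm - 1e-9) / vs[d])
    seq(-m, m)
  })
  off <- as.matrix(expand.grid(ranges[[1]], ranges[[2]], ranges[[3]]))
  d2 <- (off[, 1] * vs[1])^2 + (off[, 2] * vs[2])^2 + (off[, 3] * vs[3])^2
  off <- off[d2 < radius_mm^2, , drop = FALSE]
  ijk <- sweep(off, 2, as.numeric(cijk), "+")
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
  idx <- ijk_to_linear(ijk[ok, , drop = FALSE], dims)
  sort(intersect(idx, mask$indices))
}

#' Searchlight map of a pattern statistic
#'
#' Evaluates `statistic` on the voxels of the sphere centered at every mask
#' voxel and writes the value at the center. No feature selection happens
#' inside spheres. The statistic receives the pattern submatrix restricted
#' to the sphere's voxels (columns follow `mask$indices` order); labels or
#' other context should be captured in its closure.
#'
#' @param patterns exemplars x mask-voxels matrix (columns ordered as
#'   `mask$indices`).
#' @param mask an `roi_mask`.
#' @param statistic `function(submatrix) -> scalar`.
#' @param radius_mm sphere radius.
#' @return numeric vector, one value per mask voxel.
#' @export
searchlight_map <- function(patterns, mask, statistic, radius_mm = 8) {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) != length(mask$indices))
    abort_validation("pattern columns (%d) != mask voxels (%d)",
                     ncol(patterns), length(mask$indices))
  vapply(seq_along(mask$indices), function(ci) {
    sph <- sphere_indices(mask$indices[ci], mask, radius_mm)
    cols <- match(sph, mask$indices)
    if (length(cols) == 0) abort_validation("empty searchlight sphere")
    statistic(patterns[, cols, drop = FALSE])
  }, 0)
}
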
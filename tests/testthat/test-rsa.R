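test_that("z_similarity matches hand computation and guards the limits", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  orc <- oracle_pearson_z(x, y)
  expect_equal(as.numeric(z_similarity(x, y)), orc$z, tolerance = 1e-12)
  expect_equal(orc$z, 2.3502, tolerance = 1e-3)   # atanh(0.98198...)

  zi <- z_similarity(x, x)
  expect_true(is.finite(zi))
  expect_true(isTRUE(attr(zi, "clamped")))
  expect_equal(as.numeric(z_similarity(x, -x)), -as.numeric(zi))
  expect_error(z_similarity(c(1, 1, 1), y), class = "precon_validation_error")
  expect_error(z_similarity(1:2, 1:2), class = "precon_validation_error")
})

make_estimates <- function(pats, sets = NULL) {
  # build a pattern_estimates-like object from a named list of patterns
  m <- do.call(rbind, pats)
  conds <- names(pats)
  labels <- preconmvpa:::parse_condition_labels(conds)
  structure(list(t = m, beta = m, df = 10, labels = labels),
            class = "pattern_estimates")
}

test_that("paired contrast is null for noise, antisymmetric, and averages z first", {
  set.seed(2)
  # E[delta] = 0 for i.i.d. patterns
  deltas <- replicate(200, {
    est <- make_estimates(list(A1 = rnorm(30), B1 = rnorm(30),
                               C1 = rnorm(30), D1 = rnorm(30)))
    paired_contrast_trajectory(list(est))$delta
  })
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(200))

  est <- make_estimates(list(A1 = rnorm(30), B1 = rnorm(30),
                             C1 = rnorm(30), D1 = rnorm(30)))
  fwd <- paired_contrast_trajectory(list(est))
  swapped <- paired_contrast_trajectory(list(est), pairing = list(
    within = list(c("A", "D"), c("C", "B")),
    between = list(c("A", "B"), c("C", "D"))))
  expect_equal(swapped$delta, -fwd$delta)

  # Fisher-z before averaging over sets (regression guard on the order)
  p <- list(A1 = rnorm(30), B1 = rnorm(30), C1 = rnorm(30), D1 = rnorm(30),
            A2 = rnorm(30), B2 = rnorm(30), C2 = rnorm(30), D2 = rnorm(30))
  est2 <- make_estimates(p)
  got <- paired_contrast_trajectory(list(est2))$z_within
  zs <- sapply(1:2, function(i)
    c(as.numeric(z_similarity(p[[paste0("A", i)]], p[[paste0("B", i)]])),
      as.numeric(z_similarity(p[[paste0("C", i)]], p[[paste0("D", i)]]))))
  expect_equal(got, mean(zs))

  # invariance to voxelwise z-scoring applied to both patterns of a pair
  sc <- lapply(p, function(v) as.numeric(scale(v)))
  expect_equal(paired_contrast_trajectory(list(make_estimates(sc)))$delta,
               paired_contrast_trajectory(list(est2))$delta, tolerance = 1e-10)
})

test_that("planted convergence produces an increasing trajectory recovered near the latent oracle", {
  cfg <- tiny_cfg(n_subjects = 2, similarity_slope = 0.1, noise_sd = 1e-4,
                  rois = c(medial_OFC = 48L, posterior_HPC = 16L),
                  feature_step = c(medial_OFC = 16L, posterior_HPC = 8L),
                  seed = 21)
  ds <- simulate_dataset(cfg)
  n_runs <- cfg$runs[["preconditioning"]]
  for (s in 1:2) {
    est <- lapply(seq_len(n_runs), function(r)
      subject_glm(ds, s, "preconditioning", r, "medial_OFC"))
    traj <- paired_contrast_trajectory(est)
    traj_beta <- paired_contrast_trajectory(est, measure = "beta")
    expect_true(all(diff(traj$delta) > 0))
    # oracle: correlations of the latent (noise-free) patterns themselves
    lat <- ds$subjects[[s]]$ground_truth$latents$medial_OFC$precond
    oracle_delta <- sapply(seq_len(n_runs), function(r) {
      zs <- sapply(seq_len(cfg$n_cue_sets), function(i) {
        w <- oracle_pearson_z(lat[[r]][[i]]$A, lat[[r]][[i]]$B)$z +
          oracle_pearson_z(lat[[r]][[i]]$C, lat[[r]][[i]]$D)$z
        b <- oracle_pearson_z(lat[[r]][[i]]$A, lat[[r]][[i]]$D)$z +
          oracle_pearson_z(lat[[r]][[i]]$C, lat[[r]][[i]]$B)$z
        (w - b) / 2
      })
      mean(zs)
    })
    slope_of <- function(v) unname(coef(lm(v ~ seq_len(n_runs)))[2])
    # beta patterns recover the latent patterns exactly at negligible noise
    expect_lt(abs(slope_of(traj_beta$delta) - slope_of(oracle_delta)), 1e-3)
    # t-maps add a voxelwise scaling, so agreement is approximate
    expect_lt(abs(slope_of(traj$delta) - slope_of(oracle_delta)), 0.03)
    expect_lt(abs(slope_of(oracle_delta) - 0.1), 0.04)
  }
})

test_that("linear trend test behaves at the edges and equals the paired t for 2 runs", {
  vals <- matrix(rep(c(0, 1, 2, 3), each = 5), nrow = 5)
  res <- linear_trend_test(vals)
  expect_equal(unname(res$slopes), rep(1, 5))
  expect_true(is.infinite(res$t) && res$t > 0)
  expect_gt(res$p, 0)                        # guarded, never exactly 0

  set.seed(9)
  two <- matrix(rnorm(16), 8, 2)
  tt <- linear_trend_test(two, tail = "two.sided")
  ref <- t.test(two[, 2], two[, 1], paired = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-10)

  # null calibration of the one-tailed test
  set.seed(31)
  rej <- mean(replicate(400, {
    linear_trend_test(matrix(rnorm(24), 6, 4), tail = "greater")$p < 0.05
  }))
  ci <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(rej, ci[1]); expect_lte(rej, ci[2])

  expect_error(linear_trend_test(matrix(1, 3, 1)),
               class = "precon_validation_error")
})

test_that("reactivation contrast is signed correctly and antisymmetric", {
  set.seed(4)
  last <- list(A = rnorm(50), C = rnorm(50))
  first <- list(A = rnorm(50), C = rnorm(50))
  # template equal to the last-run pattern: positive contrast
  res <- reactivation_contrast(last, first, last)
  expect_gt(res$value, 0)
  # template independent of both: expectation zero
  nulls <- replicate(200, {
    tpl <- list(A = rnorm(50), C = rnorm(50))
    reactivation_contrast(tpl, first, last)$value
  })
  expect_lt(abs(mean(nulls)), 3 * sd(nulls) / sqrt(200))
  # swapping first and last flips the sign exactly
  tpl <- list(A = rnorm(50), C = rnorm(50))
  expect_equal(reactivation_contrast(tpl, last, first)$value,
               -reactivation_contrast(tpl, first, last)$value)
  expect_error(reactivation_contrast(tpl, first, list(A = rnorm(10),
                                                      C = rnorm(50))),
               class = "precon_validation_error")
})

test_that("scan-day correction removes an additive day effect", {
  # realistic regime: weak true pattern similarity, moderate day component
  set.seed(6)
  n <- 3000
  base_first <- list(A = rnorm(n), C = rnorm(n))
  base_last <- list(A = rnorm(n), C = rnorm(n))
  tpl <- lapply(base_last, function(v) 0.1 * v + rnorm(n))
  day <- rnorm(n) * 0.5
  # day effect contaminates all day-2 patterns: template and last run
  tpl_day <- lapply(tpl, `+`, day)
  last_day <- lapply(base_last, `+`, day)
  raw <- reactivation_contrast(tpl_day, base_first, last_day)$value
  raw_clean <- reactivation_contrast(tpl, base_first, base_last)$value
  inflation <- raw - raw_clean
  expect_gt(inflation, 0.1)                   # uncorrected value is inflated
  corr <- scanday_corrected_contrast(tpl_day, base_first, last_day)
  corr_clean <- scanday_corrected_contrast(tpl, base_first, base_last)
  # correction removes the bulk of the day-driven inflation
  expect_lt(abs(corr$corrected - corr_clean$corrected), 0.2 * inflation)
  # zero day effect: corrected equals target minus (near-null) control
  expect_equal(corr_clean$corrected, raw_clean - corr_clean$control)
  expect_lt(abs(corr_clean$control), 0.05)
  expect_error(scanday_corrected_contrast(tpl, base_first, base_last,
                                          control_pairs = list(c("A", "A"))),
               class = "precon_validation_error")
})
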
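test_that("identical config and seed give identical datasets", {
  cfg <- tiny_cfg(seed = 42)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$subjects[[2]]$events, d2$subjects[[2]]$events)
  expect_identical(d1$subjects[[3]]$bold$probe[[1]]$medial_OFC,
                   d2$subjects[[3]]$bold$probe[[1]]$medial_OFC)
  expect_identical(d1$subjects[[1]]$behavior$recognition,
                   d2$subjects[[1]]$behavior$recognition)
  d3 <- simulate_dataset(tiny_cfg(seed = 43))
  expect_false(identical(d1$subjects[[1]]$events$probe[[1]]$onset,
                         d3$subjects[[1]]$events$probe[[1]]$onset))
  # streaming generation matches batch generation
  s2 <- simulate_subject(cfg, 2)
  expect_identical(s2$bold$conditioning[[2]]$medial_OFC,
                   d1$subjects[[2]]$bold$conditioning[[2]]$medial_OFC)
})

test_that("the default configuration carries the reference design counts", {
  cfg <- sim_config()
  expect_equal(cfg$n_subjects, 24)
  expect_equal(cfg$n_cue_sets, 8)
  expect_equal(unname(cfg$runs), c(4L, 5L, 1L))
  expect_equal(unname(cfg$feature_step[c("medial_OFC", "anterior_HPC")]),
               c(40L, 20L))
  # one full-size subject: trial counts per phase as designed
  sub <- simulate_subject(cfg, 1)
  pre <- sub$events$preconditioning[[1]]
  expect_equal(nrow(pre), 2 * (2 * 8 + 4) * cfg$precond_reps)
  expect_equal(sort(unique(pre$cue_set)), 1:8)
  cond <- sub$events$conditioning[[1]]
  expect_equal(nrow(cond), 2 * 8 * cfg$cond_reps)         # 32 trials per run
  expect_equal(length(sub$events$conditioning), 5)
  # 10 repetitions of each cue-outcome association over conditioning
  all_cond <- do.call(rbind, sub$events$conditioning)
  expect_equal(unname(table(paste(all_cond$cue_role, all_cond$cue_set))),
               rep(10L, 16), ignore_attr = TRUE)
  probe <- sub$events$probe[[1]]
  expect_equal(nrow(probe), 32 * 4)                        # every cue 4 times
  expect_false(any(probe$cue_role == "E"))
  # every event lies within its run's scan window
  for (phase in names(sub$events))
    for (r in seq_along(sub$events[[phase]])) {
      ev <- sub$events[[phase]][[r]]
      nv <- sub$n_volumes[[phase]][[r]]
      expect_lte(max(ev$onset + ev$duration), nv * cfg$tr_s)
    }
})

test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(rois = c(medial_OFC = 30L), value_roi = "medial_OFC",
                          ppi_seed_roi = "medial_OFC",
                          ppi_target_roi = "medial_OFC",
                          feature_step = c(medial_OFC = 40L)),
               class = "precon_validation_error")   # ROI smaller than step
  expect_error(sim_config(ar1 = 1), class = "precon_validation_error")
  expect_error(sim_config(noise_sd = 0), class = "precon_validation_error")
  expect_error(sim_config(reactivation_gain = 1.5),
               class = "precon_validation_error")
  expect_error(sim_config(value_roi = "nope"), class = "precon_validation_error")
  # run length too short for the event sequence
  cfg <- tiny_cfg(n_subjects = 1,
                  run_volumes = list(conditioning = 10))
  expect_error(simulate_dataset(cfg), class = "precon_validation_error")
})

test_that("a null configuration plants no structure", {
  cfg <- tiny_cfg(n_subjects = 2, similarity_slope = 0, value_amplitude = 0,
                  reactivation_gain = 0, coupling_modulation = 0,
                  coupling_base = 0, seed = 5)
  ds <- simulate_dataset(cfg)
  lat <- ds$subjects[[1]]$ground_truth$latents$medial_OFC
  # latent preconditioning patterns do not drift
  expect_identical(lat$precond[[1]], lat$precond[[4]])
  # paired and unpaired latent correlations are exchangeable noise
  zs <- sapply(seq_len(cfg$n_cue_sets), function(i)
    c(oracle_pearson_z(lat$precond[[1]][[i]]$A, lat$precond[[1]][[i]]$B)$z,
      oracle_pearson_z(lat$precond[[1]][[i]]$A, lat$precond[[1]][[i]]$D)$z))
  expect_lt(abs(mean(zs[1, ] - zs[2, ])), 0.5)
  gt <- ds$subjects[[1]]$ground_truth
  expect_equal(gt$similarity_slope, 0)
  expect_equal(gt$value_amplitude, 0)
})

test_that("ground truth records the planted effects and latents match the config", {
  cfg <- tiny_cfg(n_subjects = 2, similarity_slope = 0.12,
                  value_amplitude = 0.4, reactivation_gain = 0.6, seed = 9)
  ds <- simulate_dataset(cfg)
  gt <- ds$subjects[[2]]$ground_truth
  expect_equal(gt$similarity_slope, 0.12)
  expect_equal(gt$value_amplitude, 0.4)
  expect_equal(gt$reactivation_gain, 0.6)
  # fixed-effects mode: every subject carries the configured values
  expect_equal(ds$subjects[[1]]$ground_truth$similarity_slope, 0.12)
  # random-effects mode: subjects vary around the configured value
  cfg_re <- tiny_cfg(n_subjects = 6, similarity_slope = 0.12,
                     random_effects = TRUE, seed = 9)
  slopes <- sapply(simulate_dataset(cfg_re)$subjects,
                   function(s) s$ground_truth$similarity_slope)
  expect_gt(sd(slopes), 0)
  expect_lt(abs(mean(slopes) - 0.12), 0.1)
})

test_that("planted value code separates reward from nonreward patterns in the value ROI only", {
  cfg <- tiny_cfg(n_subjects = 1, value_amplitude = 0.8, seed = 13)
  ds <- simulate_dataset(cfg)
  lat <- ds$subjects[[1]]$ground_truth$latents
  proj <- function(roi) {
    v <- lat[[roi]]$value_axis
    mean(sapply(seq_len(cfg$n_cue_sets), function(i)
      sum(lat[[roi]]$cond[[i]]$B * v) - sum(lat[[roi]]$cond[[i]]$D * v)))
  }
  nv <- cfg$rois[["medial_OFC"]]
  expect_equal(proj("medial_OFC"), 2 * 0.8 * sqrt(nv), tolerance = 0.3)
  expect_lt(abs(proj("posterior_HPC")), 2)     # no value code outside value_roi
})

test_that("behavioral generator follows its learning-curve model", {
  # zero learning rate: both cues stay exactly at chance
  cfg0 <- tiny_cfg(learning_rate = 0)
  expect_equal(preconmvpa:::learning_curve(cfg0, "B", 1:10), rep(0.5, 10))
  expect_equal(preconmvpa:::learning_curve(cfg0, "D", 1:10), rep(0.5, 10))
  # saturation at the configured asymptotes under fast learning
  cfg1 <- tiny_cfg(learning_rate = 5, asym_reward = 1, asym_nonreward = 0)
  expect_equal(preconmvpa:::learning_curve(cfg1, "B", 10), 1, tolerance = 1e-10)
  expect_equal(preconmvpa:::learning_curve(cfg1, "D", 10), 0, tolerance = 1e-10)
  beh <- simulate_behavior(sim_config(n_subjects = 8, learning_rate = 5,
                                      asym_reward = 1, asym_nonreward = 0,
                                      nonresponse_rate = 0, seed = 2))
  cond <- beh$trials[beh$trials$phase == "conditioning", ]
  last_run <- cond[cond$run == 5, ]
  expect_equal(mean(last_run$response[last_run$cue_role == "B"] == "plus"), 1)
  expect_equal(mean(last_run$response[last_run$cue_role == "D"] == "plus"), 0)
})

test_that("recognition d-prime couples to probe inference across subjects", {
  # Monte-Carlo sign check over independent cohorts
  cors <- sapply(1:4, function(k) {
    cfg <- sim_config(n_subjects = 24, dprime_coupling = 1.3, seed = 100 + k)
    beh <- simulate_behavior(cfg)
    probe <- beh$trials[beh$trials$phase == "probe" &
                          beh$trials$cue_role %in% c("A", "C") &
                          beh$trials$response %in% c("plus", "minus"), ]
    ac <- sapply(seq_len(cfg$n_subjects), function(s) {
      p <- probe[probe$subject == s, ]
      100 * (mean(p$response[p$cue_role == "A"] == "plus") -
               mean(p$response[p$cue_role == "C"] == "plus"))
    })
    dp <- sapply(seq_len(cfg$n_subjects), function(s) {
      rc <- beh$recognition[beh$recognition$subject == s, ]
      dprime(rc$hits, rc$misses, rc$false_alarms, rc$correct_rejections)
    })
    cor(dp, ac)
  })
  expect_true(all(cors > 0))
  expect_gt(mean(cors), 0.3)
})

test_that("recovered similarity slope is monotone in the planted slope", {
  grid <- c(0, 0.08, 0.2)
  est <- sapply(grid, function(sl) {
    cfg <- tiny_cfg(n_subjects = 3, similarity_slope = sl, seed = 77)
    ds <- simulate_dataset(cfg)
    res <- analyze_similarity(ds, rois = "medial_OFC")
    mean(res$tests$medial_OFC$slopes)
  })
  expect_true(all(diff(est) > 0))
})

test_that("decoding accuracy is monotone in the planted value amplitude", {
  grid <- c(0, 0.25, 0.8)
  acc <- sapply(grid, function(va) {
    cfg <- tiny_cfg(n_subjects = 3, value_amplitude = va, seed = 78)
    ds <- simulate_dataset(cfg)
    spec <- decode_spec(scheme = "ac", feature_step = 16,
                        n_permutations = 50, seed = 1)
    mean(analyze_decoding(ds, "medial_OFC", spec)$table$accuracy)
  })
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[3], acc[1])
})
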
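test_that("the sway process is deterministic under a fixed seed", {
  pr <- quiet_preset()
  t1 <- generate_com_process(pr, seed = 99)
  t2 <- generate_com_process(pr, seed = 99)
  expect_identical(t1, t2)
  t3 <- generate_com_process(pr, seed = 100)
  expect_false(identical(t1$ml30, t3$ml30))
  # both grids subsample one underlying path: common instants agree
  expect_equal(t1$ml30[1], t1$ml100[1])
  expect_equal(t1$ml30[31], t1$ml100[101]) # t = 1 s on both grids
})

test_that("zero diffusion yields a constant path with zero sway", {
  tr <- generate_com_process(quiet_preset(), seed = 1, target_rms_mm = 0)
  expect_equal(tr$ml30, rep(0, length(tr$ml30)))
  expect_equal(tr$sway_30, 0)
  expect_error(generate_com_process(quiet_preset(), seed = 1,
                                    duration_s = -5), "positive")
})

test_that("the stationary RMS matches the preset target on a long horizon", {
  pr <- quiet_preset()
  tr <- generate_com_process(pr, seed = 123, target_rms_mm = 5,
                             duration_s = 200)
  expect_lt(abs(tr$sway_30 - 5) / 5, 0.10)
  expect_lt(abs(tr$sway_100 - 5) / 5, 0.10)
})

test_that("skeleton synthesis is seed-reproducible and validates input", {
  tr <- generate_com_process(quiet_preset(), seed = 5)
  s1 <- synthesize_skeleton(tr, seed = 6)
  s2 <- synthesize_skeleton(tr, seed = 6)
  expect_identical(s1$pos, s2$pos)
  expect_error(synthesize_skeleton(tr, seed = 6, height_cm = -170),
               "positive")
  expect_error(synthesize_skeleton(tr, seed = 6, lambda = 1.5), "lambda")
})

test_that("the template body is plausibly proportioned and mirrored for the camera", {
  tr <- generate_com_process(quiet_preset(), seed = 15)
  sk <- synthesize_skeleton(tr, seed = 16, height_cm = 172,
                            joint_noise_sd_mm = 0)
  f <- skeleton_frame(sk, 1)
  expect_gt(f$pos["head", 2], f$pos["spine_mid", 2])
  expect_gt(f$pos["spine_mid", 2], f$pos["knee_left", 2])
  # rear camera: plate-left appears at negative camera-ML after mirroring
  expect_lt(f$pos["hip_left", 1], f$pos["hip_right", 1])
  # omitting the mirror step yields the ML-negated path
  p_full <- com_path(sk, "three_joint", validate = FALSE)
  aligned <- align_to_first(sk) # pipeline minus flip_ml
  jj <- c("hip_left", "hip_right", "spine_mid")
  raw_ml <- rowMeans(sapply(jj, function(j) aligned$pos[, j, 1])) * 1000
  expect_equal(raw_ml, -p_full$ml_mm, tolerance = 1e-9)
})

test_that("hip-strategy articulation preserves the centroid trajectory", {
  tr <- generate_com_process(quiet_preset(), seed = 25)
  for (lam in c(0, 0.5, 1)) {
    sk <- synthesize_skeleton(tr, seed = 26, lambda = lam,
                              joint_noise_sd_mm = 0)
    p <- com_path(sk, "three_joint", validate = FALSE)
    expect_lt(max(abs(p$ml_mm - (tr$ml30 - tr$ml30[1]))), 1e-6)
    expect_lt(max(abs(p$ap_mm - (tr$ap30 - tr$ap30[1]))), 1e-6)
  }
  # lambda moves the head more than the ankles (trunk lean), ankles only
  # by the translated share
  sk1 <- synthesize_skeleton(tr, seed = 27, lambda = 1,
                             joint_noise_sd_mm = 0)
  head_rng <- diff(range(sk1$pos[, "head", 3]))
  ankle_rng <- diff(range(sk1$pos[, "ankle_left", 3]))
  expect_gt(head_rng, 10 * max(ankle_rng, 1e-12))
})

test_that("noisy recordings recover the true sway within tolerance", {
  # perturbed-condition presets: mean recovered/true sway ratio within 5%
  presets <- sot_presets()
  for (cond in c("d", "e")) {
    pr <- presets[presets$condition == cond, ]
    ratios_cam <- ratios_bm <- numeric(20)
    for (s in 1:20) {
      tr <- generate_com_process(pr, seed = 1000 + s)
      sk <- synthesize_skeleton(tr, seed = 2000 + s, lambda = pr$lambda)
      cf <- synthesize_cof(tr, seed = 3000 + s)
      ratios_cam[s] <- sway(com_path(sk, "three_joint",
                                     validate = FALSE))$sway_rms_mm /
        tr$sway_30
      ratios_bm[s] <- sway(cof_to_com(cf))$sway_rms_mm / tr$sway_100
    }
    expect_lt(abs(mean(ratios_cam) - 1), 0.05)
    expect_lt(abs(mean(ratios_bm) - 1), 0.05)
  }
})

test_that("noise-free CoF synthesis inverts exactly through the pendulum model", {
  tr <- generate_com_process(quiet_preset(), seed = 35)
  cf <- synthesize_cof(tr, seed = 36, cof_noise_sd_mm = 0)
  p <- cof_to_com(cf)
  expect_lt(max(abs(p$ml_mm - tr$ml100)), 1e-9)
  expect_lt(max(abs(p$ap_mm - tr$ap100)), 1e-9)
  # seed reproducibility with noise on
  c1 <- synthesize_cof(tr, seed = 37); c2 <- synthesize_cof(tr, seed = 37)
  expect_identical(c1$ml_mm, c2$ml_mm)
})

test_that("generate_study produces a full factorial with both channels", {
  st <- generate_study(n_subjects = 2, repeats = 2, seed = 11,
                       bias_add_mm = 0)
  expect_equal(nrow(st$data), 2 * 6 * 2 * 2)
  expect_setequal(unique(st$data$method), c("pendulum", "three_joint"))
  expect_equal(nrow(st$truth), 2 * 6 * 2)
  # deterministic under the master seed
  st2 <- generate_study(n_subjects = 2, repeats = 2, seed = 11,
                        bias_add_mm = 0)
  expect_identical(st$data, st2$data)
})

test_that("a null study shows no significant method bias", {
  st <- generate_study(n_subjects = 10, repeats = 2, seed = 21,
                       bias_add_mm = 0,
                       presets = sot_presets()[c(1, 4), ])
  rep_ <- agreement_report(st$data)
  for (i in seq_len(nrow(rep_$table))) {
    expect_lte(rep_$table$ci_bias_lo[i], 0 + 1e-9)
    expect_gte(rep_$table$ci_bias_hi[i], 0 - 1e-9)
  }
})

test_that("repeat pairs reflect only noise when driven by identical truth", {
  # two repeats from the same true path + independent sensor noise: the
  # within-pair SD equals the noise-induced SD of the sway estimate, and
  # CR keeps its fixed ratio to it
  pr <- sot_presets()[4, ]
  diffs <- numeric(30)
  for (s in 1:30) {
    tr <- generate_com_process(pr, seed = 5000 + s)
    s1 <- sway(com_path(synthesize_skeleton(tr, seed = 6000 + s),
                        "three_joint", validate = FALSE))$sway_rms_mm
    s2 <- sway(com_path(synthesize_skeleton(tr, seed = 7000 + s),
                        "three_joint", validate = FALSE))$sway_rms_mm
    diffs[s] <- s2 - s1
  }
  subj <- rep(1:30, each = 2)
  vals <- as.vector(rbind(0, diffs)) # pairs (0, d_j) have the same d_j
  r <- repeatability(vals, subj)
  expect_equal(r$cr, 1.96 * sqrt(2) * r$sd, tolerance = 1e-12)
  # closed-form noise propagation: the within-subject SD is RMS(d)/sqrt(2),
  # which for zero-mean noise differences approaches sd(d)/sqrt(2)
  expect_lt(abs(r$sd / (sqrt(mean(diffs^2)) / sqrt(2)) - 1), 1e-9)
  expect_lt(abs(r$sd / (sd(diffs) / sqrt(2)) - 1), 0.35)
})
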
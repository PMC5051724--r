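test_that("generation is seed-deterministic and respects the protocol shape", {
  models <- default_activity_models("hip")[c(1, 12, 16), ]
  dev <- default_device_models()[1, ]
  a <- generate_recording("P1", models, dev, activity_s = 20, break_s = 5, seed = 31)
  b <- generate_recording("P1", models, dev, activity_s = 20, break_s = 5, seed = 31)
  expect_identical(a$recording$x, b$recording$x)
  expect_identical(a$log, b$log)
  c <- generate_recording("P1", models, dev, activity_s = 20, break_s = 5, seed = 32)
  expect_false(identical(a$recording$x, c$recording$x))

  # 3 activities x 20 s + 2 breaks x 5 s at 100 Hz
  expect_equal(nrow(a$recording), (3 * 20 + 2 * 5) * 100)
  expect_equal(a$log$start, c(0, 25, 50))
  expect_equal(a$log$end, c(20, 45, 70))
  # logs satisfy the activity-log invariants
  expect_silent(accelcut:::validate_activity_log(a$log))
})

test_that("a noiseless motionless identity-device protocol yields zero metrics", {
  models <- default_activity_models("hip")[1:2, ]
  models$movement_amp_mg <- 0
  models$noise_sd_mg <- 0
  dev <- tibble::tibble(brand = "AG", off_x = 0, off_y = 0, off_z = 0,
                        gain_x = 1, gain_y = 1, gain_z = 1, extra_noise_sd_mg = 0)
  g <- generate_recording("P1", models, dev, activity_s = 70, break_s = 0, seed = 33)
  em <- compute_epoch_metrics(g$recording)
  lab <- trim_and_label(em, g$log, trim_s = 30)
  expect_true(all(abs(lab$enmo_mg) < 1e-9))
  expect_true(all(abs(lab$mad_mg) < 1e-9))
})

test_that("cohorts have four recordings per participant sharing latent movement", {
  co <- generate_cohort(n_participants = 1, seed = 34, activity_ids = c(1, 16),
                        activity_s = 15, break_s = 5)
  expect_length(co, 1)
  expect_named(co[[1]]$recordings, c("AG_hip", "GA_hip", "AG_wrist", "GA_wrist"))
  expect_length(co[[1]]$log, 2)
  # same latent true signal: AG and GA at the same site differ only by the
  # device model, so their difference carries no movement signal
  ag <- co[[1]]$recordings$AG_hip
  ga <- co[[1]]$recordings$GA_hip
  d <- ga$x - ag$x
  expect_lt(sd(d), 15)                          # device noise + offsets only
  expect_gt(stats::cor(ag$x, ga$x), 0.99)
})

test_that("disabling between-subject variation equalizes participant means", {
  lab <- simulate_labeled_cohort(n_participants = 8, seed = 35, placements = "hip",
                                 brands = "AG", activity_ids = 16,
                                 activity_s = 120, between_subject_sd = 0,
                                 calibrate = FALSE)
  per <- tapply(lab$mad_mg, lab$participant_id, mean)
  cv0 <- sd(per) / mean(per)
  expect_lt(cv0, 0.15)                          # residual spread: movement-shape draw
  lab2 <- simulate_labeled_cohort(n_participants = 8, seed = 35, placements = "hip",
                                  brands = "AG", activity_ids = 16,
                                  activity_s = 120, calibrate = FALSE)
  per2 <- tapply(lab2$mad_mg, lab2$participant_id, mean)
  expect_gt(sd(per2) / mean(per2), cv0)         # the random effect dominates
})

test_that("default amplitudes reproduce the published hip/wrist metric ranges", {
  lab <- cached("range_cohort", function() {
    simulate_labeled_cohort(n_participants = 6, seed = 36)
  })
  # published cohort means (mg): AG hip MAD by group, AG/GA contrasts at rest
  s <- summarize_by_activity(lab[lab$brand == "AG" & lab$placement == "hip", ], "mad")
  means <- setNames(s$mean_mg, s$group)
  expect_lt(abs(means[["sedentary behaviours"]] - 1.2), 1.0)
  expect_lt(abs(means[["washing pots"]] - 6.9) / 6.9, 0.5)
  expect_lt(abs(means[["self-paced walk"]] - 119.3) / 119.3, 0.35)
  # hip ordering: walk > sweeping > dusting > washing pots
  expect_gt(means[["self-paced walk"]], means[["sweeping floor"]])
  expect_gt(means[["sweeping floor"]], means[["dusting"]])
  expect_gt(means[["dusting"]], means[["washing pots"]])
  # wrist values exceed hip values for motion activities
  sw <- summarize_by_activity(lab[lab$brand == "AG" & lab$placement == "wrist", ], "mad")
  wrist <- setNames(sw$mean_mg, sw$group)
  for (g in c("washing pots", "dusting", "sweeping floor", "self-paced walk")) {
    expect_gt(wrist[[g]], means[[g]])
  }
  # GA reads higher than AG at rest (extra sensor noise)
  s_ga <- summarize_by_activity(lab[lab$brand == "GA" & lab$placement == "hip", ], "mad")
  expect_gt(s_ga$mean_mg[s_ga$group == "sedentary behaviours"],
            means[["sedentary behaviours"]] + 3)
})

test_that("amplitude calibration hits supplied targets and scales near-linearly", {
  targets <- tibble::tibble(group = c("sedentary", "walk"),
                            metric = "mad", mean_mg = c(0, 119.3))
  models <- fit_generator_to_targets(targets, seed = 37)
  expect_equal(models$movement_amp_mg[models$activity_id == 1], 0)
  amp_walk <- models$movement_amp_mg[models$activity_id == 16]
  expect_gt(amp_walk, 0)
  # verify the achieved mean on an independent simulation
  m <- models[models$activity_id == 16, ]
  dev <- default_device_models()[1, ]
  g <- generate_recording("P1", m, dev, activity_s = 120, break_s = 0, seed = 38)
  achieved <- mean(compute_epoch_metrics(g$recording)$mad_mg)
  expect_lt(abs(achieved - 119.3) / 119.3, 0.15)

  doubled <- fit_generator_to_targets(
    tibble::tibble(group = "walk", metric = "mad", mean_mg = 2 * 119.3), seed = 37)
  ratio <- doubled$movement_amp_mg[doubled$activity_id == 16] / amp_walk
  expect_lt(abs(ratio - 2) / 2, 0.25)

  expect_error(fit_generator_to_targets(
    tibble::tibble(group = "walk", metric = "mad", mean_mg = -5), seed = 37),
    class = "accelcut_validation_error")
})

test_that("the standing discrimination is a null: mean AUROC within 0.5 +/- 0.03", {
  aurocs <- standing_null_study()
  expect_length(aurocs, 200)                   # 50 seeds x 2 brands x 2 metrics
  expect_lt(abs(mean(aurocs) - 0.5), 0.03)
})
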
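#' Default activity models for the synthetic protocol
#'
#' One row per protocol activity: a static gravity orientation in the
#' device frame, a movement amplitude (mg), a set of movement
#' frequencies (Hz), a base sensor-noise SD (mg) and a between-subject
#' log-normal spread. The movement model is a sum of sinusoids at the
#' listed frequencies with random phases and random unit directions,
#' riding on the static 1-g gravity vector, plus white noise.
#'
#' All eleven sedentary postures and standing still share one (near
#' zero) movement amplitude: vector-magnitude metrics carry no posture
#' information, and an exchangeable standing model is what makes the
#' standing discrimination an exact null, mirroring the laboratory
#' finding that standing cannot be separated from sitting/lying by
#' intensity alone. Motion-activity amplitudes are calibrated so that
#' cohort mean epoch MAD/ENMO land in the published ranges for each
#' wear site (hip ordering walk > sweeping > dusting > washing pots);
#' see also [fit_generator_to_targets()].
#'
#' @param placement `"hip"` or `"wrist"`; wrist motion amplitudes are
#'   larger (arm movement) and wrist base noise is higher.
#' @return Tibble `activity_id`, `label`, `ox`, `oy`, `oz`,
#'   `movement_amp_mg`, `movement_freqs` (list), `noise_sd_mg`,
#'   `between_subject_sd`.
#' @export
default_activity_models <- function(placement = c("hip", "wrist")) {
  placement <- match.arg(placement)
  acts <- protocol_activities()
  # distinct static orientations: four lying postures roll the device,
  # sitting/upright keep gravity near one axis with small tilts
  ori <- rbind(
    c(0, 0, 1), c(0, 0.4, -0.9165151), c(1, 0, 0), c(-0.8660254, 0, -0.5),
    c(0.1736482, -0.9848078, 0), c(0, -0.9848078, 0.1736482),
    c(-0.1736482, -0.9848078, 0), c(0.0871557, -0.9961947, 0),
    c(0, -0.9961947, -0.0871557), c(0.2588190, -0.9659258, 0),
    c(0, -0.9396926, 0.3420201),
    c(0, -1, 0), c(0.0871557, -0.9961947, 0), c(0, -0.9961947, 0.0871557),
    c(-0.0871557, -0.9961947, 0), c(0, -1, 0)
  )
  low_amp <- if (placement == "hip") 1.5 else 2.5
  amp <- if (placement == "hip") {
    c(rep(low_amp, 12), 19.5, 86, 109, 350)
  } else {
    c(rep(low_amp, 12), 292, 250, 518, 448)
  }
  freqs <- c(
    rep(list(c(0.8, 1.5)), 12),
    list(c(1.0, 1.7, 2.4)), list(c(1.2, 2.0, 2.8)),
    list(c(1.0, 1.8, 2.6)), list(c(0.9, 1.8, 2.7))
  )
  tibble::tibble(
    activity_id = acts$activity_id,
    label = acts$label,
    ox = ori[, 1], oy = ori[, 2], oz = ori[, 3],
    movement_amp_mg = amp,
    movement_freqs = freqs,
    noise_sd_mg = if (placement == "hip") 1.5 else 8,
    between_subject_sd = 0.3
  )
}

#' Default device models
#'
#' Brand-specific affine distortion and extra sensor noise. The GA model
#' carries larger offsets, gains further from one and markedly more
#' noise than AG, emulating the higher low-intensity readings reported
#' for that brand; the pipeline's auto-calibration can undo offset/gain
#' but not noise.
#'
#' @return Tibble `brand`, `off_x`, `off_y`, `off_z` (mg), `gain_x`,
#'   `gain_y`, `gain_z`, `extra_noise_sd_mg`.
#' @export
default_device_models <- function() {
  tibble::tibble(
    brand = c("AG", "GA"),
    off_x = c(3, 14), off_y = c(-2, -10), off_z = c(4, 8),
    gain_x = c(1, 1), gain_y = c(1, 1), gain_z = c(1, 1),
    extra_noise_sd_mg = c(0, 10)
  )
}

# True (device-free) tri-axial signal for one activity block:
# 1000 * orientation + sum_k (amp/sqrt(K)) sin(2 pi f_k t + phi_k) d_k + noise
activity_block <- function(n, fs, ox, oy, oz, amp, freqs, noise_sd) {
  t <- (seq_len(n) - 1) / fs
  x <- rep(1000 * ox, n); y <- rep(1000 * oy, n); z <- rep(1000 * oz, n)
  if (amp > 0) {
    k <- length(freqs)
    a <- amp / sqrt(k)
    # random orthonormal movement frame: the movement energy projected on
    # any fixed axis (gravity included) is then direction-invariant, so
    # epoch metrics depend on amplitude, not on the orientation draw
    frame <- qr.Q(qr(matrix(rnorm(9), 3)))
    for (j in seq_len(k)) {
      phi <- runif(1, 0, 2 * pi)
      d <- frame[, (j - 1L) %% 3L + 1L]
      s <- a * sin(2 * pi * freqs[j] * t + phi)
      x <- x + s * d[1]; y <- y + s * d[2]; z <- z + s * d[3]
    }
  }
  if (noise_sd > 0) {
    x <- x + rnorm(n, 0, noise_sd)
    y <- y + rnorm(n, 0, noise_sd)
    z <- z + rnorm(n, 0, noise_sd)
  }
  list(x = x, y = y, z = z)
}

generate_true_signal <- function(models, fs, activity_s, break_s) {
  n_act <- as.integer(round(activity_s * fs))
  n_brk <- as.integer(round(break_s * fs))
  xs <- list(); ys <- list(); zs <- list()
  log_start <- numeric(nrow(models)); log_end <- numeric(nrow(models))
  t0 <- 0
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    blk <- activity_block(n_act, fs, m$ox, m$oy, m$oz, m$movement_amp_mg,
                          m$movement_freqs[[1]], m$noise_sd_mg)
    xs[[length(xs) + 1L]] <- blk$x
    ys[[length(ys) + 1L]] <- blk$y
    zs[[length(zs) + 1L]] <- blk$z
    log_start[i] <- t0
    log_end[i] <- t0 + n_act / fs
    t0 <- log_end[i]
    if (i < nrow(models) && n_brk > 0L) {
      # break: at rest in the next activity's orientation, noise only
      nx <- models[i + 1L, ]
      brk <- activity_block(n_brk, fs, nx$ox, nx$oy, nx$oz, 0, numeric(),
                            nx$noise_sd_mg)
      xs[[length(xs) + 1L]] <- brk$x
      ys[[length(ys) + 1L]] <- brk$y
      zs[[length(zs) + 1L]] <- brk$z
      t0 <- t0 + n_brk / fs
    }
  }
  x <- unlist(xs); y <- unlist(ys); z <- unlist(zs)
  list(t = (seq_along(x) - 1) / fs, x = x, y = y, z = z,
       log = tibble::tibble(activity_id = models$activity_id,
                            label = models$label,
                            start = log_start, end = log_end))
}

apply_device_model <- function(sig, device) {
  s <- device$extra_noise_sd_mg
  n <- length(sig$x)
  ex <- if (s > 0) rnorm(n, 0, s) else 0
  ey <- if (s > 0) rnorm(n, 0, s) else 0
  ez <- if (s > 0) rnorm(n, 0, s) else 0
  list(t = sig$t,
       x = device$gain_x * (sig$x + ex) + device$off_x,
       y = device$gain_y * (sig$y + ey) + device$off_y,
       z = device$gain_z * (sig$z + ez) + device$off_z,
       log = sig$log)
}

#' Generate one synthetic raw recording with its activity log
#'
#' Emulates one laboratory session on one device: each activity in
#' `models` is performed in sequence for `activity_s` seconds with a
#' `break_s`-second rest between consecutive activities, sampled at
#' `fs` Hz. The same seed always reproduces the identical recording.
#'
#' @param participant_id Participant identifier carried into metadata.
#' @param models Activity-model tibble (see [default_activity_models()]),
#'   one row per activity to perform, in order.
#' @param device One row of [default_device_models()] (or a compatible
#'   one-row data frame).
#' @param fs Sampling frequency in Hz (default 100).
#' @param activity_s Seconds per activity (default 300 = 5 minutes).
#' @param break_s Seconds of rest between activities (default 30).
#' @param seed Integer seed; required for reproducibility.
#' @param placement Wear site recorded in metadata.
#' @return List with `recording` (an [raw_recording()]) and `log`
#'   (activity log tibble with `start`/`end` in seconds).
#' @export
generate_recording <- function(participant_id, models, device,
                               fs = 100, activity_s = 300, break_s = 30,
                               seed, placement = "hip") {
  withr::with_seed(seed, {
    sig <- generate_true_signal(models, fs, activity_s, break_s)
    obs <- apply_device_model(sig, device)
    rec <- raw_recording(
      tibble::tibble(t = obs$t, x = obs$x, y = obs$y, z = obs$z),
      fs = fs, brand = device$brand, placement = placement,
      participant_id = participant_id, validate = FALSE)
    list(recording = rec, log = sig$log[, c("activity_id", "label", "start", "end")])
  })
}

#' Generate a synthetic cohort of raw recordings
#'
#' Each participant performs the full protocol once per wear site; the
#' two brands at a site observe the *same* latent movement (identical
#' true signal) through their own device models, so brand contrasts
#' reflect sensor differences only. Per-participant log-normal random
#' effects (sd `between_subject_sd` on the log scale, drawn per
#' participant x activity) scale the movement amplitudes.
#'
#' Note: at the default protocol size a full cohort holds hours of
#' 100 Hz signal; for epoch-level analyses prefer the streaming
#' [simulate_labeled_cohort()], which never keeps more than one
#' recording in memory.
#'
#' @param n_participants Number of participants (the laboratory study
#'   had 33).
#' @param seed Integer seed.
#' @param placements,brands Wear sites / brands to generate.
#' @param fs,activity_s,break_s As in [generate_recording()].
#' @param activity_ids Subset of the protocol to perform (default all 16).
#' @param between_subject_sd Override the models' between-subject
#'   spread (`NULL` keeps the per-activity defaults; `0` disables it).
#' @return List with one element per participant: `participant_id`,
#'   `log` (per placement), and `recordings`, a named list
#'   (`"<brand>_<placement>"`) of [raw_recording()] objects.
#' @export
generate_cohort <- function(n_participants = 33, seed,
                            placements = c("hip", "wrist"),
                            brands = c("AG", "GA"),
                            fs = 100, activity_s = 300, break_s = 30,
                            activity_ids = 1:16,
                            between_subject_sd = NULL) {
  devices <- default_device_models()
  devices <- devices[devices$brand %in% brands, , drop = FALSE]
  withr::with_seed(seed, {
    lapply(seq_len(n_participants), function(p) {
      pid <- sprintf("P%02d", p)
      entry <- list(participant_id = pid, log = list(), recordings = list())
      models0 <- default_activity_models(placements[1])
      bs <- between_subject_sd %||% models0$between_subject_sd
      mult <- exp(rnorm(nrow(models0), 0, bs))
      for (pl in placements) {
        models <- default_activity_models(pl)
        models <- models[models$activity_id %in% activity_ids, , drop = FALSE]
        models$movement_amp_mg <- models$movement_amp_mg *
          mult[match(models$activity_id, models0$activity_id)]
        sig <- generate_true_signal(models, fs, activity_s, break_s)
        entry$log[[pl]] <- sig$log[, c("activity_id", "label", "start", "end")]
        for (b in seq_len(nrow(devices))) {
          obs <- apply_device_model(sig, devices[b, ])
          entry$recordings[[paste0(devices$brand[b], "_", pl)]] <- raw_recording(
            tibble::tibble(t = obs$t, x = obs$x, y = obs$y, z = obs$z),
            fs = fs, brand = devices$brand[b], placement = pl,
            participant_id = pid, validate = FALSE)
        }
      }
      entry
    })
  })
}

#' Simulate a cohort straight to labeled epoch metrics
#'
#' Streaming pipeline driver: generates each synthetic recording, runs
#' auto-calibration (optional), computes per-epoch ENMO and MAD, joins
#' the activity log with transition trimming, and binds the labeled
#' epochs of all recordings — discarding each raw signal as it goes, so
#' a full-size cohort fits comfortably in memory.
#'
#' @inheritParams generate_cohort
#' @param trim_s,epoch_s Passed to [trim_and_label()] /
#'   [compute_epoch_metrics()].
#' @param calibrate Apply [calibrate_recording()] before the metrics
#'   (default TRUE; the published pipeline auto-calibrates before ENMO,
#'   and calibrating MAD input too is harmless since MAD is offset-free
#'   to first order).
#' @return Labeled epoch tibble ready for [run_threshold_battery()].
#' @export
simulate_labeled_cohort <- function(n_participants = 33, seed,
                                    placements = c("hip", "wrist"),
                                    brands = c("AG", "GA"),
                                    fs = 100, activity_s = 300, break_s = 30,
                                    activity_ids = 1:16,
                                    between_subject_sd = NULL,
                                    trim_s = 30, epoch_s = 5,
                                    calibrate = TRUE) {
  devices <- default_device_models()
  devices <- devices[devices$brand %in% brands, , drop = FALSE]
  withr::with_seed(seed, {
    out <- vector("list", n_participants * length(placements) * nrow(devices))
    k <- 0L
    for (p in seq_len(n_participants)) {
      pid <- sprintf("P%02d", p)
      models0 <- default_activity_models(placements[1])
      bs <- between_subject_sd %||% models0$between_subject_sd
      mult <- exp(rnorm(nrow(models0), 0, bs))
      for (pl in placements) {
        models <- default_activity_models(pl)
        models <- models[models$activity_id %in% activity_ids, , drop = FALSE]
        models$movement_amp_mg <- models$movement_amp_mg *
          mult[match(models$activity_id, models0$activity_id)]
        sig <- generate_true_signal(models, fs, activity_s, break_s)
        log <- sig$log
        for (b in seq_len(nrow(devices))) {
          obs <- apply_device_model(sig, devices[b, ])
          rec <- raw_recording(
            tibble::tibble(t = obs$t, x = obs$x, y = obs$y, z = obs$z),
            fs = fs, brand = devices$brand[b], placement = pl,
            participant_id = pid, validate = FALSE)
          if (calibrate) rec <- calibrate_recording(rec)$recording
          em <- compute_epoch_metrics(rec, epoch_s = epoch_s)
          k <- k + 1L
          out[[k]] <- trim_and_label(em, log, trim_s = trim_s, epoch_s = epoch_s)
        }
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Calibrate movement amplitudes to target epoch-metric means
#'
#' One-dimensional search per activity group: finds the movement
#' amplitude whose simulated mean epoch metric matches a supplied target
#' mean (e.g. a published cohort mean) within 15%. Targets at or below
#' the sensor-noise floor resolve to amplitude 0.
#'
#' @param target_means Tibble with columns `group` (one of `sedentary`,
#'   `standing`, `washing_pots`, `dusting`, `sweeping`, `walk`),
#'   `metric` (`"enmo"` or `"mad"`), `mean_mg` (target mean, mg).
#' @param seed Integer seed (fixes the simulation noise so the search
#'   objective is deterministic and monotone).
#' @param placement Wear site whose defaults are being recalibrated.
#' @param sim_s Seconds of signal simulated per objective evaluation.
#' @param tolerance Relative matching tolerance (default 0.15).
#' @return The [default_activity_models()] tibble for `placement` with
#'   `movement_amp_mg` replaced for every targeted group.
#' @export
fit_generator_to_targets <- function(target_means, seed, placement = "hip",
                                     sim_s = 60, tolerance = 0.15) {
  models <- default_activity_models(placement)
  group_ids <- list(sedentary = 1:11, standing = 12L, washing_pots = 13L,
                    dusting = 14L, sweeping = 15L, walk = 16L)
  for (i in seq_len(nrow(target_means))) {
    g <- target_means$group[i]
    metric <- match.arg(target_means$metric[i], c("enmo", "mad"))
    target <- target_means$mean_mg[i]
    if (!g %in% names(group_ids)) {
      abort(sprintf("Unknown activity group '%s'.", g), class = "accelcut_validation_error")
    }
    if (!is.finite(target) || target < 0) {
      abort(sprintf("Target mean for '%s' must be a non-negative number.", g),
            class = "accelcut_validation_error")
    }
    ids <- group_ids[[g]]
    proto <- models[models$activity_id == ids[1], ]
    sim_mean <- function(amp) {
      withr::with_seed(seed + 1000L * i, {
        m <- proto
        m$movement_amp_mg <- amp
        sig <- generate_true_signal(m, fs = 100, activity_s = sim_s, break_s = 0)
        rec <- raw_recording(tibble::tibble(t = sig$t, x = sig$x, y = sig$y, z = sig$z),
                             fs = 100, validate = FALSE)
        em <- compute_epoch_metrics(rec)
        mean(em[[paste0(metric, "_mg")]])
      })
    }
    amp <- if (sim_mean(0) >= target) {
      0
    } else {
      hi <- 100
      while (sim_mean(hi) < target && hi < 1e5) hi <- hi * 2
      if (sim_mean(hi) < target) {
        abort(sprintf("Target %.1f mg for '%s' is unattainable.", target, g),
              class = "accelcut_validation_error")
      }
      uniroot(function(a) sim_mean(a) - target, c(0, hi), tol = 1e-3 * hi)$root
    }
    achieved <- sim_mean(amp)
    if (target > 0 && abs(achieved - target) > tolerance * target) {
      warn(sprintf("Group '%s': achieved mean %.2f mg vs target %.2f mg (outside %.0f%%).",
                   g, achieved, target, 100 * tolerance))
    }
    models$movement_amp_mg[models$activity_id %in% ids] <- amp
  }
  models
}
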
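# Small in-code fixtures and a per-session cache for the expensive
# simulation studies shared by several test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

static_recording <- function(x, y, z, seconds = 10, fs = 100, ...) {
  n <- as.integer(seconds * fs)
  raw_recording(tibble::tibble(t = (seq_len(n) - 1) / fs,
                               x = rep(x, n), y = rep(y, n), z = rep(z, n)),
                fs = fs, ...)
}

# labeled epoch table built directly (no signal generation): n_epochs
# epochs per activity per participant, values drawn around per-activity
# centres so that discriminations are assembled cheaply
make_labeled_set <- function(n_participants, n_epochs = 4, activities = 1:16,
                             brand = "AG", placement = "hip",
                             enmo_centre = NULL, mad_centre = NULL, sd = 0.5) {
  enmo_centre <- enmo_centre %||% c(rep(1, 12), 6, 18, 22, 58)
  mad_centre <- mad_centre %||% c(rep(1.2, 12), 7, 29, 37, 119)
  grid <- expand.grid(participant_id = sprintf("P%02d", seq_len(n_participants)),
                      activity_id = activities, epoch = seq_len(n_epochs),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    epoch_start = (grid$activity_id - 1) * 330 + (grid$epoch - 1) * 5 + 30,
    participant_id = grid$participant_id,
    brand = brand, placement = placement,
    activity_id = as.integer(grid$activity_id),
    enmo_mg = pmax(rnorm(nrow(grid), enmo_centre[grid$activity_id], sd), 0),
    mad_mg = pmax(rnorm(nrow(grid), mad_centre[grid$activity_id], sd), 0)
  )
}

# protocol-shaped activity log: 16 activities, 5 min each, 30-s breaks
make_protocol_log <- function(n_activities = 16, activity_s = 300, break_s = 30) {
  start <- (seq_len(n_activities) - 1) * (activity_s + break_s)
  tibble::tibble(activity_id = seq_len(n_activities),
                 label = protocol_activities()$label[seq_len(n_activities)],
                 start = start, end = start + activity_s)
}

cached <- local({
  env <- new.env(parent = emptyenv())
  function(key, fn) {
    if (!exists(key, envir = env)) assign(key, fn(), envir = env)
    get(key, envir = env)
  }
})

# Full-scale synthetic cohort (33 participants, complete protocol) and
# its threshold battery; built once per test session.
full_cohort_battery <- function() {
  cached("full_battery", function() {
    lab <- simulate_labeled_cohort(n_participants = 33, seed = 20160913)
    w <- character()
    bat <- withCallingHandlers(
      run_threshold_battery(lab),
      warning = function(cond) {
        w <<- c(w, conditionMessage(cond))
        invokeRestart("muffleWarning")
      })
    list(labeled = lab, battery = bat, warnings = w)
  })
}

# 50-seed standing-discrimination null study at reduced cohort size
# (8 participants, hip site, sedentary + standing protocol, 3-minute
# activities): standing shares the sedentary movement model, so these
# AUROCs sample the null distribution.
standing_null_study <- function() {
  cached("standing_null", function() {
    res <- numeric(0)
    for (s in 1:50) {
      lab <- simulate_labeled_cohort(n_participants = 8, seed = 40000 + s,
                                     placements = "hip", activity_ids = 1:12,
                                     activity_s = 180)
      for (br in c("AG", "GA")) {
        for (m in c("enmo", "mad")) {
          ds <- build_discrimination(lab[lab$brand == br, ], metric = m,
                                     discrimination = "standing")
          res <- c(res, auroc(ds)$auroc)
        }
      }
    }
    res
  })
}
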
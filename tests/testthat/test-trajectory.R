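# Construct a minimal trajectory + trial pair with known deviations.
# Two participants, one condition, n trials each, 4 samples per trial,
# constant toward-coded deviation `dev` at interior samples.
toy_tracking <- function(n = 30, dev = 5, seed = 1, n_participants = 4,
                         duration = 1) {
  set.seed(seed)
  rows <- list(); traj <- list()
  for (p in seq_len(n_participants)) {
    id <- sprintf("s%02d", p)
    target <- runif(n) * 360
    prev <- c(NA, target[-n])
    trials <- data.frame(participant = id, condition = "A", block = 1,
                         trial_index = seq_len(n), target = target,
                         error = rnorm(n, 0, 2), report_rt = duration)
    rows[[p]] <- trials
    delta <- rep(NA_real_, n)
    delta[-1] <- signed_diff(prev[-1], target[-1])
    for (k in seq_len(n)) {
      u <- seq(0, 1, length.out = 4)
      s <- if (is.na(delta[k]) || delta[k] == 0) 1 else sign(delta[k])
      d_tow <- rep(dev, 4) + rnorm(4, 0, 0.5)
      traj[[length(traj) + 1]] <- data.frame(
        participant = id, condition = "A", trial_index = k,
        time_from_start = u * duration,
        time_to_response = (u - 1) * duration,
        pointing_angle = wrap_circle(target[k] + d_tow * s))
    }
  }
  list(trials = do.call(rbind, rows), trajectories = do.call(rbind, traj))
}

test_that("bias surface recovers a constant toward bias", {
  tk <- toy_tracking(n = 40, dev = 6)
  surf <- trajectory_bias_surface(tk$trajectories, tk$trials,
                                  n_grid = 20, min_trials = 10, min_eff_n = 3)
  expect_s3_class(surf, "bias_surface_set")
  s <- surf$conditions[["A"]]
  expect_equal(dim(s$bias), c(20, 20))
  expect_gt(min(s$bias, na.rm = TRUE), 3)
  expect_true(any(s$significant, na.rm = TRUE))
  expect_equal(surf$support_ms, 1000)
  # one all-positive cluster
  cs <- s$cluster_summary
  expect_true(all(cs$sign == 1))
})

test_that("surface time support uses the min_trials-th largest duration", {
  tk <- toy_tracking(n = 30, duration = 1)
  # shorten ten trials of one participant
  short <- tk$trajectories$participant == "s01" &
    tk$trajectories$trial_index <= 10
  tk$trajectories$time_from_start[short] <-
    tk$trajectories$time_from_start[short] * 0.4
  tk$trajectories$time_to_response[short] <-
    (tk$trajectories$time_from_start[short] - 0.4)
  tk$trials$report_rt[tk$trials$participant == "s01" &
                        tk$trials$trial_index <= 10] <- 0.4
  surf <- trajectory_bias_surface(tk$trajectories, tk$trials, n_grid = 10,
                                  min_trials = 25, min_eff_n = 2)
  # s01 has 29 usable trials (first trial unpaired), 10 of them 400 ms:
  # the 25th largest duration is 400 ms
  expect_equal(surf$support_ms, 400)
  expect_error(trajectory_bias_surface(tk$trajectories, tk$trials,
                                       min_trials = 50),
               "min_trials")
})

test_that("cells below the effective-n floor are masked, never zeroed", {
  tk <- toy_tracking(n = 30)
  surf <- trajectory_bias_surface(tk$trajectories, tk$trials, n_grid = 15,
                                  min_trials = 10, min_eff_n = 4,
                                  diss_sd = 5)
  s <- surf$conditions[["A"]]
  expect_true(any(is.na(s$bias)))
  expect_true(all(is.na(s$t[is.na(s$bias)])))
  expect_false(any(s$significant[is.na(s$bias)]))
})

test_that("cluster labelling respects 4-connectivity and sign", {
  m <- matrix(0L, 5, 5)
  m[1:2, 1] <- 1L          # positive cluster of 2
  m[4:5, 4:5] <- 1L        # positive cluster of 4 (not connected to first)
  m[1, 3] <- -1L           # negative singleton touching nothing
  m[2, 3] <- 1L            # positive singleton diagonal to [1,3]
  lab <- serialbias:::label_clusters(m)
  expect_equal(max(lab), 4)
  expect_equal(lab[1, 1], lab[2, 1])
  expect_equal(lab[4, 4], lab[5, 5])
  expect_false(lab[1, 3] == lab[2, 3]) # different signs never merge
  tstat <- matrix(rnorm(25), 5, 5)
  p <- matrix(runif(25), 5, 5)
  summ <- serialbias:::summarize_clusters(lab, tstat, 1:5, 1:5, p)
  expect_equal(nrow(summ), 4)
  expect_equal(sum(summ$n_cells), sum(m != 0))
})

test_that("frame_bias extracts first/second/last sample signs", {
  tk <- toy_tracking(n = 20, dev = 8)
  fb <- frame_bias(tk$trajectories, tk$trials)
  # only paired trials with nonzero delta appear
  expect_true(all(fb$trial_index > 1))
  expect_true(all(fb$n_samples == 4))
  # constant +8 toward deviation: all signs positive
  expect_true(all(fb$first_sign == 1))
  expect_true(all(fb$last_sign == 1))
})

test_that("second_frame_repulsive_fraction counts what it says", {
  frames <- data.frame(participant = "s01", condition = "A",
                       trial_index = 1:6,
                       first_sign = c(1, 1, -1, 1, -1, 1),
                       second_sign = c(-1, 1, -1, NA, 1, -1),
                       last_sign = c(1, 1, 1, 1, -1, 1),
                       n_samples = c(4, 4, 4, 1, 4, 4))
  sf <- second_frame_repulsive_fraction(frames)
  # attractive-ending with second frame: trials 1,2,3,6 -> repulsive 1,3,6
  expect_equal(sf$n_trials, 4)
  expect_equal(sf$n_repulsive_second, 3)
  expect_equal(sf$percent, 75)
  expect_equal(sf$n_skipped, 1)
  expect_error(second_frame_repulsive_fraction(
    data.frame(first_sign = 1, second_sign = NA, last_sign = -1)), "no attractive")
})

test_that("generator frame knobs shape the first/second frame statistics", {
  cfg <- sim_config(n_participants = 8, n_blocks = 2,
                    first_frame_agreement = 0.61,
                    second_frame_flip_rate = 0.43, seed = 71)
  ex <- simulate_experiment(cfg)
  tr <- serial_prep(ex$trials)
  fb <- frame_bias(ex$trajectories, tr)
  sf <- second_frame_repulsive_fraction(fb)
  expect_gt(sf$percent, 33)
  expect_lt(sf$percent, 53)
  ff <- first_frame_sign_analysis(fb)
  expect_true(all(c("strata", "strata_tests", "condition_contrast") %in% names(ff)))
  # agreement > 0.5: mean first sign positive in attractive-ending strata
  att <- ff$strata_tests[ff$strata_tests$final_sign == 1, ]
  expect_true(all(att$mean > 0))
  fl <- first_last_sign_model(fb)
  expect_gt(fl$mean_slope, 0)
  expect_lt(fl$p, 0.05)
})

test_that("first_last_sign_model drops constant-sign participants and caps", {
  set.seed(5)
  frames <- do.call(rbind, lapply(1:5, function(p) {
    fs <- sample(c(-1, 1), 40, replace = TRUE)
    if (p == 1) fs <- rep(1, 40) # constant: no slope estimable
    ls <- ifelse(runif(40) < 0.7, fs, -fs)
    if (p == 2) ls <- fs # complete separation: slope capped
    data.frame(participant = sprintf("s%02d", p), condition = "A",
               trial_index = 1:40, first_sign = fs, second_sign = fs,
               last_sign = ls, n_samples = 4)
  }))
  expect_message(fl <- first_last_sign_model(frames), "dropped")
  expect_equal(fl$n_dropped, 1)
  expect_gte(fl$n_capped, 1)
  expect_true(all(abs(fl$slopes$slope) <= 10))
})
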
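test_that("sim_config validates fields and names the offender", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_participants = 0), "n_participants")
  expect_error(sim_config(n_trials_per_block = 1), "n_trials_per_block")
  expect_error(sim_config(conditions = c("A", "A")), "conditions")
  expect_error(sim_config(swap_rate = 1.5), "swap_rate")
  expect_error(sim_config(cross_condition_correlation = 2),
               "cross_condition_correlation")
  expect_error(sim_config(response_noise_sd = -1), "response_noise_sd")
  expect_error(sim_config(generate_trajectories = NA), "generate_trajectories")
})

test_that("named amplitude means are matched to conditions", {
  cfg <- sim_config(conditions = c("B", "A"),
                    bias_amplitude_mean = c(A = 3, B = -3))
  expect_equal(unname(cfg$bias_amplitude_mean), c(-3, 3))
  expect_equal(names(cfg$bias_amplitude_mean), c("B", "A"))
  cfg2 <- sim_config(bias_amplitude_mean = 2)
  expect_equal(unname(cfg2$bias_amplitude_mean), c(2, 2))
  expect_error(sim_config(bias_amplitude_mean = c(X = 1, Y = 2)),
               "bias_amplitude_mean")
})

test_that("simulate_experiment has the documented structure and scale", {
  ex <- small_experiment()
  expect_s3_class(ex, "serial_experiment")
  tr <- ex$trials
  expect_equal(nrow(tr), 6 * 2 * 2 * 60)
  expect_setequal(unique(tr$condition), c("Stroop", "NoStroop"))
  expect_true(all(tr$target >= 0 & tr$target < 360))
  expect_true(all(tr$report >= 0 & tr$report < 360))
  expect_true(all(tr$error > -180 & tr$error <= 180))
  expect_equal(tr$error, signed_diff(tr$report, tr$target))
  expect_true(all(tr$report_rt >= 0.2))
  # trajectories cover every trial and end exactly at the report
  tj <- ex$trajectories
  expect_equal(nrow(unique(tj[, c("participant", "condition", "trial_index")])),
               nrow(tr))
  last <- tj[tj$time_to_response == 0, ]
  key <- c("participant", "condition", "trial_index")
  m <- merge(tr, last, by = key)
  expect_equal(nrow(m), nrow(tr))
  expect_equal(wrap_signed(m$pointing_angle - m$report),
               rep(0, nrow(m)), tolerance = 1e-9)
})

test_that("simulation is reproducible from the seed", {
  a <- small_experiment(seed = 5)
  b <- small_experiment(seed = 5)
  d <- small_experiment(seed = 6)
  expect_identical(a$trials, b$trials)
  expect_identical(a$trajectories, b$trajectories)
  expect_false(identical(a$trials$report, d$trials$report))
})

test_that("generate_trajectories = FALSE skips the trajectory table", {
  ex <- small_experiment(generate_trajectories = FALSE)
  expect_null(ex$trajectories)
})

test_that("injected asymmetry is recovered in expectation", {
  # strong, homogeneous bias; amplitude calibration is linear in this range
  cfg <- sim_config(n_participants = 12,
                    bias_amplitude_mean = c(Stroop = 10, NoStroop = -10),
                    bias_amplitude_sd = 0.5, cardinal_bias_amplitude = 0,
                    swap_rate = 0, outlier_rate = 0,
                    generate_trajectories = FALSE, seed = 21)
  ex <- simulate_experiment(cfg)
  est <- per_subject_bias(serial_prep(ex$trials))
  means <- tapply(est$asymmetry, est$condition, mean)
  expect_gt(means[["Stroop"]], 7)
  expect_lt(means[["NoStroop"]], -7)
})

test_that("latent calibration subtracts the counting-noise variance", {
  cfg <- sim_config()
  lat <- serialbias:::latent_bias_params(cfg)
  n_eff <- cfg$n_blocks * (cfg$n_trials_per_block - 1)
  expect_equal(lat$counting_se, 100 / sqrt(n_eff))
  expect_equal(lat$sd, sqrt(cfg$bias_amplitude_sd^2 - 100^2 / n_eff))
  # latent correlation is inflated so the measured one lands on target
  expect_gt(lat$correlation, cfg$cross_condition_correlation)
  # an observed SD below the counting floor collapses the latent scale
  lat2 <- serialbias:::latent_bias_params(sim_config(bias_amplitude_sd = 1))
  expect_lt(lat2$sd, 0.01)
  expect_true(lat2$capped)
})

test_that("Stroop columns behave per condition", {
  ex <- small_experiment()
  tr <- ex$trials
  ns <- tr[tr$condition == "NoStroop", ]
  st <- tr[tr$condition == "Stroop", ]
  expect_true(all(ns$stroop_response == "down"))
  expect_gt(mean(st$stroop_correct), 0.8)
  expect_gt(mean(st$stroop_rt), mean(ns$stroop_rt))
  expect_equal(st$stroop_congruent, st$stroop_word == st$stroop_color)
})

test_that("write_experiment round-trips through the readers", {
  ex <- small_experiment(seed = 31)
  dir <- withr::local_tempdir()
  write_experiment(ex, dir)
  tr <- read_trials(file.path(dir, "trials.csv"))
  tj <- read_trajectories(file.path(dir, "trajectories.csv"))
  expect_equal(nrow(tr), nrow(ex$trials))
  expect_equal(tr$report, ex$trials$report, tolerance = 1e-9)
  expect_equal(nrow(tj), nrow(ex$trajectories))
  expect_error(read_trials(file.path(dir, "nope.csv")), "not found")
  bad <- file.path(dir, "bad.csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_trials(bad), "missing columns")
  expect_error(read_trajectories(bad), "missing columns")
})

test_that("cardinal bias function has the advertised shapes", {
  f <- serialbias:::cardinal_bias_fun
  th <- seq(0, 359.5, by = 0.5)
  s <- f(th, 5, "repel", "sine")
  expect_equal(max(abs(s)), 5, tolerance = 1e-6)
  expect_equal(f(c(0, 45, 90), 5, "repel", "sine"), c(0, 0, 0), tolerance = 1e-9)
  # sawtooth: zero at its own axes, discontinuous at the repelled ones
  lin <- f(th, 5, "repel", "linear")
  expect_equal(f(c(45, 135), 5, "repel", "linear"), c(0, 0))
  expect_equal(f(89.999, 5, "repel", "linear"), -5, tolerance = 1e-3)
  expect_equal(f(90.001, 5, "repel", "linear"), 5, tolerance = 1e-3)
  lat <- f(th, 5, "attract", "linear")
  expect_equal(f(44.999, 5, "attract", "linear"), -5, tolerance = 1e-3)
  expect_equal(f(45.001, 5, "attract", "linear"), 5, tolerance = 1e-3)
})
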
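test_that("within_subject_ci removes between-subject variance", {
  set.seed(2)
  n <- 40
  subj <- rnorm(n, 0, 50)                 # huge between-subject spread
  a <- subj + rnorm(n, 0, 1)
  b <- subj + 1 + rnorm(n, 0, 1)
  ci <- within_subject_ci(cbind(a = a, b = b))
  expect_equal(ci$condition, c("a", "b"))
  expect_equal(ci$mean, c(mean(a), mean(b)))
  # the adjusted SE reflects the within-subject noise, not the 50-unit
  # subject spread
  expect_lt(max(ci$se), 1)
  raw_se <- sd(a) / sqrt(n)
  expect_lt(ci$se[1], raw_se / 10)
  expect_true(all(ci$lower < ci$mean & ci$mean < ci$upper))
})

test_that("within_subject_ci matches the Morey rescaling analytically", {
  x <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2)
  ci <- within_subject_ci(x, level = 0.95)
  centered <- x - rowMeans(x) + mean(x)
  se_exp <- apply(centered, 2, sd) / sqrt(3) * sqrt(2 / 1)
  expect_equal(ci$se, se_exp)
  expect_error(within_subject_ci(x[1, , drop = FALSE]), "at least 2")
  expect_message(within_subject_ci(x[, 1, drop = FALSE]), "single condition")
})

test_that("paired_contrast agrees with stats::t.test and Cohen's d", {
  set.seed(4)
  x <- rnorm(20, 1)
  y <- rnorm(20)
  pc <- paired_contrast(x, y, labels = c("one", "two"))
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(pc$t, unname(tt$statistic))
  expect_equal(pc$p, tt$p.value)
  expect_equal(pc$d, mean(x - y) / sd(x - y))
  expect_equal(pc$condition_1, "one")
  expect_error(paired_contrast(1, 2), "at least 2")
})

test_that("stroop_congruency_contrast finds the planted effects", {
  ex <- small_experiment(seed = 81, n_participants = 12)
  res <- stroop_congruency_contrast(ex$trials)
  expect_equal(nrow(res), 4) # 2 conditions x (rt, accuracy)
  st_rt <- res[res$condition == "Stroop" & res$measure == "rt", ]
  # congruent faster than incongruent in the Stroop condition
  expect_lt(st_rt$mean_diff, 0)
  expect_lt(st_rt$p, 0.05)
  st_acc <- res[res$condition == "Stroop" & res$measure == "accuracy", ]
  expect_gt(st_acc$mean_diff, 0)
  # fixed-key condition: no congruency effect on RT
  ns_rt <- res[res$condition == "NoStroop" & res$measure == "rt", ]
  expect_gt(ns_rt$p, 0.05)
  expect_error(stroop_congruency_contrast(data.frame(condition = "A")),
               "congruency")
})

test_that("condition_bias_contrast pairs participants and reports all parts", {
  est <- data.frame(
    participant = rep(sprintf("s%02d", 1:10), each = 2),
    condition = rep(c("A", "B"), 10),
    asymmetry = c(rbind(rnorm(10, 5, 2), rnorm(10, -5, 2))))
  res <- condition_bias_contrast(est)
  expect_named(res, c("contrast", "one_sample", "correlation", "wide"))
  expect_equal(res$contrast$n, 10)
  expect_gt(res$contrast$t, 0)
  expect_equal(nrow(res$one_sample), 2)
  # unmatched participant dropped with a message
  est2 <- rbind(est, data.frame(participant = "s99", condition = "A",
                                asymmetry = 0))
  expect_message(res2 <- condition_bias_contrast(est2), "unmatched")
  expect_equal(res2$contrast$n, 10)
  expect_error(condition_bias_contrast(est[est$condition == "A", ]),
               "two conditions")
})

test_that("rt_dissimilarity_model recovers injected slope and offset", {
  cfg <- sim_config(n_participants = 25, rt_slope_per_degree = -0.88,
                    rt_condition_offset = -80, rt_slope_subject_sd = 0.1,
                    generate_trajectories = FALSE, seed = 91)
  ex <- simulate_experiment(cfg)
  fit <- rt_dissimilarity_model(ex$trials)
  es <- fit$estimates
  sl <- es[es$term == "slope_ms_per_deg", ]
  expect_lt(abs(sl$estimate - -0.88), 0.2)
  expect_lt(sl$p, 0.001)
  off <- es[es$term == "condition_offset_ms", ]
  # coding: NoStroop = 0, Stroop = 1 (alphabetical); Stroop is 80 ms faster
  expect_equal(fit$condition_coding, "NoStroop = 0, Stroop = 1")
  expect_lt(abs(off$estimate - -80), 25)
  inter <- es[es$term == "interaction_ms_per_deg", ]
  expect_gt(inter$p, 0.001) # no interaction injected
})

test_that("rt model excludes sparse participants and validates conditions", {
  ex <- small_experiment(seed = 95, generate_trajectories = FALSE)
  tr <- ex$trials
  # leave participant s01 with too few usable trials
  drop <- tr$participant == "s01" & tr$trial_index > 3
  tr <- tr[!drop, ]
  expect_message(fit <- rt_dissimilarity_model(tr, min_trials = 50),
                 "excluded")
  expect_equal(fit$n_excluded, 1)
  one <- ex$trials[ex$trials$condition == "Stroop", ]
  expect_error(rt_dissimilarity_model(one), "two conditions")
})

test_that("lmer variant agrees with the two-stage slope", {
  cfg <- sim_config(n_participants = 12, n_blocks = 2,
                    generate_trajectories = FALSE, seed = 97)
  ex <- simulate_experiment(cfg)
  f1 <- rt_dissimilarity_model(ex$trials, method = "two_stage")
  f2 <- suppressWarnings(rt_dissimilarity_model(ex$trials, method = "lmer"))
  s1 <- f1$estimates$estimate[f1$estimates$term == "slope_ms_per_deg"]
  s2 <- f2$estimates$estimate[f2$estimates$term == "slope_ms_per_deg"]
  expect_lt(abs(s1 - s2), 0.2)
})
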
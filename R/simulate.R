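#' Configuration for a synthetic direction-report experiment
#'
#' Builds and validates the parameter set used by [simulate_experiment()].
#' Defaults emulate a dual-session continuous direction-report study with a
#' concurrent Stroop load in one session: 33 participants, 5 blocks of 96
#' trials per condition, uniform stimulus directions, dissimilarity-tuned
#' serial bias of stable per-subject amplitude correlated across conditions,
#' cardinal anisotropy, response times decreasing with current-vs-previous
#' dissimilarity, and response-locked cursor trajectories with an early
#' repulsive lobe.
#'
#' @param n_participants Number of simulated participants.
#' @param n_blocks,n_trials_per_block Blocks per condition and trials per
#'   block; serial-bias pairing never crosses a block break.
#' @param conditions Labels of the two conditions. The first is treated as
#'   the Stroop (dual-task) condition.
#' @param bias_amplitude_mean Mean per-subject serial-bias asymmetry in
#'   percent, one value per condition (positive = attractive). May be a
#'   single number, an unnamed length-2 vector in `conditions` order, or a
#'   named vector.
#' @param bias_amplitude_sd SD across subjects of the *measured* asymmetry
#'   (percent) at the configured trial count. The generator subtracts the
#'   analytically known counting-noise variance to obtain the latent
#'   between-subject SD.
#' @param cross_condition_correlation Expected correlation across conditions
#'   of measured per-subject asymmetries at the configured trial count. The
#'   latent correlation is inflated accordingly (capped at 1; the realized
#'   value is recorded in the ground truth).
#' @param bias_tuning_width Width (degrees) of the derivative-of-Gaussian
#'   dissimilarity tuning `b(D) = a (D/w) exp(-(D/w)^2)`.
#' @param cardinal_bias_amplitude Amplitude (degrees) of the cardinal
#'   anisotropy.
#' @param cardinal_bias_sign `"repel"` or `"attract"` (relative to the
#'   cardinal axes).
#' @param cardinal_bias_shape `"sine"` for the smooth `A sin(4 theta)` form,
#'   `"linear"` for a sawtooth that is discontinuous at the repelled axes
#'   (cardinals when repelling, obliques when attracting).
#' @param response_noise_sd Baseline SD (degrees) of wrapped report noise.
#' @param noise_sd_cardinal_modulation Extra noise SD (degrees) at oblique
#'   directions; the per-trial SD is
#'   `response_noise_sd + m (1 - cos 4 theta)/2`.
#' @param swap_rate Probability a trial reports near the previous target.
#' @param outlier_rate Probability of a uniform random report.
#' @param rt_intercept Report RT intercept (seconds) for the second
#'   condition at zero dissimilarity.
#' @param rt_slope_per_degree Fixed RT slope, ms per degree of dissimilarity.
#' @param rt_condition_offset RT offset (ms) of the first condition relative
#'   to the second.
#' @param rt_subject_sd,rt_slope_subject_sd SDs of per-subject random RT
#'   intercepts (seconds) and slopes (ms/degree).
#' @param rt_noise_sd Residual report-RT SD (seconds).
#' @param rt_floor Lower truncation of report RTs (seconds).
#' @param trajectory_sample_rate Cursor polling rate (Hz).
#' @param early_bias_amplitude Toward-coded amplitude (degrees) of the early
#'   trajectory lobe (negative = repulsive).
#' @param early_bias_peak_dissimilarity,early_bias_width Centre and width
#'   (degrees) of the Gaussian dissimilarity tuning of the early lobe.
#' @param trajectory_jitter_sd Angular jitter SD (degrees) of interior
#'   trajectory samples.
#' @param initial_angle_noise_sd Magnitude scale (degrees) of the
#'   first-frame pointing deviation.
#' @param first_frame_agreement Probability that the first-frame deviation
#'   sign agrees with the trial's final bias sign.
#' @param second_frame_flip_rate Probability that the second frame of a
#'   trial ending with an attractive bias shows a repulsive deviation.
#' @param stroop_rt_mean,stroop_rt_sd Mean and SD (seconds) of Stroop RTs.
#' @param stroop_congruency_rt_effect Incongruent-minus-congruent Stroop RT
#'   difference (seconds).
#' @param stroop_accuracy Mean Stroop accuracy (proportion).
#' @param stroop_congruency_acc_effect Congruent-minus-incongruent accuracy
#'   difference (proportion).
#' @param nostroop_rt_mean,nostroop_rt_sd Mean and SD (seconds) of key-press
#'   RTs in the no-Stroop condition (fixed key).
#' @param generate_trajectories Logical; set `FALSE` to skip the trajectory
#'   table (much faster when only trial-level analyses are needed).
#' @param seed Integer seed; all randomness flows from this single seed.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_participants = 33,
                       n_blocks = 5,
                       n_trials_per_block = 96,
                       conditions = c("Stroop", "NoStroop"),
                       bias_amplitude_mean = c(Stroop = 1.9, NoStroop = -1.61),
                       bias_amplitude_sd = 8.5,
                       cross_condition_correlation = 0.7,
                       bias_tuning_width = 45,
                       cardinal_bias_amplitude = 5,
                       cardinal_bias_sign = c("repel", "attract"),
                       cardinal_bias_shape = c("sine", "linear"),
                       response_noise_sd = 8,
                       noise_sd_cardinal_modulation = 2,
                       swap_rate = 0.02,
                       outlier_rate = 0.01,
                       rt_intercept = 1.04,
                       rt_slope_per_degree = -0.88,
                       rt_condition_offset = -80,
                       rt_subject_sd = 0.15,
                       rt_slope_subject_sd = 0.3,
                       rt_noise_sd = 0.3,
                       rt_floor = 0.2,
                       trajectory_sample_rate = 60,
                       early_bias_amplitude = -4,
                       early_bias_peak_dissimilarity = 80,
                       early_bias_width = 40,
                       trajectory_jitter_sd = 3,
                       initial_angle_noise_sd = 15,
                       first_frame_agreement = 0.61,
                       second_frame_flip_rate = 0.43,
                       stroop_rt_mean = 0.64,
                       stroop_rt_sd = 0.12,
                       stroop_congruency_rt_effect = 0.04,
                       stroop_accuracy = 0.92,
                       stroop_congruency_acc_effect = 0.015,
                       nostroop_rt_mean = 0.38,
                       nostroop_rt_sd = 0.15,
                       generate_trajectories = TRUE,
                       seed = 1L) {
  cardinal_bias_sign <- match.arg(cardinal_bias_sign)
  cardinal_bias_shape <- match.arg(cardinal_bias_shape)

  cfg <- mget(setdiff(names(formals(sim_config)), c("cardinal_bias_sign", "cardinal_bias_shape")))
  cfg$cardinal_bias_sign <- cardinal_bias_sign
  cfg$cardinal_bias_shape <- cardinal_bias_shape

  chk <- function(ok, field, what) {
    if (!ok) stop(sprintf("invalid `%s`: %s", field, what), call. = FALSE)
  }
  pos_int <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
  num1 <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

  chk(pos_int(n_participants), "n_participants", "must be a positive integer")
  chk(pos_int(n_blocks), "n_blocks", "must be a positive integer")
  chk(pos_int(n_trials_per_block) && n_trials_per_block >= 2,
      "n_trials_per_block", "must be an integer >= 2")
  chk(is.character(conditions) && length(conditions) == 2 && !anyDuplicated(conditions),
      "conditions", "must be two distinct labels")
  chk(is.numeric(bias_amplitude_mean) && length(bias_amplitude_mean) %in% c(1, 2),
      "bias_amplitude_mean", "must be length 1 or 2")
  for (f in c("bias_amplitude_sd", "bias_tuning_width", "response_noise_sd",
              "noise_sd_cardinal_modulation", "rt_subject_sd", "rt_slope_subject_sd",
              "rt_noise_sd", "cardinal_bias_amplitude", "early_bias_width",
              "trajectory_jitter_sd", "initial_angle_noise_sd", "stroop_rt_sd",
              "nostroop_rt_sd")) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0, f, "must be a non-negative number")
  }
  chk(cfg$bias_tuning_width > 0, "bias_tuning_width", "must be positive")
  for (f in c("swap_rate", "outlier_rate", "first_frame_agreement",
              "second_frame_flip_rate", "stroop_accuracy")) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be a probability in [0, 1]")
  }
  chk(num1(cross_condition_correlation) && abs(cross_condition_correlation) <= 1,
      "cross_condition_correlation", "must be in [-1, 1]")
  chk(num1(trajectory_sample_rate) && trajectory_sample_rate > 0,
      "trajectory_sample_rate", "must be positive")
  for (f in c("rt_intercept", "rt_slope_per_degree", "rt_condition_offset",
              "rt_floor", "early_bias_amplitude", "early_bias_peak_dissimilarity",
              "stroop_rt_mean", "stroop_congruency_rt_effect",
              "stroop_congruency_acc_effect", "nostroop_rt_mean")) {
    chk(num1(cfg[[f]]), f, "must be a finite number")
  }
  chk(num1(seed) && is.finite(seed) && abs(seed) < 2^31, "seed", "must be a machine integer")
  chk(isTRUE(generate_trajectories) || isFALSE(generate_trajectories),
      "generate_trajectories", "must be TRUE or FALSE")

  if (length(bias_amplitude_mean) == 1) {
    bias_amplitude_mean <- rep(bias_amplitude_mean, 2)
  }
  if (!is.null(names(bias_amplitude_mean)) && all(nzchar(names(bias_amplitude_mean)))) {
    chk(all(conditions %in% names(bias_amplitude_mean)),
        "bias_amplitude_mean", "names must match `conditions`")
    bias_amplitude_mean <- bias_amplitude_mean[conditions]
  } else {
    names(bias_amplitude_mean) <- conditions
  }
  cfg$bias_amplitude_mean <- bias_amplitude_mean
  cfg$seed <- as.integer(seed)

  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_participants, "participants x",
      x$n_blocks * x$n_trials_per_block, "trials x 2 conditions\n")
  cat("  bias means (%):", paste(sprintf("%s=%.2f", names(x$bias_amplitude_mean),
                                         x$bias_amplitude_mean), collapse = ", "),
      " sd:", x$bias_amplitude_sd,
      " corr:", x$cross_condition_correlation, "\n")
  cat("  cardinal bias:", x$cardinal_bias_amplitude, "deg",
      x$cardinal_bias_sign, paste0("(", x$cardinal_bias_shape, ")"),
      " noise sd:", x$response_noise_sd, "deg\n")
  invisible(x)
}

# Cardinal anisotropy as a function of target direction (degrees).
# "sine": A sin(4 theta), smooth.
# "linear": sawtooth, discontinuous at the repelled axes.
cardinal_bias_fun <- function(theta, amplitude, sign = c("repel", "attract"),
                              shape = c("sine", "linear")) {
  sign <- match.arg(sign)
  shape <- match.arg(shape)
  if (shape == "sine") {
    s <- if (sign == "repel") 1 else -1
    return(s * amplitude * sin(4 * theta * pi / 180))
  }
  if (sign == "repel") {
    d <- ((theta + 45) %% 90) - 45 # signed distance to nearest cardinal
    amplitude * base::sign(d) * (1 - abs(d) / 45)
  } else {
    d <- (theta %% 90) - 45 # signed distance to nearest oblique
    amplitude * base::sign(d) * (1 - abs(d) / 45)
  }
}

# Derivative-of-Gaussian serial-bias shape in the signed previous-minus-
# current difference (degrees); positive amplitude attracts toward the
# previous stimulus.
dog_bias <- function(delta, amplitude, width) {
  amplitude * (delta / width) * exp(-(delta / width)^2)
}

# Convert a target measured asymmetry (percent) into the DoG amplitude in
# degrees that produces it in expectation, to first order: the per-trial
# probability of a toward error is Phi(b(D)/sd), and the DoG shape averaged
# over uniform dissimilarity has mean a*w*(1-exp(-(180/w)^2))/360.
asymmetry_to_dog_amplitude <- function(asym_pct, noise_sd, width) {
  sd_eff <- max(noise_sd, 1) # keep the map defined in the noiseless limit
  shape_mean <- width * (1 - exp(-(180 / width)^2)) / 360
  asym_pct / 100 * sd_eff * sqrt(pi / 2) / shape_mean
}

# Latent between-subject parameters implied by the measured-scale knobs:
# measured per-subject asymmetry = latent value + counting noise with
# variance 100^2/n_eff, so the latent SD and correlation are recovered by
# subtracting that variance (correlation capped at |1|).
latent_bias_params <- function(cfg) {
  n_eff <- cfg$n_blocks * (cfg$n_trials_per_block - 1)
  var_e <- 100^2 / n_eff
  var_obs <- cfg$bias_amplitude_sd^2
  var_lat <- max(var_obs - var_e, 1e-8)
  rho_lat <- cfg$cross_condition_correlation * var_obs / var_lat
  capped <- abs(rho_lat) > 1
  rho_lat <- max(-1, min(1, rho_lat))
  list(sd = sqrt(var_lat), correlation = rho_lat, capped = capped,
       counting_se = sqrt(var_e))
}

#' Simulate Stroop-task columns for one condition
#'
#' Generates word/color pairs with congruency-dependent response accuracy
#' and RT in the Stroop condition, or a fixed key press in the no-Stroop
#' condition. Used internally by [simulate_experiment()]; exported so the
#' congruency contrasts can be validated in isolation.
#'
#' @param config A [sim_config()].
#' @param n Number of trials.
#' @param stroop Logical; `TRUE` for the Stroop condition.
#' @return A `data.frame` with columns `stroop_word`, `stroop_color`,
#'   `stroop_response`, `stroop_rt`, `stroop_congruent`, `stroop_correct`.
#' @export
simulate_stroop_block <- function(config, n, stroop = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cols <- c("red", "green", "blue")
  keys <- c(red = "left", green = "down", blue = "right")
  word <- sample(cols, n, replace = TRUE)
  color <- sample(cols, n, replace = TRUE)
  congruent <- word == color
  if (stroop) {
    p <- config$stroop_accuracy +
      ifelse(congruent, 0.5, -0.5) * config$stroop_congruency_acc_effect
    p <- pmin(pmax(p, 0), 1)
    correct <- stats::runif(n) < p
    response <- keys[color]
    wrong <- vapply(color[!correct], function(cc) {
      sample(keys[setdiff(cols, cc)], 1)
    }, character(1))
    response[!correct] <- wrong
    rt <- config$stroop_rt_mean +
      ifelse(congruent, -0.5, 0.5) * config$stroop_congruency_rt_effect +
      stats::rnorm(n, 0, config$stroop_rt_sd)
    rt <- pmin(pmax(rt, 0.15), 1.2)
  } else {
    response <- rep("down", n)
    rt <- pmin(pmax(config$nostroop_rt_mean + stats::rnorm(n, 0, config$nostroop_rt_sd),
                    0.05), 1.2)
    correct <- response == keys[color]
  }
  data.frame(stroop_word = word, stroop_color = color,
             stroop_response = unname(response), stroop_rt = rt,
             stroop_congruent = congruent, stroop_correct = unname(correct))
}

#' Simulate a complete synthetic experiment
#'
#' Generates a per-trial table, an optional response-locked trajectory
#' table, and the injected ground truth, from a single seed. Targets are
#' i.i.d. uniform on \[0, 360); reports combine a dissimilarity-tuned serial
#' bias with stable per-subject amplitude correlated across conditions,
#' cardinal anisotropy, heteroscedastic wrapped noise, occasional swap
#' errors (report near the previous target) and uniform outliers. Report
#' RTs decrease linearly with dissimilarity. Trajectories interpolate from
#' a noisy first frame through an early bias lobe into the final report
#' (the last sample reproduces the report exactly).
#'
#' @param config A [sim_config()].
#' @return A list of class `"serial_experiment"` with elements `trials`
#'   (data.frame), `trajectories` (data.frame or `NULL`), and
#'   `ground_truth` (list: per-subject injected parameters and the
#'   realized latent distribution).
#' @examples
#' ex <- simulate_experiment(sim_config(n_participants = 2, n_blocks = 1,
#'                                      n_trials_per_block = 24, seed = 7))
#' head(ex$trials)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  n_cond <- cfg$n_blocks * cfg$n_trials_per_block
  P <- cfg$n_participants
  ids <- sprintf("s%02d", seq_len(P))

  lat <- latent_bias_params(cfg)
  # bivariate normal draw of latent per-subject asymmetries (percent)
  z1 <- stats::rnorm(P)
  z2 <- stats::rnorm(P)
  a1 <- cfg$bias_amplitude_mean[[1]] + lat$sd * z1
  a2 <- cfg$bias_amplitude_mean[[2]] +
    lat$sd * (lat$correlation * z1 + sqrt(1 - lat$correlation^2) * z2)
  asym_lat <- cbind(a1, a2)
  colnames(asym_lat) <- cfg$conditions

  sd_bar <- cfg$response_noise_sd + cfg$noise_sd_cardinal_modulation / 2
  dog_amp <- asymmetry_to_dog_amplitude(asym_lat, sd_bar, cfg$bias_tuning_width)

  rt_u <- stats::rnorm(P, 0, cfg$rt_subject_sd)
  rt_v <- stats::rnorm(P, 0, cfg$rt_slope_subject_sd)

  grid <- data.table::CJ(pp = seq_len(P), cond = seq_along(cfg$conditions),
                         block = seq_len(cfg$n_blocks),
                         k = seq_len(cfg$n_trials_per_block), sorted = TRUE)
  N <- nrow(grid)
  dt <- data.table::data.table(
    participant = ids[grid$pp],
    condition = cfg$conditions[grid$cond],
    block = grid$block,
    trial_index = (grid$block - 1L) * cfg$n_trials_per_block + grid$k,
    pp = grid$pp
  )
  dt[, `:=`(target = stats::runif(N) * 360)]
  dt[, prev_target := data.table::shift(target),
     by = c("participant", "condition", "block")]
  delta <- rep(NA_real_, N)
  ok <- !is.na(dt$prev_target)
  delta[ok] <- signed_diff(dt$prev_target[ok], dt$target[ok])
  dt[, delta := delta]

  amp_trial <- dog_amp[cbind(grid$pp, grid$cond)]
  serial_shift <- rep(0, N)
  serial_shift[ok] <- dog_bias(delta[ok], amp_trial[ok], cfg$bias_tuning_width)
  card_shift <- cardinal_bias_fun(dt$target, cfg$cardinal_bias_amplitude,
                                  cfg$cardinal_bias_sign, cfg$cardinal_bias_shape)
  noise_sd <- cfg$response_noise_sd +
    cfg$noise_sd_cardinal_modulation * (1 - cos(4 * dt$target * pi / 180)) / 2
  err <- serial_shift + card_shift + stats::rnorm(N, 0, noise_sd)
  report <- wrap_circle(dt$target + err)

  u_sw <- stats::runif(N)
  is_swap <- u_sw < cfg$swap_rate & !is.na(dt$prev_target)
  if (any(is_swap)) {
    report[is_swap] <- wrap_circle(dt$prev_target[is_swap] +
                                     stats::rnorm(sum(is_swap), 0, noise_sd[is_swap]))
  }
  is_out <- stats::runif(N) < cfg$outlier_rate
  if (any(is_out)) report[is_out] <- stats::runif(sum(is_out)) * 360
  dt[, report := report]
  dt[, error := signed_diff(report, target)]
  dt[, `:=`(gen_swap = is_swap & !is_out, gen_outlier = is_out)]

  absd <- ifelse(is.na(dt$delta), 90, abs(dt$delta))
  rt <- cfg$rt_intercept + rt_u[grid$pp] +
    ((cfg$rt_slope_per_degree + rt_v[grid$pp]) * absd +
       cfg$rt_condition_offset * (grid$cond == 1L)) / 1000 +
    stats::rnorm(N, 0, cfg$rt_noise_sd)
  dt[, report_rt := pmax(rt, cfg$rt_floor)]

  stroop <- vector("list", length(cfg$conditions))
  for (ci in seq_along(cfg$conditions)) {
    n_ci <- sum(grid$cond == ci)
    stroop[[ci]] <- simulate_stroop_block(cfg, n_ci, stroop = ci == 1L)
  }
  stroop_dt <- data.table::rbindlist(stroop)
  # stroop rows were generated condition-by-condition; invert the stable
  # by-condition ordering to align them with dt's row order
  stroop_full <- stroop_dt[order(order(grid$cond)), ]
  dt <- cbind(dt, stroop_full)
  dt[, is_practice := FALSE]

  trajectories <- NULL
  if (cfg$generate_trajectories) {
    trajectories <- simulate_trajectories(dt, cfg)
  }

  trials <- as.data.frame(dt[, c("participant", "condition", "block",
                                 "trial_index", "target", "report", "error",
                                 "report_rt", "stroop_word", "stroop_color",
                                 "stroop_response", "stroop_rt",
                                 "stroop_congruent", "stroop_correct",
                                 "is_practice", "gen_swap", "gen_outlier"),
                             with = FALSE])

  ground_truth <- list(
    per_subject = data.frame(
      participant = rep(ids, times = length(cfg$conditions)),
      condition = rep(cfg$conditions, each = P),
      asymmetry_pct = as.vector(asym_lat),
      dog_amplitude_deg = as.vector(dog_amp),
      rt_intercept_subj = rep(rt_u, times = length(cfg$conditions)),
      rt_slope_subj = rep(rt_v, times = length(cfg$conditions))
    ),
    latent_sd = lat$sd,
    latent_correlation = lat$correlation,
    latent_correlation_capped = lat$capped,
    counting_se = lat$counting_se,
    config = unclass(cfg)
  )

  structure(list(trials = trials, trajectories = trajectories,
                 ground_truth = ground_truth),
            class = "serial_experiment")
}

# Response-locked trajectory table for a simulated trial table.
# Toward-coded deviation path: early lobe (Gaussian in dissimilarity,
# Gaussian bump in normalized time) decaying into the final error, with
# angular jitter; the first two frames are overridden by the first-frame
# agreement and second-frame flip knobs, and the last frame reproduces the
# report exactly.
simulate_trajectories <- function(dt, cfg) {
  rate <- cfg$trajectory_sample_rate
  n_s <- pmax(3L, as.integer(round(dt$report_rt * rate)) + 1L)
  N <- nrow(dt)

  sgn <- sign(ifelse(is.na(dt$delta), 0, dt$delta))
  s_eff <- ifelse(sgn == 0, 1, sgn) # raw = toward path on unpaired trials
  t_fin <- dt$error * s_eff         # toward-coded final error
  absd <- ifelse(is.na(dt$delta), NA_real_, abs(dt$delta))
  lobe <- ifelse(is.na(absd), 0,
                 cfg$early_bias_amplitude *
                   exp(-(absd - cfg$early_bias_peak_dissimilarity)^2 /
                         (2 * cfg$early_bias_width^2)))

  # per-trial first/second frame draws
  fin_sign <- ifelse(t_fin == 0, sample(c(-1, 1), N, replace = TRUE), sign(t_fin))
  agree <- stats::runif(N) < cfg$first_frame_agreement
  s1 <- ifelse(agree, fin_sign, -fin_sign)
  d1 <- s1 * abs(stats::rnorm(N, 0, cfg$initial_angle_noise_sd))
  flip2 <- stats::runif(N) < cfg$second_frame_flip_rate & t_fin > 0

  tr <- data.table::data.table(
    row = rep(seq_len(N), n_s),
    k = sequence(n_s) - 1L
  )
  tr[, n_s := n_s[row]]
  tr[, u := k / (n_s - 1L)]
  tr[, time_from_start := u * dt$report_rt[row]]
  tr[, time_to_response := time_from_start - dt$report_rt[row]]

  base <- lobe[tr$row] * exp(-((tr$u - 0.3) / 0.25)^2) + t_fin[tr$row] * tr$u^4
  dev <- base + stats::rnorm(nrow(tr), 0, cfg$trajectory_jitter_sd)
  first <- tr$k == 0L
  dev[first] <- d1[tr$row[first]]
  second <- tr$k == 1L
  flip_here <- second & flip2[tr$row]
  dev[flip_here] <- -abs(dev[flip_here])
  keep_pos <- second & !flip2[tr$row] & t_fin[tr$row] > 0
  dev[keep_pos] <- abs(dev[keep_pos])
  last <- tr$k == tr$n_s - 1L
  dev[last] <- t_fin[tr$row[last]]

  ang <- wrap_circle(dt$target[tr$row] + dev * s_eff[tr$row])

  out <- data.table::data.table(
    participant = dt$participant[tr$row],
    condition = dt$condition[tr$row],
    trial_index = dt$trial_index[tr$row],
    time_from_start = tr$time_from_start,
    time_to_response = tr$time_to_response,
    pointing_angle = ang
  )
  as.data.frame(out)
}

#' @export
print.serial_experiment <- function(x, ...) {
  cat("<serial_experiment>", nrow(x$trials), "trials,",
      if (is.null(x$trajectories)) "no trajectories"
      else paste(nrow(x$trajectories), "trajectory samples"), "\n")
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Writes `trials.csv`, `trajectories.csv` (when present),
#' `ground_truth.json` and `config.yaml` into `dir`.
#'
#' @param x A `"serial_experiment"` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "serial_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(x$trials, file.path(dir, "trials.csv"))
  if (!is.null(x$trajectories)) {
    data.table::fwrite(x$trajectories, file.path(dir, "trajectories.csv"))
  }
  gt <- x$ground_truth
  gt$config$bias_amplitude_mean <- as.list(gt$config$bias_amplitude_mean)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  yaml::write_yaml(gt$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a trial table from CSV
#'
#' @param path CSV file with at least the columns `participant`,
#'   `condition`, `block`, `trial_index`, `target`, `report`, `report_rt`.
#' @return A `data.frame`; an `error` column is added (report minus target,
#'   wrapped) if absent.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- as.data.frame(data.table::fread(path))
  need <- c("participant", "condition", "block", "trial_index", "target",
            "report", "report_rt")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial table missing columns: ", paste(miss, collapse = ", "))
  if (!"error" %in% names(df)) df$error <- signed_diff(df$report, df$target)
  df
}

#' Read a trajectory table from CSV
#'
#' @param path CSV file with columns `participant`, `condition`,
#'   `trial_index`, `time_from_start`, `time_to_response`, `pointing_angle`.
#' @return A `data.frame`.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  df <- as.data.frame(data.table::fread(path))
  need <- c("participant", "condition", "trial_index", "time_from_start",
            "time_to_response", "pointing_angle")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trajectory table missing columns: ", paste(miss, collapse = ", "))
  df
}
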
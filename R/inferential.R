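#' Within-subject (Cousineau-Morey) confidence intervals
#'
#' Subject-centers a participant-by-condition matrix, rescales the
#' deviations by `sqrt(C/(C-1))`, and computes per-condition confidence
#' intervals from the adjusted standard errors, so that between-condition
#' differences can be read off the intervals in a repeated-measures
#' design. Rows with missing cells are removed listwise. With a single
#' condition the ordinary interval is returned (with a message).
#'
#' @param values Numeric matrix (participants x conditions), optionally
#'   with column names.
#' @param level Confidence level.
#' @return A `data.frame` with `condition`, `mean`, `lower`, `upper`,
#'   `se`, `n`.
#' @export
within_subject_ci <- function(values, level = 0.95) {
  values <- as.matrix(values)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  n <- nrow(values); C <- ncol(values)
  if (n < 2) stop("need at least 2 complete participants")
  conds <- colnames(values)
  if (is.null(conds)) conds <- paste0("cond", seq_len(C))
  means <- colMeans(values)
  if (C == 1) {
    message("single condition: ordinary confidence interval")
    se <- stats::sd(values[, 1]) / sqrt(n)
  } else {
    centered <- values - rowMeans(values) + mean(values)
    adj <- sqrt(C / (C - 1))
    se <- apply(centered, 2, stats::sd) / sqrt(n) * adj
  }
  q <- stats::qt((1 + level) / 2, n - 1)
  data.frame(condition = conds, mean = means, lower = means - q * se,
             upper = means + q * se, se = se, n = n, row.names = NULL)
}

#' Paired condition contrast
#'
#' Paired t-test between two within-subject measures with Cohen's d for
#' paired designs (mean difference over the SD of differences) and
#' within-subject confidence intervals for the two means.
#'
#' @param x,y Paired per-participant values (same participants, same
#'   order).
#' @param labels Length-2 condition labels.
#' @param level Confidence level.
#' @return A one-row `data.frame` with the two means and their
#'   within-subject CI bounds, `t`, `df`, `p`, `d`, `mean_diff`, `n`.
#' @export
paired_contrast <- function(x, y, labels = c("x", "y"), level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("paired contrast needs at least 2 complete pairs")
  tt <- stats::t.test(x, y, paired = TRUE, conf.level = level)
  dff <- x - y
  d <- mean(dff) / stats::sd(dff)
  ci <- within_subject_ci(cbind(x, y), level = level)
  data.frame(condition_1 = labels[1], condition_2 = labels[2],
             mean_1 = mean(x), lower_1 = ci$lower[1], upper_1 = ci$upper[1],
             mean_2 = mean(y), lower_2 = ci$lower[2], upper_2 = ci$upper[2],
             mean_diff = mean(dff), t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value, d = d, n = n)
}

#' Stroop congruency contrasts
#'
#' Per condition, contrasts congruent vs incongruent Stroop trials on
#' response time and accuracy (percent correct), paired across
#' participants. In the no-Stroop condition the response key is fixed, so
#' the contrast is expected to be null.
#'
#' @param trials Trial table with `stroop_congruent`, `stroop_rt`,
#'   `stroop_correct` (accuracy computed from `stroop_color` /
#'   `stroop_response` with the left/down/right = red/green/blue mapping
#'   if absent) and no practice trials (`is_practice` rows are dropped).
#' @return A `data.frame`, one row per condition x measure, with the
#'   congruent and incongruent means, t, df, p and d.
#' @export
stroop_congruency_contrast <- function(trials) {
  if (!"stroop_congruent" %in% names(trials)) {
    if (!all(c("stroop_word", "stroop_color") %in% names(trials))) {
      stop("missing Stroop congruency labels")
    }
    trials$stroop_congruent <- trials$stroop_word == trials$stroop_color
  }
  if (!"stroop_correct" %in% names(trials)) {
    keys <- c(red = "left", green = "down", blue = "right")
    trials$stroop_correct <- trials$stroop_response == keys[trials$stroop_color]
  }
  if ("is_practice" %in% names(trials)) trials <- trials[!trials$is_practice, ]

  out <- list()
  for (cond in unique(trials$condition)) {
    tc <- trials[trials$condition == cond, ]
    agg <- function(v, f) {
      a <- stats::aggregate(v ~ participant + stroop_congruent,
                            data = data.frame(v = v,
                                              participant = tc$participant,
                                              stroop_congruent = tc$stroop_congruent),
                            FUN = f)
      w <- stats::reshape(a, idvar = "participant", timevar = "stroop_congruent",
                          direction = "wide")
      w[stats::complete.cases(w), ]
    }
    for (meas in c("rt", "accuracy")) {
      v <- if (meas == "rt") tc$stroop_rt else 100 * tc$stroop_correct
      w <- agg(v, mean)
      pc <- paired_contrast(w[["v.TRUE"]], w[["v.FALSE"]],
                            labels = c("congruent", "incongruent"))
      out[[length(out) + 1]] <- cbind(data.frame(condition = cond, measure = meas),
                                      pc)
    }
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Condition contrast on per-participant serial-bias estimates
#'
#' Paired t-test of the per-participant asymmetries between the two
#' conditions, one-sample tests of each condition against zero, the
#' cross-condition correlation, and within-subject CIs. Participants
#' present in only one condition are dropped (logged).
#'
#' @param estimates A `"subject_bias"` table from [per_subject_bias()],
#'   or any data.frame with `participant`, `condition`, `asymmetry`.
#' @return A list with `contrast` (a [paired_contrast()] row),
#'   `one_sample` (per condition t-tests vs 0), `correlation`
#'   (estimate, t, df, p, n), `wide` (the paired matrix).
#' @export
condition_bias_contrast <- function(estimates) {
  conds <- unique(estimates$condition)
  if (length(conds) != 2) stop("exactly two conditions required")
  wide <- merge(estimates[estimates$condition == conds[1],
                          c("participant", "asymmetry")],
                estimates[estimates$condition == conds[2],
                          c("participant", "asymmetry")],
                by = "participant")
  names(wide)[2:3] <- conds
  n_drop <- length(unique(estimates$participant)) - nrow(wide)
  if (n_drop > 0) message(n_drop, " unmatched participant(s) dropped from contrast")
  if (nrow(wide) < 2) stop("fewer than 2 participants with both conditions")

  contrast <- paired_contrast(wide[[conds[1]]], wide[[conds[2]]], labels = conds)
  one_sample <- do.call(rbind, lapply(conds, function(cc) {
    tt <- stats::t.test(wide[[cc]])
    data.frame(condition = cc, mean = mean(wide[[cc]]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n = nrow(wide))
  }))
  ct <- stats::cor.test(wide[[conds[1]]], wide[[conds[2]]])
  correlation <- list(estimate = unname(ct$estimate),
                      t = unname(ct$statistic), df = unname(ct$parameter),
                      p = ct$p.value, n = nrow(wide))
  list(contrast = contrast, one_sample = one_sample,
       correlation = correlation, wide = wide)
}

#' Response time as a function of current-vs-previous dissimilarity
#'
#' Estimates the RT slope (ms per degree of dissimilarity), the condition
#' offset (ms) and their interaction. The default two-stage estimator
#' fits per-participant ordinary least squares and tests the coefficients
#' across participants; `method = "lmer"` fits a single hierarchical
#' model with random intercepts and slopes (requires lme4). The
#' condition factor is coded 0/1 in alphabetical order of the labels
#' (the reported `condition_coding` states which).
#'
#' @param trials Trial table; [serial_prep()] is applied if needed. Rows
#'   without a defined dissimilarity or with RTs outside
#'   `(0, rt_max]` seconds are excluded.
#' @param method `"two_stage"` or `"lmer"`.
#' @param min_trials Participants with fewer valid trials are excluded
#'   (logged).
#' @param rt_max Upper RT bound in seconds.
#' @return A list with `estimates` (term, estimate, se, t, df, p, ci),
#'   `per_participant` coefficients (two-stage only), `method`,
#'   `condition_coding`, `n_participants`, `n_excluded`.
#' @export
rt_dissimilarity_model <- function(trials, method = c("two_stage", "lmer"),
                                   min_trials = 10, rt_max = 5) {
  method <- match.arg(method)
  if (!"dissimilarity" %in% names(trials)) trials <- serial_prep(trials)
  ok <- !is.na(trials$dissimilarity) & !is.na(trials$report_rt) &
    trials$report_rt > 0 & trials$report_rt <= rt_max
  d <- trials[ok, ]
  conds <- sort(unique(d$condition))
  if (length(conds) != 2) stop("exactly two conditions required")
  d$rt_ms <- d$report_rt * 1000
  d$cond01 <- as.numeric(d$condition == conds[2])
  coding <- sprintf("%s = 0, %s = 1", conds[1], conds[2])

  if (method == "lmer") {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      stop("method = 'lmer' requires the lme4 package")
    }
    fit <- lme4::lmer(rt_ms ~ dissimilarity * cond01 +
                        (1 + dissimilarity + cond01 | participant),
                      data = d, REML = TRUE)
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    tv <- cf / se
    est <- data.frame(term = c("intercept", "slope_ms_per_deg", "condition_offset_ms",
                               "interaction_ms_per_deg"),
                      estimate = unname(cf), se = unname(se), t = unname(tv),
                      df = NA_real_, p = NA_real_,
                      lower = unname(cf - 1.96 * se),
                      upper = unname(cf + 1.96 * se))
    return(list(estimates = est, per_participant = NULL, method = method,
                condition_coding = coding,
                n_participants = length(unique(d$participant)), n_excluded = 0))
  }

  counts <- table(d$participant)
  excl <- names(counts)[counts < min_trials]
  if (length(excl)) {
    message(length(excl), " participant(s) excluded from RT model (< ",
            min_trials, " valid trials)")
    d <- d[!d$participant %in% excl, ]
  }
  per <- lapply(split(d, d$participant), function(g) {
    if (length(unique(g$cond01)) < 2) return(NULL)
    cf <- stats::coef(stats::lm(rt_ms ~ dissimilarity * cond01, data = g))
    if (any(is.na(cf))) return(NULL)
    data.frame(participant = g$participant[1], intercept = cf[1],
               slope_ms_per_deg = cf[2], condition_offset_ms = cf[3],
               interaction_ms_per_deg = cf[4], row.names = NULL)
  })
  per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  if (is.null(per) || nrow(per) < 2) stop("fewer than 2 participants with full designs")
  est <- do.call(rbind, lapply(c("intercept", "slope_ms_per_deg",
                                 "condition_offset_ms", "interaction_ms_per_deg"),
                               function(term) {
    v <- per[[term]]
    tt <- stats::t.test(v)
    data.frame(term = term, estimate = mean(v),
               se = stats::sd(v) / sqrt(length(v)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, lower = tt$conf.int[1], upper = tt$conf.int[2])
  }))
  list(estimates = est, per_participant = per, method = method,
       condition_coding = coding, n_participants = nrow(per),
       n_excluded = length(excl))
}
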
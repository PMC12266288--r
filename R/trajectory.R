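#' Response-locked trajectory bias surface
#'
#' Estimates the toward-coded pointing bias as a smooth function of time
#' to response and current-vs-previous dissimilarity, per condition, on an
#' `n_grid` x `n_grid` grid (Gaussian kernels in both dimensions). The
#' time axis is truncated to the latest onset at which every observer
#' still has at least `min_trials` trials covering that time. Each
#' observer contributes a kernel-weighted mean surface; the group surface
#' is the across-observer mean with a per-cell one-sample t-test, and
#' contiguous significant same-sign cells are grouped into clusters
#' (4-connected, pointwise threshold, no cluster-mass correction).
#'
#' @param trajectories Trajectory table (see [read_trajectories()]).
#' @param trials Trial table; [serial_prep()] is applied if needed. Only
#'   trials valid for serial analysis enter the surface.
#' @param time_sd Time smoothing kernel SD in ms.
#' @param diss_sd Dissimilarity kernel SD in degrees.
#' @param n_grid Grid points per axis.
#' @param min_trials Per-observer trial floor defining the time support.
#' @param min_eff_n Per-observer, per-cell effective-trial floor below
#'   which a cell is masked (`NA`), never zeroed.
#' @param value `"degrees"` (mean toward-coded deviation) or `"percent"`
#'   (sign asymmetry of the deviation).
#' @param alpha Pointwise significance level.
#' @return A list of class `"bias_surface_set"`: per condition a list with
#'   `bias`, `t`, `p`, `significant` matrices, `clusters` (label matrix)
#'   and `cluster_summary` (sign, size, peak location/statistic); plus the
#'   shared `time_grid` (ms, non-positive), `dissimilarity_grid`, the
#'   time-support bound `support_ms`, and the parameters.
#' @export
trajectory_bias_surface <- function(trajectories, trials, time_sd = 120,
                                    diss_sd = 20, n_grid = 90,
                                    min_trials = 20, min_eff_n = 5,
                                    value = c("degrees", "percent"),
                                    alpha = 0.05) {
  value <- match.arg(value)
  if (!"use_serial" %in% names(trials)) trials <- serial_prep(trials)
  info <- trials[trials$use_serial,
                 c("participant", "condition", "trial_index", "target",
                   "delta", "dissimilarity")]
  tr <- data.table::as.data.table(trajectories)
  tr <- merge(tr, data.table::as.data.table(info),
              by = c("participant", "condition", "trial_index"))
  if (nrow(tr) == 0) stop("no valid trials shared between trajectories and trials")
  tr[, dev := toward_code(signed_diff(pointing_angle, target), delta)]
  tr[, ttr_ms := time_to_response * 1000]

  # trial-level durations and the common time support
  trial_tab <- tr[, list(duration = -min(ttr_ms), dissimilarity = dissimilarity[1]),
                  by = c("participant", "condition", "trial_index")]
  bounds <- trial_tab[, {
    d <- sort(duration, decreasing = TRUE)
    if (length(d) < min_trials) {
      stop(sprintf("observer %s (%s) has %d valid trials (< min_trials = %d)",
                   participant[1], condition[1], length(d), min_trials))
    }
    list(bound = d[min_trials])
  }, by = c("participant", "condition")]
  support <- min(bounds$bound)
  if (!is.finite(support) || support <= 0) stop("no common supported time range")

  tg <- seq(-support, 0, length.out = n_grid)
  dg <- seq(0, 180, length.out = n_grid)

  conds <- unique(info$condition)
  participants <- sort(unique(info$participant))
  P <- length(participants)
  res <- list()
  for (cond in conds) {
    arr <- array(NA_real_, c(n_grid, n_grid, P))
    for (pi in seq_len(P)) {
      g <- tr[participant == participants[pi] & condition == cond]
      if (nrow(g) == 0) next
      x <- if (value == "degrees") g$dev else 100 * sign(g$dev)
      Wt <- exp(-(outer(tg, g$ttr_ms, `-`))^2 / (2 * time_sd^2))
      Wd <- exp(-(outer(g$dissimilarity, dg, `-`))^2 / (2 * diss_sd^2))
      num <- Wt %*% (Wd * x)
      den <- Wt %*% Wd
      s <- num / den
      gt <- trial_tab[participant == participants[pi] & condition == cond]
      It <- outer(tg, gt$duration, function(t, D) as.numeric(D >= -t))
      Wdt <- exp(-(outer(gt$dissimilarity, dg, `-`))^2 / (2 * diss_sd^2))
      eff <- It %*% Wdt
      s[eff < min_eff_n] <- NA_real_
      arr[, , pi] <- s
    }
    # cells missing for any observer stay NA (no na.rm): masked, never zeroed
    m <- rowMeans(arr, dims = 2)
    sdv <- sqrt((rowSums(arr^2, dims = 2) - P * m^2) / (P - 1))
    tt <- m / (sdv / sqrt(P))
    p <- 2 * stats::pt(-abs(tt), P - 1)
    sig <- !is.na(p) & p < alpha
    sgn_mat <- matrix(0L, n_grid, n_grid)
    sgn_mat[sig] <- ifelse(m[sig] > 0, 1L, -1L)
    cl <- label_clusters(sgn_mat)
    summ <- summarize_clusters(cl, tt, tg, dg, p)
    res[[cond]] <- list(bias = m, t = tt, p = p, significant = sig,
                        clusters = cl, cluster_summary = summ)
  }
  structure(list(conditions = res, time_grid = tg, dissimilarity_grid = dg,
                 support_ms = support, value = value,
                 params = list(time_sd = time_sd, diss_sd = diss_sd,
                               n_grid = n_grid, min_trials = min_trials,
                               min_eff_n = min_eff_n, alpha = alpha)),
            class = "bias_surface_set")
}

# label 4-connected components of same-sign significant cells
label_clusters <- function(sgn_mat) {
  nr <- nrow(sgn_mat); nc <- ncol(sgn_mat)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (sgn_mat[i, j] != 0L && lab[i, j] == 0L) {
        nxt <- nxt + 1L
        s <- sgn_mat[i, j]
        stack <- matrix(c(i, j), ncol = 2)
        lab[i, j] <- nxt
        while (nrow(stack) > 0) {
          cur <- stack[nrow(stack), ]
          stack <- stack[-nrow(stack), , drop = FALSE]
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            ii <- cur[1] + d[1]; jj <- cur[2] + d[2]
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                sgn_mat[ii, jj] == s && lab[ii, jj] == 0L) {
              lab[ii, jj] <- nxt
              stack <- rbind(stack, c(ii, jj))
            }
          }
        }
      }
    }
  }
  lab
}

summarize_clusters <- function(lab, tstat, tg, dg, p) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0) {
    return(data.frame(cluster = integer(0), sign = integer(0),
                      n_cells = integer(0), peak_time_ms = numeric(0),
                      peak_dissimilarity = numeric(0), peak_t = numeric(0),
                      peak_p = numeric(0)))
  }
  rows <- lapply(ids, function(id) {
    cells <- which(lab == id, arr.ind = TRUE)
    tv <- tstat[cells]
    k <- which.max(abs(tv))
    data.frame(cluster = id, sign = as.integer(sign(tv[k])),
               n_cells = nrow(cells),
               peak_time_ms = tg[cells[k, 1]],
               peak_dissimilarity = dg[cells[k, 2]],
               peak_t = tv[k], peak_p = p[cells[k, 1], cells[k, 2]])
  })
  do.call(rbind, rows)
}

#' @export
print.bias_surface_set <- function(x, ...) {
  cat(sprintf("<bias_surface_set> %d x %d grid, support to %.0f ms, value = %s\n",
              x$params$n_grid, x$params$n_grid, x$support_ms, x$value))
  for (cond in names(x$conditions)) {
    cs <- x$conditions[[cond]]$cluster_summary
    cat(sprintf("  %s: %d significant cluster(s)\n", cond, nrow(cs)))
    if (nrow(cs)) {
      for (i in seq_len(nrow(cs))) {
        cat(sprintf("    %s cluster, %d cells, peak t = %.2f at %.0f ms / %.0f deg\n",
                    if (cs$sign[i] > 0) "attractive" else "repulsive",
                    cs$n_cells[i], cs$peak_t[i], cs$peak_time_ms[i],
                    cs$peak_dissimilarity[i]))
      }
    }
  }
  invisible(x)
}

#' Heat map of a trajectory bias surface
#'
#' @param x A `"bias_surface_set"`.
#' @param condition Condition to plot (default: first).
#' @param ... Passed to [graphics::image()].
#' @export
plot.bias_surface_set <- function(x, condition = names(x$conditions)[1], ...) {
  s <- x$conditions[[condition]]
  z <- s$bias
  lim <- max(abs(z), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(65)
  graphics::image(x$time_grid, x$dissimilarity_grid, z, zlim = c(-lim, lim),
                  col = pal, xlab = "Time to response (ms)",
                  ylab = "Dissimilarity (deg)",
                  main = paste("Bias surface:", condition), ...)
  if (any(s$significant, na.rm = TRUE)) {
    graphics::contour(x$time_grid, x$dissimilarity_grid,
                      matrix(as.numeric(s$significant), nrow(z), ncol(z)),
                      levels = 0.5, add = TRUE, drawlabels = FALSE, lty = 2)
  }
  invisible(x)
}

#' First/second/last-frame bias signs per trial
#'
#' Extracts the toward-coded pointing deviation at the first, second and
#' last recorded sample of each valid trial and codes its sign (+1
#' attractive, -1 repulsive, 0 on the boundary).
#'
#' @inheritParams trajectory_bias_surface
#' @return A `data.frame` with `participant`, `condition`, `trial_index`,
#'   `first_sign`, `second_sign` (`NA` for single-sample trials),
#'   `last_sign`, `n_samples`.
#' @export
frame_bias <- function(trajectories, trials) {
  if (!"use_serial" %in% names(trials)) trials <- serial_prep(trials)
  info <- trials[trials$use_serial,
                 c("participant", "condition", "trial_index", "target", "delta")]
  tr <- data.table::as.data.table(trajectories)
  tr <- merge(tr, data.table::as.data.table(info),
              by = c("participant", "condition", "trial_index"))
  tr[, dev := toward_code(signed_diff(pointing_angle, target), delta)]
  fb <- tr[order(time_from_start),
           list(first_sign = sign(dev[1]),
                second_sign = if (.N >= 2) sign(dev[2]) else NA_real_,
                last_sign = sign(dev[.N]),
                n_samples = .N),
           by = c("participant", "condition", "trial_index")]
  as.data.frame(fb)
}

#' First-frame bias sign conditioned on the final bias sign
#'
#' For each participant, condition and final-frame sign stratum, computes
#' the mean first-frame sign, tests it against zero across participants,
#' and contrasts the overall mean first-frame sign between conditions
#' (paired).
#'
#' @param frames Frame-sign table from [frame_bias()].
#' @return A list with `strata` (per participant cell means),
#'   `strata_tests` (per condition x final-sign one-sample t-tests) and
#'   `condition_contrast` (a [paired_contrast()] on per-participant mean
#'   first-frame signs).
#' @export
first_frame_sign_analysis <- function(frames) {
  fb <- frames[frames$first_sign != 0 & frames$last_sign != 0 &
                 !is.na(frames$first_sign) & !is.na(frames$last_sign), ]
  strata <- stats::aggregate(first_sign ~ participant + condition + last_sign,
                             data = fb, FUN = mean)
  names(strata)[names(strata) == "first_sign"] <- "mean_first_sign"

  tests <- list()
  for (cond in unique(strata$condition)) {
    for (ls in c(1, -1)) {
      v <- strata$mean_first_sign[strata$condition == cond & strata$last_sign == ls]
      if (length(v) >= 2) {
        tt <- stats::t.test(v)
        tests[[length(tests) + 1]] <- data.frame(
          condition = cond, final_sign = ls, mean = mean(v),
          t = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value, n = length(v))
      }
    }
  }
  strata_tests <- do.call(rbind, tests)

  overall <- stats::aggregate(first_sign ~ participant + condition,
                              data = fb, FUN = mean)
  wide <- stats::reshape(overall, idvar = "participant", timevar = "condition",
                         direction = "wide")
  cc <- NULL
  if (ncol(wide) == 3) {
    wide <- wide[stats::complete.cases(wide), ]
    conds <- sub("^first_sign\\.", "", names(wide)[-1])
    if (nrow(wide) >= 2) {
      cc <- paired_contrast(wide[[2]], wide[[3]], labels = conds)
    }
  }
  list(strata = strata, strata_tests = strata_tests, condition_contrast = cc)
}

#' Does the first-frame sign predict the last-frame sign?
#'
#' Two-stage logistic model: per participant, a logistic regression of the
#' final-frame sign on the first-frame sign; the slopes are then tested
#' against zero across participants. Participants whose first-frame signs
#' are constant cannot contribute a slope and are dropped (logged);
#' slopes diverging under complete separation are capped at `cap`.
#'
#' @param frames Frame-sign table from [frame_bias()].
#' @param cap Absolute bound on per-participant slopes.
#' @return A list with `slopes` (per participant), `mean_slope`, `t`,
#'   `df`, `p`, `n_capped`, `n_dropped`.
#' @export
first_last_sign_model <- function(frames, cap = 10) {
  fb <- frames[frames$first_sign != 0 & frames$last_sign != 0 &
                 !is.na(frames$first_sign) & !is.na(frames$last_sign), ]
  parts <- unique(fb$participant)
  slopes <- rep(NA_real_, length(parts))
  capped <- logical(length(parts))
  for (i in seq_along(parts)) {
    g <- fb[fb$participant == parts[i], ]
    if (length(unique(g$first_sign)) < 2) next
    fit <- suppressWarnings(
      stats::glm((last_sign > 0) ~ first_sign, family = stats::binomial(), data = g))
    b <- unname(stats::coef(fit)[2])
    if (!is.finite(b)) next
    if (abs(b) > cap) {
      b <- sign(b) * cap
      capped[i] <- TRUE
    }
    slopes[i] <- b
  }
  dropped <- is.na(slopes)
  if (any(dropped)) {
    message(sum(dropped), " participant(s) dropped from first/last sign model ",
            "(constant first-frame sign)")
  }
  sl <- slopes[!dropped]
  if (length(sl) < 2) stop("fewer than 2 participants with both first-frame signs")
  tt <- stats::t.test(sl)
  list(slopes = data.frame(participant = parts[!dropped], slope = sl,
                           capped = capped[!dropped]),
       mean_slope = mean(sl), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       n_capped = sum(capped[!dropped]), n_dropped = sum(dropped))
}

#' Fraction of attractive-ending trials already repulsive at the second frame
#'
#' Among trials whose final frame shows an attractive (toward) bias,
#' computes the percentage whose second recorded frame deviates away from
#' the previous stimulus. Single-sample trials are skipped and counted.
#'
#' @param frames Frame-sign table from [frame_bias()].
#' @return A list with `percent`, `n_trials`, `n_repulsive_second`,
#'   `n_skipped`.
#' @export
second_frame_repulsive_fraction <- function(frames) {
  att <- frames[!is.na(frames$last_sign) & frames$last_sign > 0, ]
  skipped <- sum(is.na(att$second_sign))
  att <- att[!is.na(att$second_sign), ]
  if (nrow(att) == 0) stop("no attractive-ending trials with a second frame")
  n_rep <- sum(att$second_sign < 0)
  list(percent = 100 * n_rep / nrow(att), n_trials = nrow(att),
       n_repulsive_second = n_rep, n_skipped = skipped)
}
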
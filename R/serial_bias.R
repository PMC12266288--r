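#' Density-asymmetry serial-bias statistic
#'
#' Measures how much more probability mass of toward-coded response errors
#' lies on the positive (toward the previous stimulus) than on the negative
#' side, normalized by the total mass and scaled to percent:
#' `100 * (mass_toward - mass_away) / (mass_toward + mass_away)`. With unit
#' weights this is the signed-count asymmetry `100 (n+ - n-)/(n+ + n-)`.
#' +100 means every error was toward the previous stimulus, -100 every
#' error away from it. The statistic ignores error magnitudes entirely.
#' Exact zeros (and `NA`s) carry no toward/away information and are
#' dropped.
#'
#' @param toward_errors Toward-coded signed errors in degrees (positive =
#'   toward the previous stimulus).
#' @param weights Optional non-negative weights, one per error.
#' @param method `"count"` (the definition above) or `"kde"`, a
#'   sensitivity variant that integrates a Gaussian kernel density
#'   estimate on each side of zero instead of counting.
#' @return A list of class `"bias_estimate"` with `asymmetry` (percent),
#'   `n_toward`, `n_away`, `method`.
#' @examples
#' density_asymmetry(c(1, 2, 3))$asymmetry   # 100
#' density_asymmetry(c(2, 3, -1))$asymmetry  # 33.33
#' @export
density_asymmetry <- function(toward_errors, weights = NULL,
                              method = c("count", "kde")) {
  method <- match.arg(method)
  e <- toward_errors
  if (is.null(weights)) weights <- rep(1, length(e))
  if (length(weights) != length(e)) stop("weights must match errors in length")
  if (any(weights < 0, na.rm = TRUE)) stop("weights must be non-negative")
  keep <- !is.na(e) & !is.na(weights) & e != 0
  e <- e[keep]; w <- weights[keep]
  if (length(e) == 0 || sum(w) == 0) {
    stop("undefined asymmetry: no nonzero toward-coded errors")
  }
  n_tow <- sum(e > 0)
  n_away <- sum(e < 0)
  if (method == "count") {
    mp <- sum(w[e > 0]); mn <- sum(w[e < 0])
    asym <- 100 * (mp - mn) / (mp + mn)
  } else {
    d <- stats::density(e, weights = w / sum(w), n = 1024)
    mp <- sum(d$y[d$x > 0]); mn <- sum(d$y[d$x < 0])
    asym <- 100 * (mp - mn) / (mp + mn)
  }
  structure(list(asymmetry = asym, n_toward = n_tow, n_away = n_away,
                 method = method),
            class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf("<bias_estimate> %.2f%% (%d toward, %d away, %s)\n",
              x$asymmetry, x$n_toward, x$n_away, x$method))
  invisible(x)
}

#' Mean toward-coded error
#'
#' Companion magnitude-sensitive measure to [density_asymmetry()]: the
#' arithmetic mean of toward-coded errors, in degrees, same sign
#' convention.
#'
#' @param toward_errors Toward-coded signed errors in degrees.
#' @return Mean error in degrees.
#' @export
mean_error_bias <- function(toward_errors) {
  e <- toward_errors[!is.na(toward_errors)]
  if (length(e) == 0) stop("undefined mean bias: no errors")
  mean(e)
}

#' Rolling density asymmetry over dissimilarity
#'
#' Continuous estimate of the asymmetry as a function of the
#' current-vs-previous dissimilarity: at each grid point the asymmetry is
#' computed with Gaussian weights
#' `exp(-(|D_i| - d)^2 / (2 kernel_sd^2))`. Grid points whose effective n
#' (sum of weights) falls below `min_eff_n` are flagged unsupported.
#'
#' @param toward_errors Toward-coded signed errors in degrees.
#' @param dissimilarities Absolute current-vs-previous differences, 0-180.
#' @param kernel_sd Gaussian kernel SD in degrees.
#' @param grid Dissimilarity grid, within \[0, 180\].
#' @param min_eff_n Support floor on the per-point effective n.
#' @return A `data.frame` of class `"bias_curve"` with columns
#'   `dissimilarity`, `asymmetry`, `eff_n`, `supported`; unsupported or
#'   undefined points carry `NA` asymmetry.
#' @export
rolling_asymmetry <- function(toward_errors, dissimilarities, kernel_sd = 20,
                              grid = seq(0, 180, by = 2), min_eff_n = 5) {
  if (!is.numeric(kernel_sd) || kernel_sd <= 0) stop("kernel_sd must be positive")
  if (any(grid < 0 | grid > 180)) stop("grid must lie within [0, 180]")
  keep <- !is.na(toward_errors) & !is.na(dissimilarities) & toward_errors != 0
  e <- toward_errors[keep]
  d <- abs(dissimilarities[keep])
  s <- sign(e)
  asym <- eff <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    w <- exp(-(d - grid[i])^2 / (2 * kernel_sd^2))
    sw <- sum(w)
    eff[i] <- sw
    if (sw > 0) asym[i] <- 100 * sum(w * s) / sw
  }
  supported <- !is.na(eff) & eff >= min_eff_n
  asym[!supported] <- NA_real_
  out <- data.frame(dissimilarity = grid, asymmetry = asym, eff_n = eff,
                    supported = supported)
  attr(out, "kernel_sd") <- kernel_sd
  class(out) <- c("bias_curve", "data.frame")
  out
}

#' Pair trials with their predecessors and toward-code errors
#'
#' Adds the serial-analysis columns to a trial table: the previous target
#' within the same participant, condition and block, the signed
#' previous-minus-current difference `delta` and its absolute value
#' `dissimilarity`, the toward-coded (corrected, if available) error, and
#' a `use_serial` flag. Excluded from serial analysis are the first trial
#' of each block, trials with `delta == 0`, outlier trials, and the trial
#' following an outlier (the outlier breaks the chain).
#'
#' @param trials Trial table with `participant`, `condition`, `block`,
#'   `trial_index`, `target`, and `corrected_error` (from
#'   [correct_anisotropy()]) or `error`.
#' @return `trials` with added columns `prev_target`, `delta`,
#'   `dissimilarity`, `toward_error`, `use_serial`.
#' @export
serial_prep <- function(trials) {
  need <- c("participant", "condition", "block", "trial_index", "target")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table missing columns: ", paste(miss, collapse = ", "))
  err_col <- if ("corrected_error" %in% names(trials)) "corrected_error" else "error"
  if (!err_col %in% names(trials)) stop("no `corrected_error` or `error` column")
  out_flag <- if ("is_outlier" %in% names(trials)) trials$is_outlier else
    rep(FALSE, nrow(trials))
  out_flag[is.na(out_flag)] <- FALSE

  dt <- data.table::as.data.table(trials)
  ord <- order(dt$participant, dt$condition, dt$block, dt$trial_index)
  dt <- dt[ord]
  out_flag <- out_flag[ord]
  dt[, prev_target := data.table::shift(target),
     by = c("participant", "condition", "block")]
  prev_out <- data.table::shift(out_flag)
  first_of_block <- is.na(dt$prev_target)
  prev_out[first_of_block] <- FALSE

  delta <- rep(NA_real_, nrow(dt))
  okp <- !first_of_block
  delta[okp] <- signed_diff(dt$prev_target[okp], dt$target[okp])
  dt[, delta := delta]
  dt[, dissimilarity := abs(delta)]
  dt[, toward_error := toward_code(dt[[err_col]], delta)]
  dt[, use_serial := !first_of_block & !is.na(delta) & delta != 0 &
       !out_flag & !prev_out & !is.na(toward_error)]
  as.data.frame(dt)
}

#' Per-participant serial-bias estimates
#'
#' Computes the density asymmetry (and mean toward-coded error) for each
#' participant and condition from a prepared trial table, plus the
#' cross-condition correlation of the per-participant asymmetries.
#'
#' @param trials Trial table; [serial_prep()] is applied if its columns
#'   are absent.
#' @param ... Passed to [density_asymmetry()].
#' @return A `data.frame` with `participant`, `condition`, `asymmetry`,
#'   `mean_error`, `n_toward`, `n_away`, `n_used`. When both conditions
#'   are available for at least 3 participants, the cross-condition
#'   correlation (`estimate`, `p`, `n`) is attached as
#'   `attr(, "correlation")`; otherwise the attribute is `NULL` and a
#'   message is logged.
#' @export
per_subject_bias <- function(trials, ...) {
  if (!"use_serial" %in% names(trials)) trials <- serial_prep(trials)
  use <- trials[trials$use_serial, , drop = FALSE]
  grp <- interaction(use$participant, use$condition, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(use)), grp), function(ix) {
    da <- density_asymmetry(use$toward_error[ix], ...)
    data.frame(participant = use$participant[ix[1]],
               condition = use$condition[ix[1]],
               asymmetry = da$asymmetry,
               mean_error = mean_error_bias(use$toward_error[ix]),
               n_toward = da$n_toward, n_away = da$n_away,
               n_used = length(ix))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$participant, out$condition), , drop = FALSE]
  rownames(out) <- NULL

  conds <- unique(out$condition)
  corr <- NULL
  if (length(conds) == 2) {
    wide <- merge(out[out$condition == conds[1], c("participant", "asymmetry")],
                  out[out$condition == conds[2], c("participant", "asymmetry")],
                  by = "participant")
    if (nrow(wide) >= 3) {
      ct <- stats::cor.test(wide$asymmetry.x, wide$asymmetry.y)
      corr <- list(estimate = unname(ct$estimate), p = ct$p.value, n = nrow(wide))
    } else {
      message("cross-condition correlation undefined: fewer than 3 complete participants")
    }
  }
  attr(out, "correlation") <- corr
  class(out) <- c("subject_bias", "data.frame")
  out
}

#' Group-level bias curves with pointwise tests
#'
#' Computes per-participant rolling asymmetry curves on a common
#' dissimilarity grid and, per condition, the across-participant mean with
#' a one-sample t-test at each grid point (p < alpha flags significance,
#' uncorrected).
#'
#' @inheritParams per_subject_bias
#' @param kernel_sd Rolling kernel SD in degrees.
#' @param grid Dissimilarity grid.
#' @param min_eff_n Per-participant support floor per grid point.
#' @param alpha Pointwise significance level.
#' @return A `data.frame` with `condition`, `dissimilarity`, `mean`, `t`,
#'   `df`, `p`, `significant`, `n`; points where fewer than 3 participants
#'   are supported carry `NA` tests.
#' @export
bias_curve_tests <- function(trials, kernel_sd = 20, grid = seq(0, 180, by = 2),
                             min_eff_n = 5, alpha = 0.05) {
  if (!"use_serial" %in% names(trials)) trials <- serial_prep(trials)
  use <- trials[trials$use_serial, , drop = FALSE]
  out <- list()
  for (cond in unique(use$condition)) {
    uc <- use[use$condition == cond, , drop = FALSE]
    curves <- vapply(split(seq_len(nrow(uc)), uc$participant), function(ix) {
      rolling_asymmetry(uc$toward_error[ix], uc$dissimilarity[ix],
                        kernel_sd = kernel_sd, grid = grid,
                        min_eff_n = min_eff_n)$asymmetry
    }, numeric(length(grid)))
    curves <- matrix(curves, nrow = length(grid))
    n_ok <- rowSums(!is.na(curves))
    m <- rowMeans(curves, na.rm = TRUE)
    sdv <- apply(curves, 1, stats::sd, na.rm = TRUE)
    tt <- ifelse(n_ok >= 3, m / (sdv / sqrt(n_ok)), NA_real_)
    df <- n_ok - 1
    p <- 2 * stats::pt(-abs(tt), df)
    out[[cond]] <- data.frame(condition = cond, dissimilarity = grid,
                              mean = ifelse(n_ok > 0, m, NA_real_),
                              t = tt, df = df, p = p,
                              significant = !is.na(p) & p < alpha, n = n_ok)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}
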
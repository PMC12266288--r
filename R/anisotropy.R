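#' Bin scheme for anisotropy correction
#'
#' Directions are split into four 90-degree bins centered either on the
#' cardinal axes (0, 90, 180, 270) or on the obliques (45, 135, 225, 315).
#' Repulsion from cardinals makes the error profile discontinuous *at* the
#' cardinals, so oblique-centered bins (whose edges sit on the cardinals)
#' keep each bin continuous; attraction to cardinals does the reverse.
#'
#' @param type `"cardinal"` or `"oblique"`.
#' @return A list of class `"bin_scheme"` with `centers`, `width`, `type`.
#' @export
bin_scheme <- function(type = c("cardinal", "oblique")) {
  type <- match.arg(type)
  centers <- if (type == "cardinal") c(0, 90, 180, 270) else c(45, 135, 225, 315)
  structure(list(centers = centers, width = 90, type = type),
            class = "bin_scheme")
}

# nearest bin center and signed distance to it
assign_bins <- function(targets, scheme) {
  offset <- if (scheme$type == "cardinal") 45 else 0
  bin <- ((targets + offset) %/% 90) %% 4 + 1
  x <- signed_diff(targets, scheme$centers[bin])
  list(bin = as.integer(bin), x = x)
}

# distance to the nearest cardinal direction, in [0, 45]
dist_to_cardinal <- function(targets) {
  abs(((targets + 45) %% 90) - 45)
}

poly_basis <- function(x, degree, half_width) {
  xs <- x / half_width
  outer(xs, 0:degree, `^`)
}

# degree-2 fit of residual SD against distance-to-nearest-cardinal,
# estimated from binned SDs; falls back to a constant SD when there are
# too few usable distance bins
fit_sd_model <- function(dc, resid) {
  br <- seq(0, 45, by = 5)
  bin <- cut(dc, br, include.lowest = TRUE)
  tab <- tapply(resid, bin, function(r) if (length(r) >= 3) stats::sd(r) else NA_real_)
  cnt <- tapply(resid, bin, length)
  mid <- (br[-1] + br[-length(br)]) / 2
  keep <- !is.na(tab)
  if (sum(keep) >= 3) {
    fit <- stats::lm(s ~ d + I(d^2),
                     data = data.frame(s = tab[keep], d = mid[keep]),
                     weights = cnt[keep])
    cf <- stats::coef(fit)
  } else {
    cf <- c(stats::sd(resid), 0, 0)
  }
  unname(cf)
}

predict_sd_from <- function(cf, dc, sd_floor) {
  pmax(cf[1] + cf[2] * dc + cf[3] * dc^2, sd_floor)
}

#' Fit an anisotropy model to response errors
#'
#' Within each 90-degree bin of a [bin_scheme()], fits a fourth-degree
#' polynomial of the signed distance to the bin center to the response
#' errors, together with a heteroscedastic noise model in which the
#' residual SD is a degree-2 polynomial of the distance to the nearest
#' cardinal direction (floored at `sd_floor`). Trials with residuals
#' beyond 3 local SDs are excluded from a refit and re-included
#' afterwards. The model's fit score is the total Gaussian log-likelihood
#' of all trials under the fitted mean and SD, which is comparable across
#' schemes.
#'
#' @param targets Stimulus directions in degrees, \[0, 360).
#' @param errors Signed response errors in degrees, (-180, 180\].
#' @param scheme A [bin_scheme()].
#' @param min_per_bin Minimum trials required in every bin.
#' @param degree Polynomial degree (4 by default).
#' @param sd_floor Lower bound for the predicted local SD, degrees.
#' @return An object of class `"anisotropy_model"`.
#' @export
fit_anisotropy <- function(targets, errors, scheme = bin_scheme("cardinal"),
                           min_per_bin = 25, degree = 4, sd_floor = 0.5) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (length(targets) != length(errors)) stop("targets and errors differ in length")
  keep <- !is.na(targets) & !is.na(errors)
  targets <- targets[keep]; errors <- errors[keep]
  ab <- assign_bins(targets, scheme)
  counts <- tabulate(ab$bin, 4)
  if (any(counts == 0)) {
    stop(sprintf("empty bin centered at %d degrees (%s scheme)",
                 scheme$centers[which(counts == 0)[1]], scheme$type))
  }
  if (any(counts < min_per_bin)) {
    b <- which(counts < min_per_bin)[1]
    stop(sprintf("bin centered at %d degrees has %d trials (< %d required)",
                 scheme$centers[b], counts[b], min_per_bin))
  }
  half <- scheme$width / 2

  fit_bins <- function(include) {
    coefs <- matrix(NA_real_, degree + 1, 4)
    pred <- rep(NA_real_, length(targets))
    for (b in 1:4) {
      in_b <- ab$bin == b
      use <- in_b & include
      X <- poly_basis(ab$x[use], degree, half)
      f <- stats::lm.fit(X, errors[use])
      if (any(is.na(f$coefficients))) {
        stop(sprintf("singular polynomial fit in bin centered at %d degrees",
                     scheme$centers[b]))
      }
      coefs[, b] <- f$coefficients
      pred[in_b] <- poly_basis(ab$x[in_b], degree, half) %*% f$coefficients
    }
    list(coefs = coefs, pred = pred)
  }

  all_in <- rep(TRUE, length(targets))
  f1 <- fit_bins(all_in)
  dc <- dist_to_cardinal(targets)
  sd_cf <- fit_sd_model(dc, errors - f1$pred)
  sd_pred <- predict_sd_from(sd_cf, dc, sd_floor)
  include <- abs(errors - f1$pred) <= 3 * sd_pred
  # guard: keep bins fittable even under heavy trimming
  if (all(tapply(include, ab$bin, sum) > degree + 1)) {
    f2 <- fit_bins(include)
  } else {
    f2 <- f1
    include <- all_in
  }
  sd_cf <- fit_sd_model(dc[include], (errors - f2$pred)[include])
  sd_pred <- predict_sd_from(sd_cf, dc, sd_floor)
  ll <- sum(stats::dnorm(errors - f2$pred, 0, sd_pred, log = TRUE))

  structure(list(scheme = scheme, coefficients = f2$coefs,
                 sd_coefficients = sd_cf, sd_floor = sd_floor,
                 degree = degree, logLik = ll, n = length(targets),
                 n_excluded_fit = sum(!include)),
            class = "anisotropy_model")
}

#' Predict the anisotropy (or local SD) at given directions
#'
#' @param object An `"anisotropy_model"`.
#' @param targets Directions in degrees.
#' @param what `"mean"` for the predicted mean error, `"sd"` for the
#'   predicted local SD.
#' @param ... Unused.
#' @return Numeric vector of predictions in degrees.
#' @export
predict.anisotropy_model <- function(object, targets, what = c("mean", "sd"), ...) {
  what <- match.arg(what)
  if (what == "sd") {
    return(predict_sd_from(object$sd_coefficients, dist_to_cardinal(targets),
                           object$sd_floor))
  }
  ab <- assign_bins(targets, object$scheme)
  X <- poly_basis(ab$x, object$degree, object$scheme$width / 2)
  pred <- numeric(length(targets))
  for (b in 1:4) {
    in_b <- ab$bin == b
    if (any(in_b)) pred[in_b] <- X[in_b, , drop = FALSE] %*% object$coefficients[, b]
  }
  pred
}

#' @export
print.anisotropy_model <- function(x, ...) {
  cat(sprintf("<anisotropy_model> %s-centered bins, degree %d, logLik %.1f, n = %d\n",
              x$scheme$type, x$degree, x$logLik, x$n))
  invisible(x)
}

#' Fit both bin schemes and keep the better one
#'
#' Fits cardinal-centered and oblique-centered models and returns the one
#' with the higher Gaussian log-likelihood; ties break to the
#' cardinal-centered scheme.
#'
#' @inheritParams fit_anisotropy
#' @param ... Passed to [fit_anisotropy()].
#' @return An `"anisotropy_model"`.
#' @export
select_scheme <- function(targets, errors, ...) {
  m_card <- fit_anisotropy(targets, errors, bin_scheme("cardinal"), ...)
  m_obl <- fit_anisotropy(targets, errors, bin_scheme("oblique"), ...)
  if (m_card$logLik >= m_obl$logLik) m_card else m_obl
}

#' Remove the fitted anisotropy from response errors
#'
#' Subtracts the predicted mean error and flags trials whose corrected
#' error exceeds 3 predicted local SDs as outliers. No trials are dropped;
#' the flag is sticky downstream.
#'
#' @param model An `"anisotropy_model"`.
#' @param targets,errors Directions and raw signed errors, degrees.
#' @return A `data.frame` with columns `raw_error`, `predicted_error`,
#'   `corrected_error`, `local_sd`, `is_outlier`.
#' @export
apply_correction <- function(model, targets, errors) {
  stopifnot(inherits(model, "anisotropy_model"))
  pred <- predict(model, targets, "mean")
  sd_loc <- predict(model, targets, "sd")
  corrected <- wrap_signed(errors - pred)
  data.frame(raw_error = errors, predicted_error = pred,
             corrected_error = corrected, local_sd = sd_loc,
             is_outlier = abs(corrected) > 3 * sd_loc)
}

#' Correct anisotropies in a full trial table
#'
#' Per participant and condition, selects the better bin scheme, removes
#' the predicted anisotropy from each response error, and flags outliers.
#'
#' @param trials Trial table with columns `participant`, `condition`,
#'   `target`, and `error` (signed report-minus-target; computed from
#'   `report` if absent).
#' @param ... Passed to [fit_anisotropy()] (e.g. `min_per_bin`).
#' @return `trials` with added columns `predicted_error`,
#'   `corrected_error`, `local_sd`, `is_outlier`, `scheme`. The fitted
#'   models are attached as `attr(, "models")` (named
#'   `participant.condition`).
#' @export
correct_anisotropy <- function(trials, ...) {
  if (!"error" %in% names(trials)) {
    trials$error <- signed_diff(trials$report, trials$target)
  }
  key <- interaction(trials$participant, trials$condition, drop = TRUE)
  models <- list()
  out <- trials
  out$predicted_error <- NA_real_
  out$corrected_error <- NA_real_
  out$local_sd <- NA_real_
  out$is_outlier <- NA
  out$scheme <- NA_character_
  for (g in levels(key)) {
    rows <- which(key == g)
    m <- select_scheme(trials$target[rows], trials$error[rows], ...)
    cor_g <- apply_correction(m, trials$target[rows], trials$error[rows])
    out$predicted_error[rows] <- cor_g$predicted_error
    out$corrected_error[rows] <- cor_g$corrected_error
    out$local_sd[rows] <- cor_g$local_sd
    out$is_outlier[rows] <- cor_g$is_outlier
    out$scheme[rows] <- m$scheme$type
    models[[g]] <- m
  }
  attr(out, "models") <- models
  out
}
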
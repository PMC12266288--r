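#' Wrap angles to the signed half-circle
#'
#' Reduces angles in degrees to the interval (-180, 180]. This is the
#' canonical representation for response errors and for the circular
#' difference between two directions.
#'
#' @param angle Numeric vector of angles in degrees. Must be finite.
#'
#' @return Numeric vector of the same length with values in (-180, 180].
#'   `wrap_signed(a)` equals `wrap_signed(a + 360)` for any `a`.
#'
#' @examples
#' wrap_signed(c(350, -180, 720)) # -10, 180, 0
#' @export
wrap_signed <- function(angle) {
  if (!is.numeric(angle)) stop("`angle` must be numeric")
  if (any(!is.finite(angle))) stop("`angle` contains non-finite values")
  x <- angle %% 360
  x[x > 180] <- x[x > 180] - 360
  x
}

#' Wrap angles to the full circle [0, 360)
#'
#' @param angle Numeric vector of angles in degrees. Must be finite.
#' @return Numeric vector with values in [0, 360).
#' @export
wrap_circle <- function(angle) {
  if (!is.numeric(angle)) stop("`angle` must be numeric")
  if (any(!is.finite(angle))) stop("`angle` contains non-finite values")
  angle %% 360
}

#' Signed circular difference between two directions
#'
#' Computes `a - b` on the circle, wrapped to (-180, 180]. With
#' `a = report` and `b = target` this yields the signed response error;
#' with `a = previous target` and `b = current target` it yields the
#' signed current-vs-previous difference whose absolute value is the
#' dissimilarity (0-180 degrees).
#'
#' @param a,b Numeric vectors of directions in degrees.
#' @return Signed angles in (-180, 180]; antisymmetric up to the 180
#'   boundary convention.
#' @examples
#' signed_diff(10, 350) # 20
#' signed_diff(0, 181)  # 179
#' @export
signed_diff <- function(a, b) wrap_signed(a - b)

#' Toward-code response errors relative to the previous stimulus
#'
#' Flips the sign of each error so that positive values always mean the
#' response deviated toward the previous stimulus and negative values
#' away from it. Trials where the previous and current stimulus coincide
#' (`delta_prev == 0`) have no defined toward/away direction and are
#' returned as `NA`.
#'
#' @param error Signed response errors in degrees, (-180, 180].
#' @param delta_prev Signed previous-minus-current target difference in
#'   degrees.
#' @return `error * sign(delta_prev)`, with `NA` where `delta_prev == 0`.
#' @examples
#' toward_code(c(5, 5, -4), c(30, -30, -30)) # 5, -5, 4
#' @export
toward_code <- function(error, delta_prev) {
  s <- sign(delta_prev)
  out <- error * s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}
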
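## Storage-experiment quality metrics: respiration rate, decay rate, and
## percent change versus the uncompressed control group.

#' Respiration rate of sealed fruit
#'
#' \deqn{rate = (C_1 - C_2) \times V / (m \times t)}
#' where \eqn{C_1} is the CO2 concentration (volume fraction) in the sealed
#' box holding the fruit, \eqn{C_2} the concentration in an empty box,
#' \eqn{V} the container volume in mL, \eqn{m} the fruit mass in kg and
#' \eqn{t} the sealing time in hours; the result is in mL CO2 per kg per
#' hour.  A negative rate (C2 > C1) is physiologically suspect and raises a
#' warning, but is returned rather than rejected.
#'
#' @param C1,C2 CO2 volume fractions (>= 0); vectorized.
#' @param V container volume, mL (> 0).
#' @param m fruit mass, kg (> 0).
#' @param t sealing time, h (> 0).
#' @return Respiration rate, mL kg^-1 h^-1.
#' @examples
#' respirationRate(C1 = 0.01, C2 = 0, V = 2000, m = 0.5, t = 3)
#' @export
respirationRate <- function(C1, C2, V, m, t) {
  if (any(V <= 0) || any(m <= 0) || any(t <= 0))
    stop("V, m and t must all be positive")
  if (any(C1 < 0) || any(C2 < 0)) stop("concentrations must be >= 0")
  rate <- (C1 - C2) * V / (m * t)
  if (any(rate < 0))
    warning("negative respiration rate (C2 > C1): suspect measurement")
  rate
}

#' Decay rate of a storage group
#'
#' Percentage of fruits in a group showing visible decay (green or blue
#' *Penicillium* mold) by the observation day.  The study scored decay on a
#' dedicated subgroup of 20 fruits per deformation level, hence the default
#' group size.
#'
#' @param decayedCount number of decayed fruits (0..groupSize); vectorized.
#' @param groupSize fruits scored for decay (> 0; default 20).
#' @return Decay rate, percent in [0, 100].
#' @examples
#' decayRate(c(3, 4, 7, 9))  # 15 20 35 45
#' @export
decayRate <- function(decayedCount, groupSize = 20) {
  if (any(groupSize <= 0)) stop("groupSize must be positive")
  if (any(decayedCount < 0) || any(decayedCount > groupSize))
    stop("decayedCount must lie in [0, groupSize]")
  100 * decayedCount / groupSize
}

#' Percent change of a treated group versus control
#'
#' Positive values mean the treated group is *lower* than control (e.g.
#' firmness 41\% lower than control at the largest deformation); negative
#' values mean higher than control.
#'
#' @param treated treated-group value; vectorized.
#' @param control control-group value (nonzero).
#' @return 100 * (control - treated) / control, percent.
#' @examples
#' percentChangeVsControl(treated = 5.9, control = 10)  # 41
#' @export
percentChangeVsControl <- function(treated, control) {
  if (any(control == 0)) stop("control value must be nonzero")
  100 * (control - treated) / control
}

#' Validate a storage-observation table
#'
#' Checks the schema and invariants of a storage time-series table:
#' required columns, non-negative days, and decayed counts within group
#' size.  Missing days are allowed (metrics are per-observation; no
#' interpolation is done).
#'
#' @param obs data.frame with columns \code{group} (deformation mm, 0 =
#'   control), \code{day}, and any of \code{firmness}, \code{respiration},
#'   \code{TSS}, \code{TA}, \code{decayed_count}, \code{group_size}.
#' @return The validated data.frame, invisibly; errors describe the first
#'   violated invariant.
#' @export
validateStorageObservations <- function(obs) {
  stopifnot(is.data.frame(obs))
  if (!all(c("group", "day") %in% names(obs)))
    stop("storage observations need 'group' and 'day' columns")
  if (any(obs$day < 0)) stop("'day' must be >= 0")
  if (all(c("decayed_count", "group_size") %in% names(obs))) {
    bad <- !is.na(obs$decayed_count) &
      (obs$decayed_count < 0 | obs$decayed_count > obs$group_size)
    if (any(bad)) stop("'decayed_count' outside [0, group_size] in row(s) ",
                       paste(which(bad), collapse = ", "))
  }
  invisible(obs)
}
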
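#' Cavity-based damage rate
#'
#' The damage rate A (percent) is the relative change in central-cavity
#' pixel area from pre- to post-compression:
#' \deqn{A = (S_2 - S_1)/S_1 \times 100}
#' where \eqn{S_1} and \eqn{S_2} are the cavity areas before and after
#' compression.  Negative values (cavity shrinkage) are reported as-is, not
#' clamped.  The statistic is scale-free: areas may be raw pixel counts.
#'
#' @param S1 pre-compression cavity area (> 0); vectorized.
#' @param S2 post-compression cavity area (>= 0); vectorized.
#' @return Damage rate in percent.
#' @examples
#' damageRate(100, 150)  # 50
#' damageRate(200, 190)  # -5
#' @export
damageRate <- function(S1, S2) {
  if (any(!is.finite(S1)) || any(!is.finite(S2)))
    stop("areas must be finite")
  if (any(S1 <= 0))
    stop("damage rate is undefined for S1 <= 0 (no pre-compression cavity)")
  if (any(S2 < 0)) stop("S2 must be >= 0")
  (S2 - S1) / S1 * 100
}

#' Summarize damage rates by deformation group
#'
#' Computes, per deformation level, the group mean and sample standard
#' deviation (n - 1 denominator) of the damage rate, as tabulated in the
#' study's damage-rate table.  A single-record group has an undefined SD,
#' reported as 0 with \code{sd_defined = FALSE}.
#'
#' @param records data.frame with columns \code{deformation_mm} and either
#'   \code{A} or both \code{S1} and \code{S2} (from which A is computed).
#' @param deformation_mm optional: restrict to one deformation level.
#' @return data.frame with columns \code{deformation_mm}, \code{n},
#'   \code{mean_A}, \code{sd_A}, \code{sd_defined}, \code{any_negative},
#'   plus display columns \code{mean_A_2dp}, \code{sd_A_2dp} rounded to two
#'   decimals.
#' @examples
#' summarizeDamage(data.frame(deformation_mm = 4, A = c(3, 5)))
#' @export
summarizeDamage <- function(records, deformation_mm = NULL) {
  stopifnot(is.data.frame(records), "deformation_mm" %in% names(records))
  if (!"A" %in% names(records)) {
    stopifnot(all(c("S1", "S2") %in% names(records)))
    records$A <- damageRate(records$S1, records$S2)
  }
  if (!is.null(deformation_mm))
    records <- records[records$deformation_mm %in% deformation_mm, ,
                       drop = FALSE]
  if (!nrow(records)) stop("no records in the requested group(s)")
  groups <- split(records$A, records$deformation_mm)
  out <- data.frame(
    deformation_mm = as.numeric(names(groups)),
    n = vapply(groups, length, integer(1)),
    mean_A = vapply(groups, mean, numeric(1)),
    sd_A = vapply(groups, function(a)
      if (length(a) > 1) stats::sd(a) else 0, numeric(1)),
    sd_defined = vapply(groups, function(a) length(a) > 1, logical(1)),
    any_negative = vapply(groups, function(a) any(a < 0), logical(1)),
    row.names = NULL)
  out$mean_A_2dp <- round(out$mean_A, 2)
  out$sd_A_2dp <- round(out$sd_A, 2)
  out[order(out$deformation_mm), , drop = FALSE]
}
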
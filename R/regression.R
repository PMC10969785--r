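## Linear models linking compression deformation (X, mm) to damage rate
## (Y1, percent) and storage decay rate (Y2, percent).

#' Fit a deformation-rate linear model
#'
#' Ordinary least squares of rate on deformation via [stats::lm()], with
#' \eqn{R^2 = 1 - SSE/SST} and a two-sided t-test of the slope on n - 2
#' degrees of freedom (reported as NA when n < 3, where inference is
#' impossible).
#'
#' @param x compression deformations, mm.
#' @param y rates, percent.
#' @param response label of the dependent rate (e.g. \code{"Y1"} for damage,
#'   \code{"Y2"} for decay).
#' @return A [RateModel-class].
#' @examples
#' fitRateModel(c(4, 8, 12, 16), c(15, 20, 35, 45), response = "Y2")
#' @export
fitRateModel <- function(x, y, response = "Y") {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(unique(x)) < 2L)
    stop("singular design: need at least 2 distinct deformation values")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  n <- length(x)
  sst <- sum((y - mean(y))^2)
  sse <- sum(stats::residuals(fit)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  # two-sided t-test of the slope; degenerate (perfect or n < 3) fits get NA
  sxx <- sum((x - mean(x))^2)
  p <- if (n >= 3L && sse > 0) {
    se <- sqrt(sse / (n - 2) / sxx)
    2 * stats::pt(-abs(cf[["x"]] / se), n - 2)
  } else NA_real_
  new("RateModel", response = response,
      slope = unname(cf["x"]), intercept = unname(cf["(Intercept)"]),
      rSquared = r2, slopePValue = p, n = as.numeric(n),
      residuals = unname(stats::residuals(fit)), xRange = range(x))
}

#' Predict a rate from a fitted model
#'
#' \code{slope * x + intercept}; predictions outside the fitted deformation
#' range are flagged as extrapolation in the \code{"extrapolated"}
#' attribute.
#'
#' @param model a [RateModel-class].
#' @param x deformations (mm) at which to predict.
#' @return Numeric predictions with a logical attribute
#'   \code{"extrapolated"}.
#' @examples
#' m <- fitRateModel(c(4, 8, 12, 16), c(15, 20, 35, 45), "Y2")
#' predictRate(m, 8)  # 23.5
#' @export
predictRate <- function(model, x) {
  stopifnot(is(model, "RateModel"))
  out <- model@slope * x + model@intercept
  attr(out, "extrapolated") <- x < model@xRange[1] | x > model@xRange[2]
  out
}

#' Format a fitted model as an equation string
#'
#' Renders e.g. \code{"Y2 = 2.625X + 2.5"}: coefficients rounded to three
#' decimals with trailing zeros dropped.
#'
#' @param model a [RateModel-class].
#' @return A single character string.
#' @export
formatModelEquation <- function(model) {
  num <- function(v) as.character(round(v, 3))
  sign <- if (model@intercept < 0) " - " else " + "
  paste0(model@response, " = ", num(model@slope), "X",
         sign, num(abs(model@intercept)))
}

#' Fit and compare the damage and decay regressions
#'
#' Fits both deformation-rate models (damage rate Y1, storage decay rate
#' Y2), and returns their coefficients (3-decimal display), coefficients of
#' determination (2-decimal display), slope p-values and residual tables.
#' If published reference coefficients are supplied, fitted coefficients
#' that disagree with them beyond \code{referenceTolerance} are flagged in
#' \code{notes} — group means cannot always reproduce a fit made on
#' per-sample values, and the report surfaces that rather than hiding it.
#'
#' @param damagePoints data.frame (columns \code{X}, \code{Y}) of
#'   deformation vs damage rate, or NULL to skip.
#' @param decayPoints data.frame (columns \code{X}, \code{Y}) of
#'   deformation vs decay rate, or NULL to skip.
#' @param referenceCoefficients optional named list, e.g.
#'   \code{list(Y1 = c(intercept = -0.468, slope = 0.964))}, of published
#'   coefficients to compare against.
#' @param referenceTolerance absolute tolerance for the comparison
#'   (default 0.01, i.e. agreement at display precision).
#' @return A list with elements \code{models} (named [RateModel-class]
#'   list), \code{table} (coefficients and statistics, raw and display
#'   columns), \code{residuals} (long residual table) and \code{notes}
#'   (character; discrepancy flags).
#' @examples
#' rateModelReport(decayPoints = data.frame(X = c(4, 8, 12, 16),
#'                                          Y = c(15, 20, 35, 45)))
#' @export
rateModelReport <- function(damagePoints = NULL, decayPoints = NULL,
                            referenceCoefficients = NULL,
                            referenceTolerance = 0.01) {
  if (is.null(damagePoints) && is.null(decayPoints))
    stop("supply at least one point set")
  models <- list()
  if (!is.null(damagePoints))
    models$Y1 <- fitRateModel(damagePoints$X, damagePoints$Y, "Y1")
  if (!is.null(decayPoints))
    models$Y2 <- fitRateModel(decayPoints$X, decayPoints$Y, "Y2")
  tab <- do.call(rbind, lapply(models, function(m) data.frame(
    response = m@response, slope = m@slope, intercept = m@intercept,
    r_squared = m@rSquared, slope_p_value = m@slopePValue, n = m@n,
    equation = formatModelEquation(m),
    slope_3dp = round(m@slope, 3), intercept_3dp = round(m@intercept, 3),
    r_squared_2dp = round(m@rSquared, 2))))
  rownames(tab) <- NULL
  resid <- do.call(rbind, lapply(models, function(m) {
    pts <- if (m@response == "Y1") damagePoints else decayPoints
    data.frame(response = m@response, X = pts$X, Y = pts$Y,
               fitted = as.numeric(predictRate(m, pts$X)),
               residual = m@residuals)
  }))
  rownames(resid) <- NULL
  notes <- character()
  for (nm in names(referenceCoefficients)) {
    if (is.null(models[[nm]])) next
    ref <- referenceCoefficients[[nm]]
    m <- models[[nm]]
    if (abs(m@slope - ref[["slope"]]) > referenceTolerance ||
        abs(m@intercept - ref[["intercept"]]) > referenceTolerance)
      notes <- c(notes, sprintf(
        paste0("%s: fitted coefficients (slope %.3f, intercept %.3f) do not ",
               "reproduce the reference (slope %.3f, intercept %.3f); a fit ",
               "on group means cannot recover a fit made on per-sample ",
               "values"),
        nm, m@slope, m@intercept, ref[["slope"]], ref[["intercept"]]))
  }
  list(models = models, table = tab, residuals = resid, notes = notes)
}
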
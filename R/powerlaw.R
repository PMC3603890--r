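#' Construct a power-law fit object
#'
#' \code{y = coeff x^exponent}.  Use \code{\link{fit_power_law}} to estimate
#' one from data; this constructor also lets published constants be wrapped
#' for evaluation.
#'
#' @param coeff multiplicative coefficient.
#' @param exponent exponent.
#' @param r_squared coefficient of determination of the log-log fit, if any.
#' @param n number of points the fit used, if any.
#' @return an object of class \code{"powerlaw_fit"}.
#' @export
powerlaw_fit <- function(coeff, exponent, r_squared = NA_real_,
                         n = NA_integer_) {
  stopifnot(is.finite(coeff), coeff > 0, is.finite(exponent))
  structure(list(coeff = coeff, exponent = exponent,
                 r_squared = r_squared, n = n),
            class = "powerlaw_fit")
}

#' Fit a power law by least squares in log-log space
#'
#' Ordinary least squares of \code{log(y)} on \code{log(x)}; exact on
#' noiseless power-law data.
#'
#' @param x,y positive numeric vectors of equal length (n >= 2).
#' @return a \code{\link{powerlaw_fit}}.
#' @examples
#' f <- fit_power_law(c(16.15, 27.525, 42.15),
#'                    6.10 * c(16.15, 27.525, 42.15)^-0.615)
#' coef(f)  # 6.10, -0.615 recovered exactly
#' @export
fit_power_law <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("need at least two (x, y) pairs")
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fitting requires strictly positive data")
  fit <- stats::lm(log(y) ~ log(x))
  # R^2 computed directly (summary.lm warns on numerically perfect fits)
  ly <- log(y)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  powerlaw_fit(coeff = exp(unname(coef(fit)[1])),
               exponent = unname(coef(fit)[2]),
               r_squared = r2, n = length(x))
}

#' Evaluate a power-law fit
#'
#' @param fit a \code{\link{powerlaw_fit}}.
#' @param x positive evaluation points.
#' @return \code{coeff * x^exponent}.
#' @examples
#' eval_power_law(powerlaw_fit(6.10, -0.615), 27.525)  # 0.79 s
#' eval_power_law(powerlaw_fit(4.02, -0.5), 27.525)    # 0.77 s
#' @export
eval_power_law <- function(fit, x) {
  stopifnot(inherits(fit, "powerlaw_fit"), all(x > 0))
  fit$coeff * x^fit$exponent
}

#' @export
predict.powerlaw_fit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  eval_power_law(object, x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(coeff = object$coeff, exponent = object$exponent)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power law: y = %.4g * x^(%.4g)", x$coeff, x$exponent))
  if (!is.na(x$r_squared)) cat(sprintf("  (R^2 = %.4f, n = %d)",
                                       x$r_squared, x$n))
  cat("\n")
  invisible(x)
}

#' Crossing point of two power laws
#'
#' The abscissa where \code{c1 x^p1 = c2 x^p2}:
#' \code{(c2/c1)^(1/(p1 - p2))}.
#'
#' @param fit1,fit2 \code{\link{powerlaw_fit}} objects with distinct
#'   exponents.
#' @return the crossing abscissa.
#' @examples
#' crossing_radius(powerlaw_fit(6.10, -0.615),
#'                 powerlaw_fit(4.02, -0.5))  # 37.6 um
#' @export
crossing_radius <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "powerlaw_fit"), inherits(fit2, "powerlaw_fit"))
  if (abs(fit1$exponent - fit2$exponent) < 1e-12)
    stop("no crossing: the two power laws have equal exponents")
  (fit2$coeff / fit1$coeff)^(1 / (fit1$exponent - fit2$exponent))
}
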
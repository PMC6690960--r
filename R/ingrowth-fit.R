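#' Fit the two-amplitude daughter-ingrowth model to a counting series
#'
#' Fits \deqn{A_2(t) = A_{eq} (1 - e^{-\lambda_2 t}) + A_0 e^{-\lambda_2 t}}
#' to a post-sacrifice gamma-counting series of a short-lived daughter
#' (Bi-213 by default) growing back into equilibrium with its carrier-bound
#' parent. `t = 0` is the time of sacrifice; the back-extrapolated intercept
#' `A_0` is the total daughter activity at sacrifice (carrier-bound plus
#' redistributed free daughter), and the asymptote `A_eq` is the
#' carrier-bound equilibrium activity. With \eqn{\lambda_2} fixed the model
#' is linear in the two amplitudes, so the fit is the exact (weighted)
#' linear least-squares solution, not an iterative approximation.
#'
#' @param x Either a numeric vector of measurement times (with `values`
#'   supplied), or a data frame holding one series with time and value
#'   columns.
#' @param values Numeric vector of measured activities or count rates, same
#'   length as the times. Any single consistent unit; the ratio statistic is
#'   scale-invariant.
#' @param lambda2 Daughter decay constant in reciprocal time units of the
#'   series (default: Bi-213, `ln 2 / 45.6` per minute).
#' @param weighting `"none"` (ordinary least squares, the default) or
#'   `"poisson"` (inverse-expected-count weights, one reweighting pass from
#'   the OLS fit).
#' @param time_col,value_col Column names used by the data-frame method.
#' @param ... Passed between methods.
#'
#' @return An object of class `"ingrowth_fit"`: a list with components
#'   `coefficients` (named `A_eq`, `A0`), `se`, `vcov`, `fitted.values`,
#'   `residuals`, `residual_rms`, `sigma`, `df.residual`, `times`, `values`,
#'   `lambda2`, `weighting`, `n`. Supports [coef()], [vcov()], [predict()],
#'   [fitted()], [residuals()], [summary()], [plot()], [simulate()] and
#'   [confint()].
#'
#' @details Times must be non-negative, strictly increasing, and at least
#'   three points are required (two amplitudes plus a residual degree of
#'   freedom). A warning is issued when the series spans less than
#'   \eqn{2/\lambda_2}: the asymptote is then poorly constrained. A design
#'   that is numerically singular (all points effectively at `t = 0` or all
#'   at equilibrium) raises a conditioning error. A negative fitted
#'   intercept, possible under counting noise, is reported with a warning
#'   rather than clipped.
#'
#' @examples
#' lam <- decay_constant(45.6)                         # Bi-213, min^-1
#' t <- seq(0, 1080, by = 10)                          # ~18 h of counting
#' y <- ingrowth_activity(86, 58, lam, t)              # spleen-like series
#' fit <- fit_ingrowth(t, y, lambda2 = lam)
#' coef(fit)
#' free_ratio(fit)
#' @export
fit_ingrowth <- function(x, ...) UseMethod("fit_ingrowth")

#' @rdname fit_ingrowth
#' @export
fit_ingrowth.default <- function(x, values, lambda2 = decay_constant(45.6),
                                 weighting = c("none", "poisson"), ...) {
  times <- x
  weighting <- match.arg(weighting)
  if (!is.numeric(times) || !is.numeric(values))
    stop("'times' and 'values' must be numeric", call. = FALSE)
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length", call. = FALSE)
  if (length(times) < 3L)
    stop("at least 3 points are required to fit the ingrowth model",
         call. = FALSE)
  if (any(times < 0) || any(diff(times) <= 0))
    stop("'times' must be non-negative and strictly increasing",
         call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("'values' must be finite and non-negative", call. = FALSE)
  if (!is.numeric(lambda2) || length(lambda2) != 1L || lambda2 <= 0)
    stop("'lambda2' must be a single positive rate", call. = FALSE)
  if (max(times) - min(times) < 2 / lambda2)
    warning("series spans less than 2/lambda2; the equilibrium amplitude ",
            "is weakly constrained", call. = FALSE)

  e <- exp(-lambda2 * times)
  X <- cbind(A_eq = 1 - e, A0 = e)
  w <- rep(1, length(times))
  est <- .wls_ingrowth(X, values, w)
  if (weighting == "poisson") {
    mu <- pmax(drop(X %*% est$beta), .Machine$double.eps)
    w <- 1 / mu
    est <- .wls_ingrowth(X, values, w)
  }
  beta <- est$beta
  fitted <- drop(X %*% beta)
  res <- values - fitted
  n <- length(times)
  dfres <- n - 2L
  sigma2 <- sum(w * res^2) / dfres
  vcov <- sigma2 * est$XtXinv
  dimnames(vcov) <- list(c("A_eq", "A0"), c("A_eq", "A0"))
  if (beta["A0"] < 0)
    warning("back-extrapolated intercept A0 is negative (counting noise); ",
            "reported as-is", call. = FALSE)
  structure(list(
    coefficients = beta,
    se = sqrt(pmax(diag(vcov), 0)),
    vcov = vcov,
    fitted.values = fitted,
    residuals = res,
    residual_rms = sqrt(mean(res^2)),
    sigma = sqrt(sigma2),
    df.residual = dfres,
    times = times, values = values, weights = w,
    lambda2 = lambda2, weighting = weighting, n = n
  ), class = "ingrowth_fit")
}

.wls_ingrowth <- function(X, y, w) {
  XtX <- crossprod(X * w, X)
  # conditioning guard: both basis functions must genuinely vary
  sv <- svd(sqrt(w) * X, nu = 0, nv = 0)$d
  if (sv[2L] < 1e-10 * sv[1L])
    stop("singular ingrowth design: measurement times do not separate the ",
         "intercept from the asymptote (all t ~ 0 or all t >> 1/lambda2)",
         call. = FALSE)
  XtXinv <- solve(XtX)
  beta <- drop(XtXinv %*% crossprod(X * w, y))
  names(beta) <- colnames(X)
  list(beta = beta, XtXinv = XtXinv)
}

#' @rdname fit_ingrowth
#' @export
fit_ingrowth.data.frame <- function(x, lambda2 = decay_constant(45.6),
                                    weighting = c("none", "poisson"),
                                    time_col = "t_min", value_col = "value",
                                    ...) {
  if (!all(c(time_col, value_col) %in% names(x)))
    stop("data frame must contain columns '", time_col, "' and '",
         value_col, "'", call. = FALSE)
  ord <- order(x[[time_col]])
  fit_ingrowth.default(x[[time_col]][ord], x[[value_col]][ord],
                       lambda2 = lambda2, weighting = weighting)
}

#' @export
print.ingrowth_fit <- function(x, digits = 4, ...) {
  cat("Daughter ingrowth fit (two-amplitude model)\n")
  cat(sprintf("  lambda2 = %.6g (t1/2 = %.4g), n = %d, weighting = %s\n",
              x$lambda2, log(2) / x$lambda2, x$n, x$weighting))
  cat(sprintf("  A_eq (equilibrium) = %.*g +/- %.*g\n", digits,
              x$coefficients["A_eq"], digits, x$se["A_eq"]))
  cat(sprintf("  A0   (at t = 0)    = %.*g +/- %.*g\n", digits,
              x$coefficients["A0"], digits, x$se["A0"]))
  cat(sprintf("  residual RMS = %.*g\n", digits, x$residual_rms))
  invisible(x)
}

#' @export
coef.ingrowth_fit <- function(object, ...) object$coefficients

#' @export
vcov.ingrowth_fit <- function(object, ...) object$vcov

#' @export
fitted.ingrowth_fit <- function(object, ...) object$fitted.values

#' @export
residuals.ingrowth_fit <- function(object, ...) object$residuals

#' Predicted ingrowth curve from a fitted model
#'
#' @param object An `"ingrowth_fit"`.
#' @param newtimes Times at which to evaluate the fitted curve (defaults to
#'   the observed times).
#' @param se.fit Also return pointwise standard errors.
#' @param ... Unused.
#' @return Numeric vector of predictions, or a list with `fit` and `se.fit`.
#' @export
predict.ingrowth_fit <- function(object, newtimes = NULL, se.fit = FALSE,
                                 ...) {
  t <- if (is.null(newtimes)) object$times else newtimes
  e <- exp(-object$lambda2 * t)
  X <- cbind(1 - e, e)
  fit <- drop(X %*% object$coefficients)
  if (!se.fit) return(fit)
  se <- sqrt(pmax(rowSums((X %*% object$vcov) * X), 0))
  list(fit = fit, se.fit = se)
}

#' @export
summary.ingrowth_fit <- function(object, ...) {
  co <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  r <- tryCatch(free_ratio(object), error = function(e) NULL)
  structure(list(coefficients = co, fit = object, ratio = r),
            class = "summary.ingrowth_fit")
}

#' @export
print.summary.ingrowth_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$ratio))
    cat(sprintf("  free-daughter ratio A0/A_eq = %.*g +/- %.*g  [%s]\n",
                digits, x$ratio$ratio, digits, x$ratio$se,
                x$ratio$classification))
  invisible(x)
}

#' @export
plot.ingrowth_fit <- function(x, ...,
                              xlab = "time since sacrifice",
                              ylab = "daughter activity") {
  graphics::plot(x$times, x$values, xlab = xlab, ylab = ylab, ...)
  tt <- seq(min(x$times), max(x$times), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  graphics::abline(h = x$coefficients["A_eq"], lty = 3)
  invisible(x)
}

#' Simulate Poisson-noise replicates of a fitted counting series
#'
#' Draws new series from the fitted ingrowth curve with Poisson counting
#' noise at a given counts-per-activity-unit scale.
#'
#' @param object An `"ingrowth_fit"`.
#' @param nsim Number of replicate series.
#' @param seed Optional integer seed.
#' @param counts_per_unit Expected counts per activity unit per measurement.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated values (rows follow
#'   `object$times`).
#' @export
simulate.ingrowth_fit <- function(object, nsim = 1, seed = NULL,
                                  counts_per_unit = 1e4, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- pmax(object$fitted.values, 0) * counts_per_unit
  out <- replicate(nsim, stats::rpois(length(mu), mu) / counts_per_unit)
  as.data.frame(out)
}

#' @export
confint.ingrowth_fit <- function(object, parm = c("A_eq", "A0"),
                                 level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  q <- stats::qt(1 - (1 - level) / 2, object$df.residual)
  est <- object$coefficients[parm]
  se <- object$se[parm]
  out <- cbind(est - q * se, est + q * se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2)), "%")
  out
}

#' Back-extrapolated daughter activity at the time of sacrifice
#'
#' Accessor for the fitted intercept `A0` (the ingrowth curve evaluated at
#' `t = 0`) with its standard error.
#'
#' @param fit An `"ingrowth_fit"`.
#' @return Named list with `estimate` and `se`.
#' @export
extrapolate_A0 <- function(fit) {
  stopifnot(inherits(fit, "ingrowth_fit"))
  list(estimate = unname(fit$coefficients["A0"]),
       se = unname(fit$se["A0"]))
}
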
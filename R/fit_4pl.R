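#' Fit a four-parameter logistic dose-response curve
#'
#' Fits `y = bottom + (top - bottom) / (1 + (dose/ec50)^hill)` to percent
#' viability by bounded Levenberg-Marquardt least squares, with
#' `log10(ec50)` as the free potency parameter. Starting values come from
#' the data (top = max response, bottom = min response, ec50 = dose whose
#' response is nearest to the half-range, hill = 1); `log10(ec50)` is
#' bounded one decade beyond the tested dose range, `hill` to `[0.1, 10]`,
#' and the plateaus to one response-range beyond the observed extremes.
#'
#' If the observed response range is below `flat_range` percentage points
#' no fit is attempted and a flat-curve sentinel is returned
#' (`top = bottom = mean response`, `ec50 = hill = NA`,
#' `converged = FALSE`).
#'
#' @param doses Dose vector, nM, at least 4 distinct positive values.
#' @param responses Percent viability at each dose.
#' @param flat_range Minimum response range (percentage points) required
#'   to attempt a fit.
#' @return An object of class `pl4` with components `coefficients`
#'   (top, bottom, ec50, hill), `rss`, `converged`, `flat`, `doses`,
#'   `responses`, `fitted.values`.
#' @examples
#' d <- 45000 / 3^(0:10)
#' fit <- fit_4pl(d, 100 / (1 + d / 1000))
#' coef(fit)
#' @export
fit_4pl <- function(doses, responses, flat_range = 5) {
  if (length(doses) != length(responses)) {
    stop_validation("doses and responses must have equal length")
  }
  ok <- is.finite(doses) & is.finite(responses) & doses > 0
  doses <- doses[ok]; responses <- responses[ok]
  if (length(unique(doses)) < 4) stop_validation("need >= 4 distinct positive doses")
  rng <- range(responses)
  if (diff(rng) < flat_range) {
    cf <- c(top = mean(responses), bottom = mean(responses),
            ec50 = NA_real_, hill = NA_real_)
    return(structure(list(coefficients = cf,
                          rss = sum((responses - mean(responses))^2),
                          converged = FALSE, flat = TRUE, doses = doses,
                          responses = responses,
                          fitted.values = rep(mean(responses), length(responses))),
                     class = "pl4"))
  }
  half <- mean(rng)
  start <- c(top = rng[2], bottom = rng[1],
             lec50 = log10(doses[which.min(abs(responses - half))]), hill = 1)
  span <- diff(rng)
  lower <- c(rng[1] - span, rng[1] - span, log10(min(doses)) - 1, 0.1)
  upper <- c(rng[2] + span, rng[2] + span, log10(max(doses)) + 1, 10)
  resid_fn <- function(p) {
    responses - (p[2] + (p[1] - p[2]) / (1 + (doses / 10^p[3])^p[4]))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200,
                                                            ftol = 1e-14,
                                                            ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) {
    cf <- c(top = rng[2], bottom = rng[1], ec50 = NA_real_, hill = NA_real_)
    return(structure(list(coefficients = cf, rss = Inf, converged = FALSE,
                          flat = FALSE, doses = doses, responses = responses,
                          fitted.values = rep(NA_real_, length(responses))),
                     class = "pl4"))
  }
  p <- fit$par
  # keep top >= bottom by swapping if the optimizer crossed them
  if (p[1] < p[2]) { p[1:2] <- p[2:1]; p[4] <- -p[4] }
  cf <- c(top = unname(p[1]), bottom = unname(p[2]),
          ec50 = unname(10^p[3]), hill = unname(p[4]))
  fitted <- cf["bottom"] + (cf["top"] - cf["bottom"]) /
    (1 + (doses / cf["ec50"])^cf["hill"])
  structure(list(coefficients = cf, rss = sum(fit$fvec^2),
                 converged = fit$info %in% 1:4 && cf["hill"] > 0,
                 flat = FALSE, doses = doses, responses = responses,
                 fitted.values = unname(fitted)),
            class = "pl4")
}

#' @export
coef.pl4 <- function(object, ...) object$coefficients

#' @export
print.pl4 <- function(x, digits = 4, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  if (x$flat) {
    cat(sprintf("  flat curve at %.4g%% (range < threshold; no fit attempted)\n",
                x$coefficients[["top"]]))
  } else {
    cf <- x$coefficients
    cat(sprintf("  top = %.*g%%, bottom = %.*g%%, EC50 = %.*g nM, hill = %.*g\n",
                digits, cf[["top"]], digits, cf[["bottom"]],
                digits, cf[["ec50"]], digits, cf[["hill"]]))
    cat(sprintf("  RSS = %.4g on %d doses; converged: %s\n",
                x$rss, length(x$doses), x$converged))
  }
  invisible(x)
}

#' Predict viability from a fitted 4PL curve
#'
#' @param object A `pl4` fit.
#' @param newdata Optional dose vector (nM); defaults to the fitted doses.
#' @param ... Unused.
#' @return Percent viability.
#' @export
predict.pl4 <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$doses else newdata
  cf <- object$coefficients
  if (object$flat) return(rep(cf[["top"]], length(d)))
  cf[["bottom"]] + (cf[["top"]] - cf[["bottom"]]) /
    (1 + (d / cf[["ec50"]])^cf[["hill"]])
}

#' @export
residuals.pl4 <- function(object, ...) object$responses - object$fitted.values

#' @export
summary.pl4 <- function(object, ...) {
  structure(list(fit = object,
                 sigma = sqrt(object$rss / max(1, length(object$doses) - 4))),
            class = "summary.pl4")
}

#' @export
print.summary.pl4 <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SD = %.4g\n", x$sigma))
  invisible(x)
}

#' Plot a fitted 4PL curve
#'
#' Draws observed responses against log10 dose with the fitted curve.
#'
#' @param x A `pl4` fit.
#' @param ... Passed to [plot()].
#' @export
plot.pl4 <- function(x, ...) {
  lx <- log10(x$doses)
  graphics::plot(lx, x$responses, xlab = "log10 dose (nM)",
                 ylab = "viability (%)", ...)
  grid <- seq(min(lx), max(lx), length.out = 200)
  graphics::lines(grid, predict(x, 10^grid))
  invisible(x)
}
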
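#' Saturation-curve series
#'
#' A series of variant counts against coverage (x) or iteration round,
#' carrying both the raw counts and their logarithm (base 2 by default; the
#' published fitted asymptotes match the terminal counts only in base 2).
#'
#' @param x Strictly increasing positive values (coverage in x, or round).
#' @param y_raw Positive variant counts.
#' @param log_base Base for the log transform (default 2).
#' @return A `curve_series` tibble with columns `x`, `y_raw`, `y`.
#' @export
curve_series <- function(x, y_raw, log_base = 2) {
  stopifnot(length(x) == length(y_raw), all(y_raw > 0), all(x > 0),
            all(diff(x) > 0))
  out <- tibble::tibble(x = as.numeric(x), y_raw = as.numeric(y_raw),
                        y = log(y_raw, base = log_base))
  attr(out, "log_base") <- log_base
  class(out) <- c("curve_series", class(out))
  out
}

#' Logistic saturation fits
#'
#' The model is `y = a / (1 + b * exp(-c * x))` (rising orientation, used
#' for variant counts against coverage) or `y = a / (1 - b * exp(-c * x))`
#' (falling orientation, used for counts against iteration round), with
#' `a, b, c > 0`. `logistic_fit()` builds a fit object from known
#' parameters (e.g. published ones); [fit_logistic()] estimates them by
#' nonlinear least squares.
#'
#' Two goodness-of-fit figures are carried: `r_squared` (one minus
#' SSres/SStot) and its square root `r`, the correlation coefficient that
#' curve-fitting programs in the CurveExpert tradition print as their fit
#' quality (published "R^2" columns follow that convention).
#'
#' @param a Asymptote (log2 variant counts).
#' @param b Shape parameter (dimensionless).
#' @param c Rate per unit x.
#' @param orientation `"rising"` or `"falling"`.
#' @param r_squared,r Optional goodness-of-fit values.
#' @param log_base Log base of the y scale.
#' @param data Optional `curve_series` the fit describes.
#' @return A `logistic_fit` object.
#' @export
logistic_fit <- function(a, b, c, orientation = c("rising", "falling"),
                         r_squared = NA_real_, r = NA_real_, log_base = 2,
                         data = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(a > 0, b > 0, c > 0)
  structure(list(a = a, b = b, c = c, orientation = orientation,
                 r_squared = r_squared, r = r, log_base = log_base,
                 data = data, converged = NA),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  sign <- if (x$orientation == "rising") "+" else "-"
  cat(sprintf("<logistic_fit> y = %.4g / (1 %s %.4g * exp(-%.4g x))  [%s]\n",
              x$a, sign, x$b, x$c, x$orientation))
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R^2 = %.6f (r = %.6f), n = %d\n", x$r_squared, x$r,
                if (is.null(x$data)) NA_integer_ else nrow(x$data)))
  }
  invisible(x)
}

orientation_sign <- function(fit) if (fit$orientation == "rising") 1 else -1

#' Evaluate a logistic fit
#'
#' @param fit A `logistic_fit`.
#' @param x Evaluation points.
#' @return `y = a / (1 +/- b exp(-c x))` per orientation. For the falling
#'   orientation, `b * exp(-c x) >= 1` is a domain error.
#' @export
logistic_eval <- function(fit, x) {
  s <- orientation_sign(fit)
  denom <- 1 + s * fit$b * exp(-fit$c * x)
  if (s < 0 && any(denom <= 0)) {
    stop("falling logistic undefined where b*exp(-c*x) >= 1 (x too small)")
  }
  fit$a / denom
}

#' Analytic tangent slope of a logistic fit
#'
#' `d y / d x = +/- a b c exp(-c x) / (1 +/- b exp(-c x))^2`: positive for
#' the rising orientation, negative for the falling one. This is the
#' quantity thresholded to pick the optimal coverage and iteration count.
#'
#' @inheritParams logistic_eval
#' @return The derivative at `x`.
#' @export
tangent_slope <- function(fit, x) {
  s <- orientation_sign(fit)
  e <- exp(-fit$c * x)
  denom <- 1 + s * fit$b * e
  if (s < 0 && any(denom <= 0)) {
    stop("falling logistic undefined where b*exp(-c*x) >= 1 (x too small)")
  }
  s * fit$a * fit$b * fit$c * e / denom^2
}

#' Fit a logistic saturation curve by nonlinear least squares
#'
#' Fits `y = a / (1 +/- b exp(-c x))` to the log-transformed counts of a
#' [curve_series()] with `minpack.lm` Levenberg-Marquardt. Initialization:
#' the asymptote from the data's extreme value, the rate from a log-linear
#' regression of the transformed residual, the shape solved from the first
#' point; up to 20 random restarts on non-convergence.
#'
#' @param series A [curve_series()] (or data frame with `x` and `y_raw` or
#'   `y`).
#' @param orientation `"rising"` or `"falling"`.
#' @param log_base Log base when `series` lacks a `y` column.
#' @return A `logistic_fit` with `r_squared`, `r` and the data attached.
#' @export
fit_logistic <- function(series, orientation = c("rising", "falling"),
                         log_base = 2) {
  orientation <- match.arg(orientation)
  if (!"y" %in% names(series)) {
    series <- curve_series(series$x, series$y_raw, log_base = log_base)
  } else {
    lb <- attr(series, "log_base")
    if (!is.null(lb)) log_base <- lb
  }
  if (nrow(series) < 4) stop("need at least 4 points to fit a logistic")
  x <- series$x
  y <- series$y
  s <- if (orientation == "rising") 1 else -1

  model <- function(a, b, c) {
    denom <- 1 + s * b * exp(-c * x)
    denom[denom < 1e-9] <- 1e-9  # steer the optimizer away from the pole
    a / denom
  }

  start_values <- function() {
    a0 <- if (s > 0) max(y) * (1 + 1e-3) else min(y) * (1 - 1e-3)
    z <- if (s > 0) a0 / y - 1 else 1 - a0 / y
    ok <- z > 0
    c0 <- 0.5
    b0 <- 0.3
    if (sum(ok) >= 2) {
      co <- unname(stats::coef(stats::lm(log(z[ok]) ~ x[ok])))
      if (is.finite(co[2]) && co[2] < 0) c0 <- -co[2]
      if (is.finite(co[1])) b0 <- exp(co[1])
    }
    b0 <- max(b0, 1e-6)
    list(a = a0, b = b0, c = c0)
  }

  st <- start_values()
  fit <- NULL
  for (attempt in 0:20) {
    st_try <- if (attempt == 0) st else {
      lapply(st, function(v) v * exp(stats::rnorm(1, 0, 0.5)))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ model(a, b, c),
        start = st_try,
        lower = c(a = 1e-9, b = 1e-9, c = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("logistic fit did not converge after 20 restarts (orientation = ",
         orientation, ", n = ", length(x), ", y range = [",
         signif(min(y), 4), ", ", signif(max(y), 4), "])")
  }
  p <- stats::coef(fit)
  ssr <- sum(stats::resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - ssr / sst
  out <- logistic_fit(p[["a"]], p[["b"]], p[["c"]], orientation,
                      r_squared = r2, r = sqrt(max(r2, 0)),
                      log_base = log_base, data = series)
  out$converged <- TRUE
  out
}

#' Optimal coverage from the tangent-slope threshold
#'
#' For a rising fit, finds the unique `x` past the slope maximum where the
#' tangent slope falls to `tau`, by bracketing and bisection to
#' `|dx| <= 1e-4`; the recommended integer coverage is the ceiling ("rounded
#' up"). If the slope never exceeds `tau`, the lower domain bound is
#' returned with a warning flag.
#'
#' @param fit A rising `logistic_fit`.
#' @param tau Slope threshold (default `1e-4`).
#' @param x_max Upper search bound.
#' @return A one-row tibble `x_star, recommendation, boundary`.
#' @export
threshold_coverage <- function(fit, tau = 1e-4, x_max = 1e4) {
  if (fit$orientation != "rising") stop("threshold_coverage needs a rising fit")
  g <- function(x) tangent_slope(fit, x) - tau
  x_lo <- max(log(fit$b) / fit$c, 1e-8)  # slope maximum (inflection)
  if (g(x_lo) <= 0) {
    warning("tangent slope never exceeds tau on the saturating branch; ",
            "returning the lower domain bound")
    return(tibble::tibble(x_star = x_lo, recommendation = ceiling(x_lo),
                          boundary = TRUE))
  }
  hi <- x_lo + 1
  while (g(hi) > 0) {
    hi <- x_lo + (hi - x_lo) * 2
    if (hi > x_max) stop("no threshold crossing below x_max = ", x_max)
  }
  root <- stats::uniroot(g, c(x_lo, hi), tol = 1e-6)$root
  tibble::tibble(x_star = root, recommendation = ceiling(root), boundary = FALSE)
}

#' Optimal iteration count from the tangent-slope threshold
#'
#' For a falling fit, the smallest integer round `n >= 2` whose absolute
#' tangent slope is at most `tau`.
#'
#' @param fit A falling `logistic_fit`.
#' @param tau Slope-magnitude threshold (default `1e-4`).
#' @param n_max Upper scan bound.
#' @return An integer round count.
#' @export
optimal_iterations <- function(fit, tau = 1e-4, n_max = 1000L) {
  if (fit$orientation != "falling") stop("optimal_iterations needs a falling fit")
  for (n in 2:n_max) {
    if (abs(tangent_slope(fit, n)) <= tau) return(as.integer(n))
  }
  stop("no round up to ", n_max, " reaches |slope| <= ", tau)
}

#' Optimal coverage across several breeds
#'
#' The recommendation is driven by the slowest-saturating breed: the
#' maximum of the per-fit threshold coverages, with its ceiling.
#'
#' @param fits A list of rising `logistic_fit`s.
#' @param tau Slope threshold.
#' @return A one-row tibble `x_star_max, recommendation`.
#' @export
multi_breed_recommendation <- function(fits, tau = 1e-4) {
  stopifnot(length(fits) >= 1)
  per <- purrr::map_dbl(fits, function(f) threshold_coverage(f, tau)$x_star)
  tibble::tibble(x_star_max = max(per), recommendation = ceiling(max(per)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c))
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, r = x$r,
                 orientation = x$orientation, log_base = x$log_base,
                 nobs = if (is.null(x$data)) NA_integer_ else nrow(x$data),
                 converged = x$converged)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a logistic fit over its data
#'
#' @param object A `logistic_fit`.
#' @param ... Ignored.
#' @return A ggplot: observed log-counts (points) and the fitted curve.
#' @export
autoplot.logistic_fit <- function(object, ...) {
  xr <- if (!is.null(object$data)) range(object$data$x) else c(1, 30)
  grid <- tibble::tibble(x = seq(xr[1], xr[2], length.out = 200))
  grid$y <- logistic_eval(object, grid$x)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x (coverage or round)",
                  y = paste0("log", object$log_base, " variant count"),
                  title = sprintf("logistic fit (%s), R^2 = %.4f",
                                  object$orientation, object$r_squared))
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(data = object$data,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 colour = "darkgreen")
  }
  p
}
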
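#' Wood curve parameters
#'
#' Constructs and validates the parameter triple of the minimum-shaped Wood
#' incomplete-gamma lactation curve for milk fat percentage,
#' \deqn{Y(t) = a \, t^{-b} e^{c t},}
#' where `t` is the lactation month. `a` (in % units) scales the curve and is
#' read as the lactation potential of fat percentage; `b` governs the initial
#' descent towards the fat minimum; `c` (per month) governs the rise after the
#' minimum. For `b, c > 0` the curve has an interior minimum at `t = b/c`.
#'
#' @param a Positive scale parameter (%).
#' @param b Non-negative descent exponent (dimensionless).
#' @param c Non-negative ascent rate (per lactation month).
#'
#' @return An object of class `wood_params`: a named list with elements
#'   `a`, `b`, `c`.
#'
#' @examples
#' wp <- wood_params(4.07, 0.35, 0.08)
#' wood_curve(wp, 1:11)
#' @export
wood_params <- function(a, b, c) {
  for (nm in c("a", "b", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (a <= 0) stop("`a` must be positive", call. = FALSE)
  if (b < 0 || c < 0) stop("`b` and `c` must be non-negative", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "wood_params")
}

#' @export
print.wood_params <- function(x, ...) {
  cat(sprintf("Wood curve parameters: a = %.4g, b = %.4g, c = %.4g\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Evaluate the Wood fat-percentage curve
#'
#' @param params A [wood_params] object.
#' @param t Vector of lactation months, all strictly positive.
#'
#' @return Fat percentage `a * t^-b * exp(c t)` at each `t`; strictly positive.
#' @export
wood_curve <- function(params, t) {
  stopifnot(inherits(params, "wood_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop("`t` must be strictly positive lactation months", call. = FALSE)
  }
  params$a * t^(-params$b) * exp(params$c * t)
}

#' Derived lactation traits of a Wood fat-percentage curve
#'
#' Computes the closed-form summaries of the minimum-shaped Wood curve:
#' time to the fat minimum `T_min = b/c` (months, also reported in days),
#' the minimum fat percentage `Y_min = a (b/c)^-b e^b`, and the persistency
#' score `Per = -(b + 1) ln c`. When `b = 0` or `c = 0` the curve is monotone
#' and has no interior minimum; the result is flagged `degenerate` and the
#' minimum-location traits are `NA` (persistency is still finite when
#' `c > 0`).
#'
#' @param params A [wood_params] object.
#' @param days_per_month Days per lactation month used to convert `T_min`
#'   from months to days. Default 30.25; 30 matches the month-binning width.
#'
#' @return An object of class `wood_traits`: a list with `t_min_months`,
#'   `t_min_days` (rounded to integer days), `y_min_pct`, `persistency`,
#'   `degenerate`.
#' @export
wood_traits <- function(params, days_per_month = 30.25) {
  stopifnot(inherits(params, "wood_params"))
  stopifnot(is.numeric(days_per_month), days_per_month > 0)
  degenerate <- params$b == 0 || params$c == 0
  persistency <- if (params$c > 0) -(params$b + 1) * log(params$c) else NA_real_
  if (degenerate) {
    out <- list(t_min_months = NA_real_, t_min_days = NA_real_,
                y_min_pct = NA_real_, persistency = persistency,
                degenerate = TRUE)
  } else {
    t_min <- params$b / params$c
    out <- list(
      t_min_months = t_min,
      t_min_days = round(t_min * days_per_month),
      y_min_pct = params$a * t_min^(-params$b) * exp(params$b),
      persistency = persistency,
      degenerate = FALSE
    )
  }
  structure(out, class = "wood_traits")
}

#' @export
print.wood_traits <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate Wood curve (b = 0 or c = 0): no interior fat minimum\n")
    if (is.finite(x$persistency)) {
      cat(sprintf("  persistency = %.2f\n", x$persistency))
    }
  } else {
    cat(sprintf(
      "Fat minimum %.2f%% at %.2f months (%d days); persistency %.2f\n",
      x$y_min_pct, x$t_min_months, as.integer(x$t_min_days), x$persistency))
  }
  invisible(x)
}

#' Locate the curve minimum by grid search and golden-section refinement
#'
#' Brute-force locator of the Wood-curve minimum, independent of the
#' closed-form traits: evaluates the curve on a dense grid over
#' `[t_lo, t_hi]`, takes the grid argmin, and refines it by golden-section
#' search to an interval shorter than `tol`. Intended as a numerical
#' cross-check of [wood_traits()]; a boundary minimum (monotone curve) is
#' returned as the corresponding endpoint.
#'
#' @param params A [wood_params] object.
#' @param t_lo,t_hi Search interval in months, `0 < t_lo < t_hi`.
#' @param n_grid Number of grid points (at least 1000).
#' @param tol Absolute tolerance on the minimiser, default `1e-8`.
#'
#' @return List with `t_min` (months) and `y_min` (%).
#' @export
wood_minimum_search <- function(params, t_lo = 0.01, t_hi = 11,
                                n_grid = 2000, tol = 1e-8) {
  stopifnot(inherits(params, "wood_params"), t_lo > 0, t_hi > t_lo,
            n_grid >= 1000)
  grid <- seq(t_lo, t_hi, length.out = n_grid)
  yg <- wood_curve(params, grid)
  i <- which.min(yg)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo)
  x2 <- lo + phi * (hi - lo)
  f1 <- wood_curve(params, x1)
  f2 <- wood_curve(params, x2)
  while (hi - lo > tol) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo)
      f1 <- wood_curve(params, x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo)
      f2 <- wood_curve(params, x2)
    }
  }
  t_star <- (lo + hi) / 2
  list(t_min = t_star, y_min = wood_curve(params, t_star))
}
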
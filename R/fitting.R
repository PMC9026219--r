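#' Log-linear starting values for the Wood curve
#'
#' The Wood model is exactly linear after a log transform:
#' `ln y = ln a - b ln t + c t`. Ordinary least squares on `(ln t, t)`
#' therefore recovers the parameters exactly from noiseless data and gives a
#' serviceable initialiser for the nonlinear fit otherwise. Negative estimates
#' of `b` or `c` are clamped to zero so the result is a valid parameter set.
#'
#' @param t Lactation months (positive).
#' @param y Fat percentages (positive), same length as `t`.
#'
#' @return A [wood_params] object.
#' @export
wood_init_loglinear <- function(t, y) {
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y))
  if (length(unique(t)) < 3L) {
    stop("need at least 3 distinct lactation months to initialise",
         call. = FALSE)
  }
  if (any(t <= 0) || any(y <= 0)) {
    stop("`t` and `y` must be strictly positive", call. = FALSE)
  }
  co <- stats::coef(stats::lm.fit(cbind(1, log(t), t), log(y)))
  wood_params(a = exp(co[[1L]]), b = max(0, -co[[2L]]), c = max(0, co[[3L]]))
}

#' Fit the Wood curve by damped Gauss-Newton least squares
#'
#' Minimises the residual sum of squares of `y - a t^-b e^{c t}` by
#' Levenberg-Marquardt-style damped Gauss-Newton iterations using the
#' analytic Jacobian (`dY/da = Y/a`, `dY/db = -Y ln t`, `dY/dc = Y t`).
#' Steps that would make `a` non-positive or `b`/`c` negative are rejected
#' and retried with increased damping, so degenerate boundary curves
#' (`b = 0` or `c = 0`) remain reachable while the parameters stay valid.
#' Standard errors come from the Jacobian-based asymptotic covariance at the
#' optimum, `SSE/(n-3) * (J'J)^{-1}`.
#'
#' @param t Lactation months (positive).
#' @param y Fat percentages (positive), same length as `t`.
#' @param init Optional [wood_params] starting values; default is
#'   [wood_init_loglinear()] with a fixed fallback of `(4.0, 0.2, 0.05)` if
#'   the log-linear fit is unavailable.
#' @param tol Convergence tolerance on the relative SSE change per accepted
#'   step, default `1e-10`.
#' @param max_iter Maximum number of outer iterations, default 200.
#'
#' @return An object of class `wood_fit`: a list with `params`
#'   ([wood_params]), `se` (named standard errors of a, b, c; `NA` when
#'   `n <= 3`), `r_squared` (corrected convention),
#'   `r_squared_uncorrected`, `residual_mean_square` (`SSE/(n-3)`), `sse`,
#'   `n_obs`, `converged`, `n_iter`, `init` (starting values used) and
#'   `sse_trace` (SSE after each accepted step).
#' @export
wood_fit <- function(t, y, init = NULL, tol = 1e-10, max_iter = 200) {
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y))
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations to fit", call. = FALSE)
  if (any(t <= 0) || any(y <= 0)) {
    stop("`t` and `y` must be strictly positive", call. = FALSE)
  }
  if (is.null(init)) {
    init <- tryCatch(wood_init_loglinear(t, y),
                     error = function(e) wood_params(4.0, 0.2, 0.05))
  }
  stopifnot(inherits(init, "wood_params"))

  theta <- c(a = init$a, b = init$b, c = init$c)
  model <- function(th) th[[1L]] * t^(-th[[2L]]) * exp(th[[3L]] * t)
  sse_of <- function(th) sum((y - model(th))^2)

  sse <- sse_of(theta)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  trace <- sse
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- model(theta)
    r <- y - mu
    J <- cbind(mu / theta[[1L]], -mu * log(t), mu * t)
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    accepted <- FALSE
    for (k in seq_len(40L)) {
      A <- JtJ + lambda * diag(diag(JtJ), 3L)
      delta <- tryCatch(solve(A, g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        feasible <- cand[[1L]] > 0 && cand[[2L]] >= 0 && cand[[3L]] >= 0
        if (feasible) {
          sse_new <- sse_of(cand)
          if (is.finite(sse_new) && sse_new <= sse) {
            rel <- if (sse > 0) (sse - sse_new) / sse else 0
            theta <- cand
            sse <- sse_new
            trace <- c(trace, sse)
            lambda <- max(lambda / 10, 1e-12)
            accepted <- TRUE
            if (rel < tol) converged <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) {
      # no acceptable step at any damping level: stationary for our purposes
      converged <- TRUE
    }
    if (converged) break
  }

  params <- wood_params(theta[[1L]], max(0, theta[[2L]]), max(0, theta[[3L]]))
  mu <- model(theta)
  J <- cbind(mu / theta[[1L]], -mu * log(t), mu * t)
  se <- rep(NA_real_, 3L)
  if (n > 3L) {
    covm <- tryCatch(sse / (n - 3) * solve(crossprod(J)),
                     error = function(e) NULL)
    if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
  }
  names(se) <- c("a", "b", "c")
  if (n > 3L) {
    gof <- wood_gof(t, y, params)
  } else {
    # exactly determined: residual df is zero, fit statistics are undefined
    gof <- list(r_squared = NA_real_, r_squared_uncorrected = NA_real_,
                residual_mean_square = NA_real_)
  }
  structure(list(
    params = params, se = se,
    r_squared = gof$r_squared,
    r_squared_uncorrected = gof$r_squared_uncorrected,
    residual_mean_square = gof$residual_mean_square,
    sse = sse, n_obs = n, converged = converged, n_iter = iter,
    init = init, sse_trace = trace
  ), class = "wood_fit")
}

#' @export
print.wood_fit <- function(x, ...) {
  cat(sprintf(
    "Wood curve fit on %d observations (%s after %d iterations)\n",
    x$n_obs, if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("  a = %.4f ± %.4f\n", x$params$a, x$se[["a"]]))
  cat(sprintf("  b = %.4f ± %.4f\n", x$params$b, x$se[["b"]]))
  cat(sprintf("  c = %.4f ± %.4f\n", x$params$c, x$se[["c"]]))
  cat(sprintf("  R² = %.4f (uncorrected %.4f), residual mean square = %.4g\n",
              x$r_squared, x$r_squared_uncorrected, x$residual_mean_square))
  invisible(x)
}

#' Goodness of fit of a Wood curve
#'
#' Computes the residual sum of squares of the observations around the given
#' curve and reports the coefficient of determination under both common
#' conventions: corrected, `1 - SSE / sum((y - mean(y))^2)`, and
#' uncorrected, `1 - SSE / sum(y^2)` (the convention some nonlinear
#' regression programs print for models without an intercept). The residual
#' mean square is `SSE/(n-3)`, with 3 the number of curve parameters.
#'
#' @param t Lactation months (positive).
#' @param y Fat percentages, same length as `t`.
#' @param params A [wood_params] object.
#'
#' @return List with `r_squared` (corrected; `NA` and `flag =
#'   "undefined_tss"` when all `y` are equal), `r_squared_uncorrected`,
#'   `residual_mean_square`, `sse`, and `flag` (`"ok"`, `"poor_fit"` when the
#'   corrected R-squared is not positive, or `"undefined_tss"`).
#' @export
wood_gof <- function(t, y, params) {
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y))
  n <- length(y)
  if (n < 4L) stop("need at least 4 observations for goodness of fit",
                   call. = FALSE)
  resid <- y - wood_curve(params, t)
  sse <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  uss <- sum(y^2)
  r2u <- 1 - sse / uss
  if (tss == 0) {
    list(r_squared = NA_real_, r_squared_uncorrected = r2u,
         residual_mean_square = sse / (n - 3), sse = sse,
         flag = "undefined_tss")
  } else {
    r2 <- 1 - sse / tss
    list(r_squared = r2, r_squared_uncorrected = r2u,
         residual_mean_square = sse / (n - 3), sse = sse,
         flag = if (r2 <= 0) "poor_fit" else "ok")
  }
}
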
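.factor_cols <- c("farm_size_class", "parity_class", "season", "ci_class",
                  "milk_class")

#' Fixed-effects least-squares model for milk fat percentage
#'
#' Fits the additive fixed-effects model
#' `fat = mu + farm size + parity + season + calving interval + 305-d yield`
#' (no interactions) by ordinary least squares, under sum-to-zero contrasts
#' so the intercept is the grand least-squares mean. Records with a missing
#' class in any requested factor are excluded (their count is reported on
#' the object). Rank deficiency beyond the identifiability constraints —
#' confounded factor levels — raises an error naming the aliased columns.
#'
#' Because first-parity cows have no previous calving, the calving-interval
#' level `"none"` occurs exactly when parity is 1; with both factors in the
#' model those two indicators are identical and one degree of freedom is
#' lost. The model absorbs this by giving the `"none"` level a zero contrast
#' row (its effect is carried by the parity-1 effect) while the real
#' interval levels stay sum-to-zero among themselves, keeping the design
#' full rank. The `"none"` level is reported non-estimable by
#' [fat_lsmeans()].
#'
#' @param records Data frame from [assign_factor_bins()] with `fat_pct` and
#'   the factor class columns.
#' @param factors Character vector of factor columns to include; default the
#'   five non-genetic factors.
#'
#' @return An object of class `fat_factor_model`: list with `fit` (the
#'   underlying `lm`), `factors`, `contrasts` (per-factor contrast
#'   matrices), `data` (the analysed rows), `n_used`, `n_dropped`,
#'   `residual_df`, `mse`.
#' @export
fat_factor_model <- function(records, factors = .factor_cols) {
  stopifnot("fat_pct" %in% names(records),
            all(factors %in% names(records)), length(factors) >= 1L)
  dat <- records[, c("fat_pct", factors), drop = FALSE]
  for (f in factors) dat[[f]] <- as.factor(dat[[f]])
  complete <- stats::complete.cases(dat)
  n_dropped <- sum(!complete)
  dat <- droplevels(dat[complete, , drop = FALSE])
  for (f in factors) {
    if (nlevels(dat[[f]]) < 2L) {
      stop("factor `", f, "` has fewer than 2 observed levels", call. = FALSE)
    }
  }
  contr <- lapply(factors, function(f) {
    levs <- levels(dat[[f]])
    k <- length(levs)
    C <- stats::contr.sum(k)
    rownames(C) <- levs
    # "none" interval exists exactly for parity-1 records: absorb its effect
    # into the parity-1 coefficient via a zero contrast row
    if (f == "ci_class" && "none" %in% levs &&
        "parity_class" %in% factors && k > 2L) {
      C <- matrix(0, k, k - 2L, dimnames = list(levs, NULL))
      real <- setdiff(levs, "none")
      C[real, ] <- stats::contr.sum(length(real))
    }
    C
  })
  names(contr) <- factors
  form <- stats::as.formula(paste("fat_pct ~", paste(factors, collapse = " + ")))
  fit <- stats::lm(form, data = dat, contrasts = contr)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("confounded design: aliased columns ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  structure(list(
    fit = fit, factors = factors, contrasts = contr, data = dat,
    n_used = nrow(dat), n_dropped = n_dropped,
    residual_df = fit$df.residual,
    mse = sum(stats::resid(fit)^2) / fit$df.residual
  ), class = "fat_factor_model")
}

#' @export
print.fat_factor_model <- function(x, ...) {
  cat(sprintf(
    "Fixed-effects fat%% model: %d records (%d dropped), factors: %s\n",
    x$n_used, x$n_dropped, paste(x$factors, collapse = ", ")))
  cat(sprintf("  residual df = %d, residual mean square = %.4g\n",
              x$residual_df, x$mse))
  invisible(x)
}

#' Least-squares means of a factor
#'
#' The least-squares mean of a level is the model prediction at that level
#' with every other factor averaged with equal weight over its observed
#' levels; under sum-to-zero contrasts this is the intercept plus the
#' level's own effect. Standard errors come from the variance of the
#' corresponding linear contrast of the coefficients. In a balanced design
#' the LSM equals the raw level mean.
#'
#' @param model A [fat_factor_model()].
#' @param factor Name of one of the model's factors.
#'
#' @return Data frame with one row per level: `level`, `n`, `lsm`, `se`,
#'   `estimable` (`FALSE` for a level whose effect is absorbed by another
#'   factor, e.g. the `"none"` calving interval of first-parity cows).
#' @export
fat_lsmeans <- function(model, factor) {
  stopifnot(inherits(model, "fat_factor_model"))
  if (!factor %in% model$factors) {
    stop("`", factor, "` is not a factor of this model", call. = FALSE)
  }
  fit <- model$fit
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  levs <- levels(model$data[[factor]])
  k <- length(levs)
  contrast_row <- function(f, level = NULL) {
    C <- model$contrasts[[f]]
    cols <- paste0(f, seq_len(ncol(C)))
    stopifnot(all(cols %in% names(beta)))
    v <- if (is.null(level)) colMeans(C) else C[level, ]
    stats::setNames(v, cols)
  }
  out <- data.frame(level = levs, n = as.integer(table(model$data[[factor]])),
                    lsm = NA_real_, se = NA_real_, estimable = TRUE,
                    stringsAsFactors = FALSE)
  C_self <- model$contrasts[[factor]]
  absorbed <- rowSums(C_self != 0) == 0 & k > 1L
  for (i in seq_len(k)) {
    x <- stats::setNames(numeric(length(beta)), names(beta))
    x[["(Intercept)"]] <- 1
    for (f in model$factors) {
      row <- if (f == factor) contrast_row(f, levs[i]) else contrast_row(f)
      x[names(row)] <- row
    }
    out$lsm[i] <- sum(x * beta)
    out$se[i] <- sqrt(drop(t(x) %*% V %*% x))
    if (absorbed[i]) {
      # its effect column was absorbed elsewhere: the LSM is not estimable
      out$lsm[i] <- NA_real_
      out$se[i] <- NA_real_
      out$estimable[i] <- FALSE
    }
  }
  out
}

#' Type-III partial F tests for each factor
#'
#' For each factor, the increase in residual sum of squares when that
#' factor's columns are dropped from the full model (all other factors
#' retained), divided by the factor's degrees of freedom and the full
#' model's residual mean square. Under a balanced design this coincides
#' with the classical sequential ANOVA F. Significance flags follow the
#' usual convention: `**` for p <= 0.01 (extremely significant), `*` for
#' p <= 0.05, `NS` otherwise.
#'
#' @param model A [fat_factor_model()].
#' @return Data frame with `factor`, `df`, `f_value`, `p_value`, `flag`.
#' @export
fat_partial_f <- function(model) {
  stopifnot(inherits(model, "fat_factor_model"))
  d1 <- stats::drop1(model$fit, scope = stats::as.formula(
    paste("~", paste(model$factors, collapse = " + "))), test = "F")
  d1 <- d1[model$factors, , drop = FALSE]
  p <- d1[["Pr(>F)"]]
  data.frame(
    factor = model$factors,
    df = d1$Df,
    f_value = d1[["F value"]],
    p_value = p,
    flag = ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "NS")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.duncan_lsr <- function(p, df, alpha, mse, n_h) {
  stats::qtukey((1 - alpha)^(p - 1), p, df) * sqrt(mse / n_h)
}

#' Duncan's multiple range test
#'
#' Stepwise multiple comparison of factor-level means. For a span of `p`
#' ordered means the least significant range is
#' `q(gamma_p, p, df) * sqrt(mse / n_h)`, where `gamma_p = (1-alpha)^(p-1)`
#' is Duncan's protection level, `q` the studentized-range quantile and
#' `n_h` the harmonic mean of the span's level counts (equal to the common
#' `n` when counts are equal). Testing proceeds from the full span downward;
#' a span whose range falls short of its least significant range is declared
#' homogeneous and none of its sub-spans are tested. Levels sharing a letter
#' do not differ at `alpha`.
#'
#' @param means Named numeric vector of level means.
#' @param n Level counts (recycled if length 1).
#' @param mse Residual mean square of the underlying model.
#' @param df Residual degrees of freedom (at least 1).
#' @param alpha Test level; default 0.01 with capital letters (the
#'   convention for "extremely significant" groupings); alpha = 0.05 uses
#'   lowercase letters.
#'
#' @return An object of class `duncan_grouping`: data frame sorted by
#'   decreasing mean with `level`, `mean`, `n`, `letters`; attribute
#'   `alpha`.
#' @export
duncan_mrt <- function(means, n, mse, df, alpha = 0.01) {
  stopifnot(is.numeric(means), length(means) >= 2L, mse > 0, df >= 1)
  if (is.null(names(means))) names(means) <- as.character(seq_along(means))
  if (length(n) == 1L) n <- rep(n, length(means))
  stopifnot(length(n) == length(means), all(n >= 1))
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  nn <- n[ord]
  k <- length(m)

  groups <- list()
  # step-down: a homogeneous span shields all its sub-spans
  test_span <- function(i, j) {
    if (j <= i) return(invisible(NULL))
    p <- j - i + 1L
    n_h <- p / sum(1 / nn[i:j])
    if (m[i] - m[j] < .duncan_lsr(p, df, alpha, mse, n_h)) {
      groups[[length(groups) + 1L]] <<- c(i, j)
    } else {
      test_span(i, j - 1L)
      test_span(i + 1L, j)
    }
  }
  test_span(1L, k)
  groups <- unique(groups)
  # keep maximal spans only
  if (length(groups)) {
    keep <- vapply(seq_along(groups), function(g) {
      !any(vapply(seq_along(groups), function(h) {
        h != g && groups[[h]][1] <= groups[[g]][1] &&
          groups[[h]][2] >= groups[[g]][2]
      }, logical(1)))
    }, logical(1))
    groups <- groups[keep]
    groups <- groups[order(vapply(groups, `[`, numeric(1), 1L))]
  }
  # singletons not covered by any span get their own letter
  covered <- rep(FALSE, k)
  for (g in groups) covered[g[1]:g[2]] <- TRUE
  for (i in which(!covered)) groups[[length(groups) + 1L]] <- c(i, i)
  groups <- groups[order(vapply(groups, `[`, numeric(1), 1L),
                         vapply(groups, `[`, numeric(1), 2L))]

  alphabet <- if (alpha <= 0.01) LETTERS else letters
  if (length(groups) > length(alphabet)) {
    stop("more homogeneous groups than letters available", call. = FALSE)
  }
  lab <- character(k)
  for (g in seq_along(groups)) {
    idx <- groups[[g]][1]:groups[[g]][2]
    lab[idx] <- paste0(lab[idx], alphabet[g])
  }
  structure(data.frame(
    level = names(m), mean = unname(m), n = unname(nn), letters = lab,
    stringsAsFactors = FALSE
  ), class = c("duncan_grouping", "data.frame"), alpha = alpha)
}

#' @export
print.duncan_grouping <- function(x, ...) {
  cat(sprintf("Duncan multiple range test (alpha = %g)\n", attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Factor-level summary table: LSM, SE, Duncan letters and partial F
#'
#' Convenience wrapper combining [fat_lsmeans()], [duncan_mrt()] and
#' [fat_partial_f()] for one factor of a fitted model, in the layout of a
#' factor-effects report table.
#'
#' @param model A [fat_factor_model()].
#' @param factor One of the model's factors.
#' @param alpha Duncan test level, default 0.01.
#' @return Data frame `level`, `n`, `lsm`, `se`, `letters`; attributes
#'   `f_value`, `p_value`, `flag` carry the factor's partial F test.
#' @export
fat_factor_table <- function(model, factor, alpha = 0.01) {
  lsm <- fat_lsmeans(model, factor)
  est <- lsm[lsm$estimable, , drop = FALSE]
  dg <- duncan_mrt(stats::setNames(est$lsm, est$level), est$n,
                   mse = model$mse, df = model$residual_df, alpha = alpha)
  lsm$letters <- dg$letters[match(lsm$level, dg$level)]
  ft <- fat_partial_f(model)
  i <- match(factor, ft$factor)
  attr(lsm, "f_value") <- ft$f_value[i]
  attr(lsm, "p_value") <- ft$p_value[i]
  attr(lsm, "flag") <- ft$flag[i]
  lsm
}
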
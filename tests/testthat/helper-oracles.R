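# independent oracles, deliberately written along different routes than the
# package implementation

# dense grid search over the (a, b, c) box; the profile over `a` is
# evaluated in closed form from the sufficient statistics of each (b, c)
oracle_grid_sse <- function(t, y, a_range = c(3, 5), b_range = c(0.05, 0.5),
                            c_range = c(0.02, 0.1), n = 60) {
  av <- seq(a_range[1], a_range[2], length.out = n)
  bv <- seq(b_range[1], b_range[2], length.out = n)
  cv <- seq(c_range[1], c_range[2], length.out = n)
  sy2 <- sum(y^2)
  best <- Inf
  for (b in bv) {
    tb <- t^(-b)
    for (cc in cv) {
      g <- tb * exp(cc * t)
      syg <- sum(y * g)
      sgg <- sum(g * g)
      best <- min(best, min(sy2 - 2 * av * syg + av^2 * sgg))
    }
  }
  best
}

# least-squares means by generalized-inverse normal equations on the
# overparameterized dummy design
oracle_lsm_ginv <- function(data, response, factors, target) {
  blocks <- lapply(factors, function(f) {
    stats::model.matrix(~ 0 + data[[f]])
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  y <- data[[response]]
  G <- MASS::ginv(crossprod(X))
  beta <- G %*% crossprod(X, y)
  rank <- qr(X)$rank
  mse <- sum((y - X %*% beta)^2) / (nrow(X) - rank)
  klev <- vapply(blocks, ncol, integer(1))
  offs <- cumsum(c(1L, klev))
  ti <- match(target, factors)
  levs <- levels(data[[target]])
  out <- data.frame(level = levs, lsm = NA_real_, se = NA_real_,
                    stringsAsFactors = FALSE)
  for (l in seq_along(levs)) {
    x <- numeric(ncol(X))
    x[1] <- 1
    for (f in seq_along(factors)) {
      idx <- offs[f] + seq_len(klev[f])
      if (f == ti) x[idx[l]] <- 1 else x[idx] <- 1 / klev[f]
    }
    out$lsm[l] <- drop(x %*% beta)
    out$se[l] <- sqrt(mse * drop(t(x) %*% G %*% x))
  }
  out
}

# Duncan grouping by exhaustive span enumeration: every contiguous span is
# tested against its own least significant range; a span contained in a
# homogeneous span is protected; groups are the maximal protected spans
oracle_duncan_groups <- function(means, n, mse, df, alpha) {
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  nn <- n[ord]
  k <- length(m)
  nonsig <- matrix(FALSE, k, k)
  for (i in 1:k) for (j in i:k) {
    p <- j - i + 1L
    if (p == 1L) {
      nonsig[i, j] <- TRUE
    } else {
      nh <- p / sum(1 / nn[i:j])
      lsr <- qtukey((1 - alpha)^(p - 1), p, df) * sqrt(mse / nh)
      nonsig[i, j] <- (m[i] - m[j]) < lsr
    }
  }
  prot <- matrix(FALSE, k, k)
  for (i in 1:k) for (j in i:k) {
    for (u in 1:i) for (v in j:k) {
      if (nonsig[u, v]) prot[i, j] <- TRUE
    }
  }
  spans <- list()
  for (i in 1:k) for (j in i:k) {
    if (prot[i, j] && !(i > 1 && prot[i - 1, j]) &&
        !(j < k && prot[i, j + 1])) {
      spans[[length(spans) + 1L]] <- sort(names(m)[i:j])
    }
  }
  spans[order(vapply(spans, `[`, character(1), 1L))]
}

# letters -> list of level sets sharing a letter, for comparison with the
# span oracle
grouping_to_sets <- function(grouping) {
  letters_used <- unique(unlist(strsplit(grouping$letters, "")))
  sets <- lapply(letters_used, function(L) {
    sort(grouping$level[grepl(L, grouping$letters, fixed = TRUE)])
  })
  sets[order(vapply(sets, `[`, character(1), 1L))]
}
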
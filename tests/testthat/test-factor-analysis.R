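# balanced two-factor layout used by the equivalence checks
balanced_fixture <- function(seed = 21, reps = 6) {
  set.seed(seed)
  dat <- expand.grid(g1 = factor(c("a", "b", "c")),
                     g2 = factor(c("x", "y")),
                     rep = seq_len(reps))
  dat$fat_pct <- 3.8 + c(a = -0.1, b = 0, c = 0.1)[dat$g1] +
    c(x = -0.05, y = 0.05)[dat$g2] + rnorm(nrow(dat), 0, 0.1)
  dat
}

test_that("under balance the LSM equals the raw level mean", {
  dat <- balanced_fixture()
  m <- fat_factor_model(dat, factors = c("g1", "g2"))
  lsm <- fat_lsmeans(m, "g1")
  raw <- tapply(dat$fat_pct, dat$g1, mean)
  expect_equal(lsm$lsm, as.numeric(raw[lsm$level]), tolerance = 1e-12)
  expect_true(all(lsm$se > 0))
  expect_true(all(lsm$estimable))
})

test_that("under balance the partial F equals the classical ANOVA F", {
  dat <- balanced_fixture()
  m <- fat_factor_model(dat, factors = c("g1", "g2"))
  ft <- fat_partial_f(m)
  av <- summary(stats::aov(fat_pct ~ g1 + g2, data = dat))[[1]]
  expect_equal(ft$f_value, av[c("g1", "g2"), "F value"], tolerance = 1e-10)
  expect_equal(ft$p_value, av[c("g1", "g2"), "Pr(>F)"], tolerance = 1e-10)
})

test_that("single-factor LSMs are the raw means exactly", {
  dat <- balanced_fixture()
  dat <- dat[-c(1, 5, 8), ]  # unbalance it; one-way LSM is still the mean
  m <- fat_factor_model(dat, factors = "g1")
  lsm <- fat_lsmeans(m, "g1")
  raw <- tapply(dat$fat_pct, dat$g1, mean)
  expect_equal(lsm$lsm, as.numeric(raw[lsm$level]), tolerance = 1e-12)
})

test_that("unbalanced LSMs and SEs match the generalized-inverse oracle", {
  dat <- unbalanced_two_factor_fixture()
  names(dat)[names(dat) == "y"] <- "fat_pct"
  m <- fat_factor_model(dat, factors = c("g1", "g2"))
  for (target in c("g1", "g2")) {
    lsm <- fat_lsmeans(m, target)
    orc <- oracle_lsm_ginv(dat, "fat_pct", c("g1", "g2"), target)
    expect_equal(lsm$lsm, orc$lsm, tolerance = 1e-10)
    expect_equal(lsm$se, orc$se, tolerance = 1e-10)
  }
})

test_that("LSMs agree with emmeans on an unbalanced design", {
  skip_if_not_installed("emmeans")
  dat <- unbalanced_two_factor_fixture(seed = 12)
  names(dat)[names(dat) == "y"] <- "fat_pct"
  m <- fat_factor_model(dat, factors = c("g1", "g2"))
  em <- as.data.frame(emmeans::emmeans(m$fit, "g1"))
  lsm <- fat_lsmeans(m, "g1")
  expect_equal(lsm$lsm, em$emmean[match(lsm$level, em$g1)],
               tolerance = 1e-10)
  expect_equal(lsm$se, em$SE[match(lsm$level, em$g1)], tolerance = 1e-10)
})

test_that("duplicated levels give identical LSM and SE", {
  dat <- balanced_fixture()
  dup <- dat
  dup$g1 <- factor(ifelse(as.character(dup$g1) == "c", "b",
                          as.character(dup$g1)))
  # make two truly identical levels by duplicating level b's data as "c"
  extra <- dup[dup$g1 == "b", ]
  extra$g1 <- "c"
  dat2 <- rbind(dup, extra)
  dat2$g1 <- factor(dat2$g1)
  m <- fat_factor_model(dat2, factors = c("g1", "g2"))
  lsm <- fat_lsmeans(m, "g1")
  expect_equal(lsm$lsm[lsm$level == "b"], lsm$lsm[lsm$level == "c"],
               tolerance = 1e-12)
  expect_equal(lsm$se[lsm$level == "b"], lsm$se[lsm$level == "c"],
               tolerance = 1e-12)
})

test_that("perfectly confounded factors raise an aliasing error", {
  dat <- balanced_fixture()
  dat$g3 <- dat$g1  # copy: fully aliased
  expect_error(fat_factor_model(dat, factors = c("g1", "g3")),
               "confounded|aliased")
})

test_that("the parity-1 'none' interval level is absorbed, not aliased", {
  sim <- simulate_herd(sim_config(n_cows = 300), seed = 5)
  lab <- assign_factor_bins(qc_filter(sim$records)$records)
  m <- fat_factor_model(lab)
  expect_s3_class(m$fit, "lm")
  lsm <- fat_lsmeans(m, "ci_class")
  expect_false(lsm$estimable[lsm$level == "none"])
  expect_true(all(lsm$estimable[lsm$level != "none"]))
  expect_true(all(is.finite(lsm$lsm[lsm$level != "none"])))
  # the factor table runs Duncan on the estimable levels only
  tab <- fat_factor_table(m, "ci_class")
  expect_true(is.na(tab$letters[tab$level == "none"]))
})

test_that("a large injected effect is flagged extremely significant", {
  set.seed(99)
  n <- 5000
  dat <- data.frame(
    g1 = factor(sample(c("lo", "hi"), n, replace = TRUE)),
    g2 = factor(sample(c("x", "y", "z"), n, replace = TRUE))
  )
  dat$fat_pct <- 3.8 + ifelse(dat$g1 == "hi", 0.5, 0) + rnorm(n, 0, 0.23)
  m <- fat_factor_model(dat, factors = c("g1", "g2"))
  ft <- fat_partial_f(m)
  expect_identical(ft$flag[ft$factor == "g1"], "**")
})

test_that("Duncan assigns one letter to indistinguishable means", {
  g <- duncan_mrt(c(a = 3.8, b = 3.8), n = 50, mse = 0.05, df = 98)
  expect_equal(g$letters, c("A", "A"))
  g2 <- duncan_mrt(c(a = 3.0, b = 5.0), n = 100, mse = 1e-6, df = 198,
                   alpha = 0.01)
  expect_setequal(g2$letters, c("A", "B"))
})

test_that("Duncan groupings match the span-enumeration oracle", {
  means <- c(p1 = 3.76, p2 = 3.85, p3 = 3.92, p4 = 4.01)
  g <- duncan_mrt(means, n = 500, mse = 0.15, df = 1996, alpha = 0.01)
  expect_equal(grouping_to_sets(g),
               oracle_duncan_groups(means, rep(500, 4), 0.15, 1996, 0.01))
  # unequal level counts exercise the harmonic-mean spans
  means2 <- c(a = 3.70, b = 3.78, c = 3.80, d = 3.95, e = 3.97)
  n2 <- c(40, 200, 35, 120, 60)
  g2 <- duncan_mrt(means2, n2, mse = 0.12, df = 450, alpha = 0.05)
  expect_equal(grouping_to_sets(g2),
               oracle_duncan_groups(means2, n2, 0.12, 450, 0.05))
  # lowercase letters at the 5% level
  expect_true(all(grepl("^[a-z]+$", g2$letters)))
})

test_that("Duncan letters are invariant to input ordering and order-consistent", {
  means <- c(a = 3.70, b = 3.78, c = 3.80, d = 3.95)
  n <- c(40, 200, 35, 120)
  g <- duncan_mrt(means, n, mse = 0.12, df = 450)
  perm <- c(3, 1, 4, 2)
  g2 <- duncan_mrt(means[perm], n[perm], mse = 0.12, df = 450)
  expect_equal(g[order(g$level), ], g2[order(g2$level), ],
               ignore_attr = TRUE)
  # order consistency: significantly different pairs share no letter and
  # every pair separated further apart is also significantly different
  sets <- grouping_to_sets(g)
  shared <- function(x, y) any(vapply(sets, function(s) all(c(x, y) %in% s),
                                      logical(1)))
  lv <- g$level  # sorted by decreasing mean
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (j > i + 1 && !shared(lv[i], lv[i + 1])) {
      expect_false(shared(lv[i], lv[j]))
    }
  }
})

test_that("degenerate Duncan inputs are rejected", {
  expect_error(duncan_mrt(c(a = 3.8), n = 10, mse = 0.1, df = 9), "2")
  expect_error(duncan_mrt(c(a = 3.8, b = 3.9), n = 10, mse = 0, df = 9),
               "mse")
  expect_error(duncan_mrt(c(a = 3.8, b = 3.9), n = 10, mse = 0.1, df = 0),
               "df")
})
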
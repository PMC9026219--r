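# fixtures built in code; no data files

make_wood_points <- function(params, t = 1:11) {
  list(t = t, y = wood_curve(params, t))
}

# random draws over the parameter box typical of fat-percentage curves
rand_wood_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    wood_params(a = runif(1, 3, 5), b = runif(1, 0.05, 0.5),
                c = runif(1, 0.02, 0.1))
  })
}

# ten well-formed single test-day records
ten_record_fixture <- function() {
  data.frame(
    cow_id = sprintf("C%03d", 1:10),
    farm_id = "F1",
    farm_size_count = 1500,
    test_date = as.Date("2019-06-15") + 0:9,
    calving_date = as.Date("2019-04-01"),
    parity = c(1, 2, 3, 1, 2, 4, 5, 1, 2, 3),
    days_in_milk = c(75, 45, 105, 135, 165, 15, 195, 225, 255, 285),
    fat_pct = c(3.5, 3.7, 3.9, 3.6, 3.8, 4.0, 3.4, 3.5, 3.7, 3.9),
    calving_interval_days = c(NA, 380, 410, NA, 350, 430, 450, NA, 370, 390),
    milk_305d_kg = c(9500, 10500, 8000, 12000, 11500, 6500, 4500, 13500,
                     9000, 10000),
    stringsAsFactors = FALSE
  )
}

# unbalanced two-factor layout with effects set by hand (no parity/interval
# confounding, so every LSM is estimable)
unbalanced_two_factor_fixture <- function(seed = 11) {
  set.seed(seed)
  cells <- expand.grid(g1 = c("a", "b", "c", "d"), g2 = c("x", "y"),
                       stringsAsFactors = FALSE)
  counts <- c(5, 2, 4, 1, 3, 5, 2, 4)
  eff1 <- c(a = 0, b = 0.2, c = -0.1, d = 0.4)
  eff2 <- c(x = 0, y = 0.3)
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(g1 = cells$g1[i], g2 = cells$g2[i],
               y = 3.8 + eff1[[cells$g1[i]]] + eff2[[cells$g2[i]]] +
                 rnorm(counts[i], 0, 0.15),
               stringsAsFactors = FALSE)
  }))
  rows$g1 <- factor(rows$g1)
  rows$g2 <- factor(rows$g2)
  rows
}
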
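#' Default Wood parameters per calving season
#'
#' Season-specific curve parameters used by the simulator's default
#' configuration, on the scale typical of Holstein milk-fat-percentage
#' curves (spring shows the deepest, earliest minimum; winter the largest
#' descent exponent).
#'
#' @return Named list of [wood_params], one per season.
#' @export
season_wood_params <- function() {
  list(
    spring = wood_params(3.68, 0.31, 0.08),
    summer = wood_params(3.54, 0.11, 0.04),
    autumn = wood_params(3.95, 0.16, 0.03),
    winter = wood_params(4.07, 0.35, 0.08)
  )
}

#' Simulation configuration for a synthetic DHI herd
#'
#' Defaults describe a multi-farm Holstein population: four farms spanning
#' the herd-size classes with most cows on the largest farm; parity
#' frequencies declining from first to fifth lactation; calvings
#' concentrated in autumn and winter; calving intervals mostly 300-400 days;
#' 305-day yields centred on 9000-13000 kg; season-specific Wood fat curves
#' ([season_wood_params()]) observed every 30 days from day 15 in milk with
#' i.i.d. Gaussian noise of SD 0.232 percentage points (the square root of a
#' typical residual mean square of 0.054).
#'
#' @param n_cows Number of cows, default 2000.
#' @param farms Data frame `farm_id`, `head_count`, `prob` (cow allocation).
#' @param parity_probs Probabilities of parities 1-5.
#' @param season_probs Probabilities of spring, summer, autumn, winter.
#' @param ci_classes Data frame `lo`, `hi`, `prob` of calving-interval
#'   ranges in days (parity >= 2 only).
#' @param milk_classes Data frame `lo`, `hi`, `prob` of 305-day-yield
#'   ranges in kg.
#' @param stratum_factor Cow attribute driving the curve parameters,
#'   default `"season"`.
#' @param stratum_params Named list of [wood_params], one per stratum level.
#' @param noise_sd SD of the Gaussian test-day noise, in fat-% points.
#' @param test_start,test_interval,max_dim Test-day schedule: first test
#'   day in milk, spacing in days, last allowed day in milk.
#' @param years Calendar years calvings are drawn from.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cows = 2000,
                       farms = data.frame(
                         farm_id = c("F1", "F2", "F3", "F4"),
                         head_count = c(800, 1500, 3500, 8000),
                         prob = c(0.048, 0.075, 0.115, 0.762)),
                       parity_probs = c(0.395, 0.310, 0.173, 0.071, 0.051),
                       season_probs = c(spring = 0.116, summer = 0.134,
                                        autumn = 0.448, winter = 0.302),
                       ci_classes = data.frame(
                         lo = c(300, 366, 401, 421, 441),
                         hi = c(365, 400, 420, 440, 520),
                         prob = c(0.409, 0.265, 0.085, 0.057, 0.184)),
                       milk_classes = data.frame(
                         lo = c(3000, 5001, 7001, 9001, 11001, 13001),
                         hi = c(5000, 7000, 9000, 11000, 13000, 15000),
                         prob = c(0.006, 0.037, 0.166, 0.351, 0.286, 0.154)),
                       stratum_factor = "season",
                       stratum_params = season_wood_params(),
                       noise_sd = 0.232,
                       test_start = 15, test_interval = 30, max_dim = 305,
                       years = 2018:2020) {
  stopifnot(n_cows >= 1, noise_sd >= 0, test_start >= 1,
            test_interval >= 1, max_dim >= test_start)
  for (p in list(farms$prob, parity_probs, season_probs, ci_classes$prob,
                 milk_classes$prob)) {
    stopifnot(abs(sum(p) - 1) < 1e-6, all(p >= 0))
  }
  stopifnot(all(vapply(stratum_params, inherits, logical(1), "wood_params")))
  structure(list(
    n_cows = n_cows, farms = farms, parity_probs = parity_probs,
    season_probs = season_probs, ci_classes = ci_classes,
    milk_classes = milk_classes, stratum_factor = stratum_factor,
    stratum_params = stratum_params, noise_sd = noise_sd,
    test_start = test_start, test_interval = test_interval,
    max_dim = max_dim, years = years
  ), class = "sim_config")
}

.season_months <- list(spring = 3:5, summer = 6:8, autumn = 9:11,
                       winter = c(12, 1, 2))

#' Simulate a DHI test-day herd with known ground truth
#'
#' Each cow receives a farm, parity, calving season (and a calving date in
#' that season), a calving interval (parity >= 2), and a 305-day yield, all
#' drawn from the configured distributions. Test days run every
#' `test_interval` days from `test_start` through `max_dim`; the fat
#' percentage of a test day is the cow's stratum Wood curve evaluated at the
#' test day's lactation month, plus i.i.d. Gaussian noise truncated to stay
#' positive. Fully reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for all randomness.
#'
#' @return List with `records` (a test-day record data frame readable and
#'   writable by the data-io functions) and `truth` (list: `stratum_factor`,
#'   `stratum_params`, `stratum_traits`, `cows` — the per-cow attribute
#'   table).
#' @export
simulate_herd <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_cows
  strata <- names(config$stratum_params)
  if (config$stratum_factor == "season" &&
      !all(names(config$season_probs) %in% strata)) {
    stop("every season with positive probability needs stratum parameters",
         call. = FALSE)
  }

  fi <- sample.int(nrow(config$farms), n, replace = TRUE,
                   prob = config$farms$prob)
  parity <- sample.int(5L, n, replace = TRUE, prob = config$parity_probs)
  season <- sample(names(config$season_probs), n, replace = TRUE,
                   prob = config$season_probs)
  year <- sample(config$years, n, replace = TRUE)
  month <- vapply(season, function(s) {
    ms <- .season_months[[s]]
    ms[sample.int(length(ms), 1L)]
  }, numeric(1))
  day <- sample.int(28L, n, replace = TRUE)
  calving_date <- as.Date(sprintf("%d-%02d-%02d", year, month, day))

  cic <- sample.int(nrow(config$ci_classes), n, replace = TRUE,
                    prob = config$ci_classes$prob)
  ci <- config$ci_classes$lo[cic] +
    floor(stats::runif(n) * (config$ci_classes$hi[cic] -
                               config$ci_classes$lo[cic] + 1))
  ci[parity == 1L] <- NA_real_

  mc <- sample.int(nrow(config$milk_classes), n, replace = TRUE,
                   prob = config$milk_classes$prob)
  milk <- config$milk_classes$lo[mc] +
    floor(stats::runif(n) * (config$milk_classes$hi[mc] -
                               config$milk_classes$lo[mc] + 1))

  stratum <- switch(config$stratum_factor,
    season = season,
    parity = as.character(parity),
    stop("unsupported stratum factor: ", config$stratum_factor,
         call. = FALSE)
  )
  missing_strata <- setdiff(unique(stratum), strata)
  if (length(missing_strata)) {
    stop("no Wood parameters configured for stratum: ",
         paste(missing_strata, collapse = ", "), call. = FALSE)
  }

  cows <- data.frame(
    cow_id = sprintf("C%05d", seq_len(n)),
    farm_id = config$farms$farm_id[fi],
    farm_size_count = config$farms$head_count[fi],
    parity = parity, calving_date = calving_date,
    calving_interval_days = ci, milk_305d_kg = milk,
    season = season, stratum = stratum,
    stringsAsFactors = FALSE
  )

  dims <- seq(config$test_start, config$max_dim, by = config$test_interval)
  idx <- rep(seq_len(n), each = length(dims))
  dim_rec <- rep(dims, times = n)
  lm_rec <- lactation_month(dim_rec)
  ab <- vapply(config$stratum_params, function(p) c(p$a, p$b, p$c),
               numeric(3))
  si <- match(stratum[idx], strata)
  mu <- ab[1, si] * lm_rec^(-ab[2, si]) * exp(ab[3, si] * lm_rec)
  fat <- mu + stats::rnorm(length(mu), 0, config$noise_sd)
  fat <- pmax(fat, 1e-6)

  records <- data.frame(
    cow_id = cows$cow_id[idx],
    farm_id = cows$farm_id[idx],
    farm_size_count = cows$farm_size_count[idx],
    test_date = cows$calving_date[idx] + dim_rec,
    calving_date = cows$calving_date[idx],
    parity = cows$parity[idx],
    days_in_milk = dim_rec,
    fat_pct = fat,
    calving_interval_days = cows$calving_interval_days[idx],
    milk_305d_kg = cows$milk_305d_kg[idx],
    stringsAsFactors = FALSE
  )
  truth <- list(
    stratum_factor = config$stratum_factor,
    stratum_params = config$stratum_params,
    stratum_traits = lapply(config$stratum_params, wood_traits),
    cows = cows
  )
  list(records = records, truth = truth)
}

#' Inject known QC violations into a record table
#'
#' Deterministically mutates the first records of the table so each violates
#' exactly one screening rule: `n_parity` records get parity 6, the next
#' `n_dim` get 310 days in milk, the next `n_fat` get 0.5% fat. Used to
#' exercise the QC screen with a known expected outcome.
#'
#' @param records Record data frame (must pass QC beforehand for the
#'   expected count to be exact).
#' @param n_parity,n_dim,n_fat Number of violations per rule.
#'
#' @return List with `records` (mutated), `expected_kept`, and `injected`
#'   (data frame `row`, `rule`).
#' @export
inject_qc_violations <- function(records, n_parity = 0, n_dim = 0,
                                 n_fat = 0) {
  total <- n_parity + n_dim + n_fat
  stopifnot(total <= nrow(records))
  out <- records
  rows <- seq_len(total)
  rule <- rep(c("parity", "days_in_milk", "fat_pct"),
              times = c(n_parity, n_dim, n_fat))
  if (n_parity > 0) out$parity[rows[rule == "parity"]] <- 6
  if (n_dim > 0) out$days_in_milk[rows[rule == "days_in_milk"]] <- 310
  if (n_fat > 0) out$fat_pct[rows[rule == "fat_pct"]] <- 0.5
  list(records = out, expected_kept = nrow(records) - total,
       injected = data.frame(row = rows, rule = rule,
                             stringsAsFactors = FALSE))
}

#' Null-effects dataset: every stratum shares one curve
#'
#' Rebuilds the configuration so all strata share a single Wood parameter
#' set, making every factor's true effect on fat percentage zero. The
#' default shared curve is flat (`a = 3.90, b = 0, c = 0`), so the
#' test-day records are the constant mean plus i.i.d. Gaussian noise —
#' exactly the error structure the fixed-effects model assumes, as a
#' type-I-error calibration requires. A curved shared profile (e.g. the
#' pooled-population parameters `3.89, 0.22, 0.05`) is also a valid null
#' for the factor effects, but its common lactation-stage trend sits in the
#' residual of the five-factor model and makes the F tests conservative;
#' pass it explicitly to study that robustness scenario.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param shared_params The common [wood_params].
#' @return The simulated record data frame.
#' @export
null_effects_dataset <- function(config = sim_config(), seed = 1L,
                                 shared_params = wood_params(3.90, 0, 0)) {
  stopifnot(inherits(config, "sim_config"))
  config$stratum_params <- stats::setNames(
    rep(list(shared_params), length(config$stratum_params)),
    names(config$stratum_params))
  simulate_herd(config, seed = seed)$records
}
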
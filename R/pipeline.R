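utils::globalVariables(c("t", "fat_pct", "level"))

#' Wood-curve fits stratified by a factor
#'
#' For each observed level of the factor, fits the Wood curve to that
#' level's test-day records (fat percentage against integer lactation
#' month), computes the derived traits from the fitted parameters, and
#' appends a pooled `Total` fit over all records. Levels with fewer records
#' than `min_n` are fitted but flagged `low_n`; a stratum whose fit does not
#' converge keeps its row with the traits suppressed.
#'
#' @param records Data frame from [assign_factor_bins()].
#' @param factor One of `farm_size_class`, `parity_class`, `season`,
#'   `ci_class`, `milk_class`.
#' @param min_n Minimum records per stratum before the `low_n` flag, default
#'   50.
#' @param include_total Append the pooled `Total` row, default `TRUE`.
#' @param days_per_month Month-to-day conversion for `T_min`, passed to
#'   [wood_traits()].
#'
#' @return An object of class `stratum_fits`: a list of per-stratum results
#'   (`factor`, `level`, `n_records`, `low_n`, `fit`, `traits`).
#' @export
run_stratified_fits <- function(records, factor, min_n = 50,
                                include_total = TRUE,
                                days_per_month = 30.25) {
  stopifnot(factor %in% names(records),
            all(c("fat_pct", "lactation_month") %in% names(records)))
  f <- records[[factor]]
  levs <- if (is.factor(f)) intersect(levels(f), unique(as.character(f)))
          else sort(unique(as.character(f)))
  fit_one <- function(level, rows) {
    fit <- wood_fit(rows$lactation_month, rows$fat_pct)
    traits <- if (fit$converged) {
      wood_traits(fit$params, days_per_month = days_per_month)
    } else NULL
    list(factor = factor, level = level, n_records = nrow(rows),
         low_n = nrow(rows) < min_n, fit = fit, traits = traits)
  }
  out <- lapply(levs, function(lv) {
    fit_one(lv, records[!is.na(f) & as.character(f) == lv, , drop = FALSE])
  })
  names(out) <- levs
  if (include_total) out$Total <- fit_one("Total", records)
  structure(out, class = "stratum_fits")
}

#' @export
print.stratum_fits <- function(x, ...) {
  print(stratum_table(x))
  invisible(x)
}

#' Report table of stratified Wood fits
#'
#' Flattens a [run_stratified_fits()] result into one row per stratum with
#' the columns of a lactation-curve parameter report: parameters with
#' standard errors (2 dp), `T_min` in months (2 dp) and days (integer),
#' `Y_min` and persistency (2 dp), corrected R-squared (4 dp) and residual
#' mean square (3 dp). Full precision is available on the `stratum_fits`
#' object itself; rounding happens only here.
#'
#' @param results A `stratum_fits` object.
#' @param digits Rounding as above when `TRUE` (default); `FALSE` returns
#'   full precision.
#' @return Data frame, one row per stratum plus the `Total` row.
#' @export
stratum_table <- function(results, digits = TRUE) {
  stopifnot(inherits(results, "stratum_fits"))
  rows <- lapply(results, function(s) {
    tr <- s$traits
    data.frame(
      factor = s$factor, level = s$level, n = s$n_records,
      low_n = s$low_n,
      a = s$fit$params$a, a_se = s$fit$se[["a"]],
      b = s$fit$params$b, b_se = s$fit$se[["b"]],
      c = s$fit$params$c, c_se = s$fit$se[["c"]],
      t_min_month = if (!is.null(tr)) tr$t_min_months else NA_real_,
      t_min_day = if (!is.null(tr)) tr$t_min_days else NA_real_,
      y_min = if (!is.null(tr)) tr$y_min_pct else NA_real_,
      persistency = if (!is.null(tr)) tr$persistency else NA_real_,
      r_squared = s$fit$r_squared,
      residual_mean_square = s$fit$residual_mean_square,
      converged = s$fit$converged,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (digits) {
    two <- c("a", "a_se", "b", "b_se", "c", "c_se", "t_min_month", "y_min",
             "persistency")
    tab[two] <- lapply(tab[two], round, 2)
    tab$r_squared <- round(tab$r_squared, 4)
    tab$residual_mean_square <- round(tab$residual_mean_square, 3)
  }
  tab
}

#' Per-parity descriptive summary of fat percentage
#'
#' Count, mean, standard deviation, minimum and maximum of fat percentage
#' for each parity 1-5 plus a pooled `Total` row. The SD of a single-record
#' parity is undefined and reported `NA`.
#'
#' @param records QC'd record data frame with `parity` and `fat_pct`.
#' @return Data frame `parity`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
run_parity_summary <- function(records) {
  stopifnot(all(c("parity", "fat_pct") %in% names(records)))
  summarise <- function(v) {
    c(n = length(v), mean = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
      min = if (length(v)) min(v) else NA_real_,
      max = if (length(v)) max(v) else NA_real_)
  }
  levs <- sort(unique(records$parity))
  rows <- lapply(levs, function(p) summarise(records$fat_pct[records$parity == p]))
  rows <- c(rows, list(summarise(records$fat_pct)))
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(parity = c(as.character(levs), "Total"), tab,
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Plot fitted fat-percentage curves per factor
#'
#' Evaluates each converged stratum curve on a dense lactation-month grid,
#' writes the curve data to CSV (the deterministic record of the plot), and
#' renders one figure per factor with one line per level.
#'
#' @param results_by_factor Named list of `stratum_fits`, one per factor.
#' @param outdir Output directory (created if needed).
#' @param t_grid Lactation-month grid, default `seq(1, 11, by = 0.05)`.
#' @param include_total Draw the pooled `Total` curve too, default `FALSE`.
#' @param device Image format, `"png"` (default) or `"pdf"`.
#'
#' @return Invisibly, a data frame of the written files (`factor`, `csv`,
#'   `image`).
#' @export
render_curves <- function(results_by_factor, outdir,
                          t_grid = seq(1, 11, by = 0.05),
                          include_total = FALSE, device = "png") {
  stopifnot(is.list(results_by_factor), length(results_by_factor) >= 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- lapply(names(results_by_factor), function(fname) {
    res <- results_by_factor[[fname]]
    stopifnot(inherits(res, "stratum_fits"))
    keep <- Filter(function(s) s$fit$converged &&
                     (include_total || s$level != "Total"), res)
    dat <- do.call(rbind, lapply(keep, function(s) {
      data.frame(factor = fname, level = s$level, t = t_grid,
                 fat_pct = wood_curve(s$fit$params, t_grid),
                 stringsAsFactors = FALSE)
    }))
    csv <- file.path(outdir, paste0("curves_", fname, ".csv"))
    utils::write.csv(dat, csv, row.names = FALSE, quote = FALSE)
    img <- file.path(outdir, paste0("curves_", fname, ".", device))
    p <- ggplot2::ggplot(dat, ggplot2::aes(
      x = t, y = fat_pct, colour = level)) +
      ggplot2::geom_line(linewidth = 0.7) +
      ggplot2::labs(x = "Lactation month", y = "Milk fat percentage (%)",
                    colour = fname,
                    title = paste("Wood fat-percentage curves by", fname)) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(img, p, width = 7, height = 4.5, dpi = 150)
    data.frame(factor = fname, csv = csv, image = img,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, files))
}

#' Run the full analysis on a simulated or supplied herd
#'
#' End-to-end orchestration: simulate a herd (unless records are supplied),
#' QC-screen, assign factor classes and lactation months, and write to
#' `outdir`: the QC report, the cleaned records, the per-parity summary,
#' stratified Wood-fit tables for all five factors, the factor-effects table
#' (LSM, SE, Duncan letters, partial F) and per-factor curve data and
#' figures, plus a JSON run manifest. Reproducible from `(records|seed,
#' config)`.
#'
#' @param outdir Output directory.
#' @param config A [sim_config()] used when simulating.
#' @param seed Integer seed for the simulation.
#' @param records Optional pre-loaded record data frame; skips simulation.
#' @param min_n Minimum records per stratum, see [run_stratified_fits()].
#' @param alpha Duncan test level, default 0.01.
#' @param render Also write figures, default `TRUE`.
#'
#' @return Invisibly, a list with `records`, `qc_report`, `parity_summary`,
#'   `stratum_tables`, `factor_tables`, `f_tests` and `files`.
#' @export
run_full_analysis <- function(outdir, config = sim_config(), seed = 1L,
                              records = NULL, min_n = 50, alpha = 0.01,
                              render = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  simulated <- is.null(records)
  if (simulated) {
    sim <- simulate_herd(config, seed = seed)
    records <- sim$records
  }
  qc <- qc_filter(records)
  labelled <- assign_factor_bins(qc$records)
  write_qc_report(qc$report, file.path(outdir, "qc_report.csv"),
                  file.path(outdir, "qc_report.json"))
  write_dhi_records(qc$records, file.path(outdir, "records_clean.csv"))

  parity_summary <- run_parity_summary(labelled)
  utils::write.csv(parity_summary, file.path(outdir, "parity_summary.csv"),
                   row.names = FALSE)

  factors <- intersect(.factor_cols, names(labelled))
  strat <- lapply(factors, function(f) {
    run_stratified_fits(labelled, f, min_n = min_n)
  })
  names(strat) <- factors
  stratum_tables <- do.call(rbind, lapply(strat, stratum_table))
  rownames(stratum_tables) <- NULL
  utils::write.csv(stratum_tables, file.path(outdir, "wood_fits.csv"),
                   row.names = FALSE)

  model <- fat_factor_model(labelled, factors)
  factor_tables <- do.call(rbind, lapply(factors, function(f) {
    tab <- fat_factor_table(model, f, alpha = alpha)
    cbind(factor = f, tab,
          f_value = attr(tab, "f_value"), flag = attr(tab, "flag"),
          stringsAsFactors = FALSE)
  }))
  rownames(factor_tables) <- NULL
  utils::write.csv(factor_tables, file.path(outdir, "factor_effects.csv"),
                   row.names = FALSE)
  f_tests <- fat_partial_f(model)

  files <- NULL
  if (render) files <- render_curves(strat, outdir)

  manifest <- list(
    package = "woodlac",
    version = as.character(utils::packageVersion("woodlac")),
    seed = if (simulated) seed else NULL,
    simulated = simulated,
    n_input = qc$report$n_input, n_kept = qc$report$n_kept,
    factors = factors, min_n = min_n, alpha = alpha,
    noise_sd = if (simulated) config$noise_sd else NULL
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)

  invisible(list(records = labelled, qc_report = qc$report,
                 parity_summary = parity_summary,
                 stratum_tables = stratum_tables,
                 factor_tables = factor_tables, f_tests = f_tests,
                 files = files))
}
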
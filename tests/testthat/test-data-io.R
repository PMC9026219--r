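test_that("a well-formed CSV round-trips through write and read", {
  recs <- ten_record_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dhi_records(recs, path)
  back <- read_dhi_records(path)
  expect_equal(nrow(back), 10L)
  expect_equal(nrow(attr(back, "parse_failures")), 0L)
  attr(back, "parse_failures") <- NULL
  expect_equal(back, recs)
})

test_that("unparseable mandatory fields are reported, not silently dropped", {
  recs <- ten_record_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dhi_records(recs, path)
  lines <- readLines(path)
  # corrupt fat_pct in data row 3 and parity in data row 6
  lines[4] <- sub("3.9", "abc", lines[4], fixed = TRUE)
  lines[7] <- sub(",4,", ",??,", lines[7], fixed = TRUE)
  writeLines(lines, path)
  expect_warning(back <- read_dhi_records(path), "parse-failure")
  expect_equal(nrow(back), 8L)
  failures <- attr(back, "parse_failures")
  expect_setequal(failures$row, c(3L, 6L))
  expect_setequal(failures$field, c("fat_pct", "parity"))
})

test_that("a missing mapped column is a configuration error", {
  recs <- ten_record_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dhi_records(recs[, setdiff(names(recs), "fat_pct")], path)
  expect_error(read_dhi_records(path), "fat_pct")
  expect_error(default_column_map(no_such_field = "x"), "unknown")
})

test_that("an empty file yields an empty table with a warning", {
  recs <- ten_record_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dhi_records(recs[0, ], path)
  expect_warning(back <- read_dhi_records(path), "no data rows")
  expect_equal(nrow(back), 0L)
})

test_that("QC screening applies the three rules in fixed order", {
  recs <- ten_record_fixture()
  recs$parity[1] <- 6          # parity rule
  recs$days_in_milk[2] <- 310  # days-in-milk rule
  recs$fat_pct[3] <- 0.9       # fat-range rule
  recs$parity[4] <- 6; recs$fat_pct[4] <- 0.5  # fails both: counted once
  out <- qc_filter(recs)
  expect_equal(out$report$n_kept, 6L)
  expect_equal(out$report$n_rejected_by_rule[["parity"]], 2L)
  expect_equal(out$report$n_rejected_by_rule[["days_in_milk"]], 1L)
  expect_equal(out$report$n_rejected_by_rule[["fat_pct"]], 1L)
  # conservation: every input record is kept or rejected exactly once
  expect_equal(out$report$n_input,
               out$report$n_kept + sum(out$report$n_rejected_by_rule))
})

test_that("QC boundary values are inclusive and the filter is idempotent", {
  recs <- ten_record_fixture()
  recs$parity[1:2] <- c(1, 5)
  recs$days_in_milk[3:4] <- c(1, 305)
  recs$fat_pct[5:6] <- c(1, 7)
  out <- qc_filter(recs)
  expect_equal(out$report$n_kept, 10L)
  again <- qc_filter(out$records)
  expect_equal(again$records, out$records)
  expect_equal(again$report$n_kept, again$report$n_input)
})

test_that("lactation months follow the 30-day rule with an 11-month cap", {
  expect_equal(lactation_month(1), 1L)
  expect_equal(lactation_month(30), 1L)
  expect_equal(lactation_month(31), 2L)
  expect_equal(lactation_month(300), 10L)
  expect_equal(lactation_month(301), 11L)
  expect_equal(lactation_month(305), 11L)
  expect_error(lactation_month(0), "at least 1")
  # non-decreasing in days and bounded by 11
  m <- lactation_month(1:400)
  expect_true(all(diff(m) >= 0))
  expect_true(all(m >= 1 & m <= 11))
  expect_equal(sort(unique(m)), 1:11)
})

test_that("every calendar month maps to exactly one calving season", {
  dates <- as.Date(sprintf("2019-%02d-15", 1:12))
  s <- calving_season(dates)
  expect_false(anyNA(s))
  expect_equal(as.character(s[3]), "spring")   # March
  expect_equal(as.character(s[2]), "winter")   # February
  expect_equal(as.character(s[c(6, 9, 12)]), c("summer", "autumn", "winter"))
  expect_equal(as.integer(table(s)), c(3L, 3L, 3L, 3L))
})

test_that("factor bins use the documented boundary conventions", {
  recs <- ten_record_fixture()
  recs$farm_size_count <- c(999, 1000, 2000, 2001, 5000, 5001, 300, 1500,
                            4000, 9000)
  recs$calving_interval_days <- c(NA, 300, 365, 366, 400, 401, 420, 421,
                                  440, 441)
  recs$milk_305d_kg <- c(3000, 5000, 5001, 13000, 13001, 15000, 2999,
                         15001, 9000, 11000)
  out <- assign_factor_bins(recs)
  expect_equal(as.character(out$farm_size_class[1:6]),
               c("<1000", "1000-2000", "1000-2000", "2001-5000",
                 "2001-5000", ">5000"))
  expect_equal(as.character(out$ci_class[2:3]), rep("300-365", 2))
  expect_equal(as.character(out$ci_class[10]), ">=441")
  expect_equal(as.character(out$milk_class[c(1, 2, 3, 4, 5, 6)]),
               c("3000-5000", "3000-5000", "5001-7000", "11001-13000",
                 ">13000", ">13000"))
  # out-of-range yields are flagged, not dropped
  expect_true(is.na(out$milk_class[7]) && is.na(out$milk_class[8]))
  expect_equal(attr(out, "factor_exclusions")[["milk_class"]], 2L)
  expect_equal(nrow(out), nrow(recs))
  # parity-1 records get the explicit "none" interval level
  expect_equal(as.character(out$ci_class[recs$parity == 1]),
               rep("none", sum(recs$parity == 1)))
})

test_that("bin assignments partition their in-range domains", {
  set.seed(88)
  recs <- ten_record_fixture()[rep(1, 500), ]
  recs$parity <- sample(2:5, 500, replace = TRUE)
  recs$farm_size_count <- sample(1:12000, 500, replace = TRUE)
  recs$calving_interval_days <- sample(300:600, 500, replace = TRUE)
  recs$milk_305d_kg <- runif(500, 3000, 15000)
  recs$days_in_milk <- sample(1:305, 500, replace = TRUE)
  recs$calving_date <- as.Date("2018-01-01") + sample(0:1000, 500, TRUE)
  out <- assign_factor_bins(recs)
  for (col in c("farm_size_class", "parity_class", "season", "ci_class",
                "milk_class", "lactation_month")) {
    expect_false(anyNA(out[[col]]), info = col)
  }
})
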
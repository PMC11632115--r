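test_that("write then read is the identity on all five table kinds", {
  recs <- random_record_sets(n = 100)
  dir <- withr::local_tempdir()
  write_faers_quarter(recs, dir, "2020Q1")
  back <- read_faers_quarter(dir, "2020Q1", quiet = TRUE)
  for (kind in names(recs)) {
    got <- back[[kind]]
    attributes(got)[c("table_kind", "quarter")] <- NULL
    expect_equal(got, as.data.frame(lapply(recs[[kind]], trimws)),
                 ignore_attr = TRUE)
  }
})

test_that("parsing tolerates CRLF line endings and a trailing newline", {
  dir <- withr::local_tempdir()
  demo <- random_record_sets(n = 3)$DEMO
  write_faers_quarter(list(DEMO = demo), dir, "2019Q2")
  path <- file.path(dir, "DEMO19Q2.txt")
  txt <- readLines(path)
  writeLines(paste0(txt, "\r"), path, sep = "\n")
  cat("\n", file = path, append = TRUE)
  got <- read_faers_file(path, "DEMO", "2019Q2")
  expect_equal(nrow(got), 3L)
  expect_equal(got$PRIMARYID, trimws(demo$PRIMARYID))
})

test_that("line count equals row count and fields are split on the dollar sign", {
  dir <- withr::local_tempdir()
  writeLines(c("PRIMARYID$CASEID$PT",
               "1001$12345$Rash",
               "1002$12346$ Pyrexia ",
               "1003$12347$Erythema"),
             file.path(dir, "REAC20Q3.txt"))
  for (k in c("DEMO", "DRUG", "OUTC", "THER")) {
    cols <- pvsignal:::faers_required_columns[[k]]
    writeLines(paste(cols, collapse = "$"),
               file.path(dir, pvsignal:::faers_file_name(k, "2020Q3")))
  }
  got <- read_faers_quarter(dir, "2020Q3", quiet = TRUE)
  expect_equal(nrow(got$REAC), 3L)
  expect_equal(got$REAC$PT[1:2], c("Rash", "Pyrexia"))  # trimmed
  expect_equal(got$REAC$PRIMARYID[1], "1001")
  expect_true("CASEID" %in% names(got$REAC))            # extra column kept
})

test_that("a spurious trailing delimiter is dropped with a warning", {
  dir <- withr::local_tempdir()
  writeLines(c("PRIMARYID$PT", "10$Rash$", "11$Nausea"),
             file.path(dir, "REAC21Q1.txt"))
  # "10$Rash$" splits to 2 fields (strsplit drops the trailing empty), so
  # exercise the explicit extra-field case too
  writeLines(c("PRIMARYID$PT", "10$Rash$$", "11$Nausea"),
             file.path(dir, "REAC21Q2.txt"))
  got1 <- read_faers_file(file.path(dir, "REAC21Q1.txt"), "REAC", "2021Q1")
  expect_equal(got1$PT, c("Rash", "Nausea"))
  expect_warning(
    got2 <- read_faers_file(file.path(dir, "REAC21Q2.txt"), "REAC", "2021Q2"),
    "trailing empty field")
  expect_equal(got2$PT, c("Rash", "Nausea"))
})

test_that("field-count mismatches follow the configured policy", {
  dir <- withr::local_tempdir()
  writeLines(c("PRIMARYID$PT", "10$Rash$extra$fields", "11$Nausea"),
             file.path(dir, "bad.txt"))
  expect_warning(
    got <- read_faers_file(file.path(dir, "bad.txt"), "REAC", "2021Q1", "warn"),
    "field count")
  expect_equal(got$PT, "Nausea")
  expect_error(
    read_faers_file(file.path(dir, "bad.txt"), "REAC", "2021Q1", "abort"),
    "field count")
})

test_that("a missing file errors naming the table kind", {
  dir <- withr::local_tempdir()
  expect_error(read_faers_quarter(dir, "2018Q4", quiet = TRUE), "DEMO")
})

test_that("an empty record set round-trips as a header-only file", {
  dir <- withr::local_tempdir()
  empty <- random_record_sets(n = 1)$REAC[0, ]
  write_faers_quarter(list(REAC = empty), dir, "2022Q4")
  expect_length(readLines(file.path(dir, "REAC22Q4.txt")), 1L)
  got <- read_faers_file(file.path(dir, "REAC22Q4.txt"), "REAC", "2022Q4")
  expect_equal(nrow(got), 0L)
  expect_equal(names(got), c("PRIMARYID", "PT"))
})

test_that("a field containing the delimiter cannot be written", {
  dir <- withr::local_tempdir()
  bad <- data.frame(PRIMARYID = "1", PT = "costs $100")
  expect_error(write_faers_quarter(list(REAC = bad), dir, "2020Q1"),
               "delimiter")
})

test_that("signal tables render estimates at two decimals, zeros trimmed", {
  df <- data.frame(term = "E1", a = 5, ror = 2.5, ror_lo = 0.7712758,
                   ror_hi = 8.103457, prr = 2, prr_lo = 0.8809278,
                   prr_hi = 4.540667, chi2 = 1.474261, ic = 1.1,
                   ic025 = 0.35, ebgm = 2.049, ebgm05 = 1.204,
                   significant_any = TRUE, significant_all = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_signal_table(df, path)
  expect_equal(out[["ROR (95% CI)"]], "2.5 (0.77, 8.1)")
  expect_equal(out[["PRR (95% CI)"]], "2 (0.88, 4.54)")
  expect_equal(out$n, 5)                    # n is the contingency a cell
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back[["Chi-squared"]], 1.47)
})
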
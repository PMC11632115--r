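make_candidates <- function(caseid, caseversion, fda_date,
                            primaryid = paste0(caseid, "-", caseversion)) {
  data.frame(primaryid = primaryid, caseid = caseid,
             caseversion = as.integer(caseversion), fda_date = fda_date,
             stringsAsFactors = FALSE)
}

test_that("the most recent case version survives deduplication", {
  cand <- make_candidates(c("777", "777"), c(1, 2), c("20190101", "20190601"))
  expect_equal(deduplicate_reports(cand)$primaryid, "777-2")

  # same version, different receipt dates: the later receipt date wins
  cand2 <- make_candidates(c("9", "9"), c(1, 1), c("20200301", "20200101"),
                           primaryid = c("9a", "9b"))
  expect_equal(deduplicate_reports(cand2)$primaryid, "9a")

  # single-version input is untouched
  single <- make_candidates("5", 1, "20190101")
  expect_equal(deduplicate_reports(single), single)
})

test_that("deduplication matches a brute-force maximum over the sort key", {
  set.seed(31)
  for (rep in 1:5) {
    cand <- make_candidates(
      caseid = as.character(sample(20, 60, TRUE)),
      caseversion = sample(3, 60, TRUE),
      fda_date = sample(c("20190101", "20200315", "20211230"), 60, TRUE),
      primaryid = as.character(sample(1e6, 60)))
    got <- deduplicate_reports(cand)
    brute <- do.call(rbind, lapply(split(cand, cand$caseid), function(g) {
      key <- paste(g$fda_date, sprintf("%09d", g$caseversion), g$primaryid)
      g[order(key, method = "radix")[nrow(g)], ]
    }))
    expect_setequal(got$primaryid, brute$primaryid)
    # idempotence and order determinism
    expect_equal(deduplicate_reports(got), got)
    shuffled <- cand[sample(nrow(cand)), ]
    expect_equal(deduplicate_reports(shuffled), got)
  }
})

test_that("candidates without a caseid are kept keyed by primaryid", {
  cand <- make_candidates(c("1", "", ""), c(1, 1, 1), "20190101",
                          primaryid = c("a", "b", "c"))
  expect_warning(got <- deduplicate_reports(cand), "without caseid")
  expect_equal(nrow(got), 3L)
})

test_that("drug names standardize by normalized exact lookup", {
  syn <- data.frame(variant = c("POTELIGEO", "mogamulizumab"),
                    ingredient = "mogamulizumab")
  expect_equal(standardize_drug("POTELIGEO", syn), "mogamulizumab")
  expect_equal(standardize_drug("poteligeo ", syn), "mogamulizumab")
  expect_equal(standardize_drug("Mogamulizumab-kpkc", syn), "mogamulizumab")
  expect_true(is.na(standardize_drug("aspirin", syn)))
  # suffix stripping follows the configured token list
  expect_true(is.na(standardize_drug("Mogamulizumab-kpkc", syn,
                                     strip_suffixes = character())))
})

test_that("suspect selection honours the role policy", {
  reports <- data.frame(primaryid = as.character(1:10))
  drug_rows <- data.frame(
    PRIMARYID = c("1", "2", "3", "4", "4", "5", "6"),
    ROLE_COD = c("PS", "PS", "PS", "PS", "C", "SS", "C"),
    DRUGNAME = "x",
    std_name = c("target", "target", "target", "target", "target",
                 "target", "target"),
    stringsAsFactors = FALSE)
  got <- select_suspect_reports(reports, drug_rows, "target", "PS_only")
  expect_setequal(got$primaryid, c("1", "2", "3", "4"))  # 4 counted once
  got2 <- select_suspect_reports(reports, drug_rows, "target", "PS_and_SS")
  expect_setequal(got2$primaryid, c("1", "2", "3", "4", "5"))
})

test_that("the minimum-report-count filter is boundary-exact", {
  pairs <- data.frame(
    primaryid = c("1", "2", "1", "2", "3", "9"),
    drug = c(rep("target", 5), "other"),
    pt = c("rare", "rare", "common", "common", "common", "rare"),
    stringsAsFactors = FALSE)
  out <- apply_min_count_filter(pairs, "target", min_count = 3)
  expect_false("rare" %in% out$pt[out$drug == "target"])   # 2 reports: gone
  expect_equal(sum(out$pt == "common"), 3L)                # 3 reports: kept
  expect_equal(attr(out, "removed"),
               data.frame(pt = "rare", n_reports = 2L), ignore_attr = TRUE)
  # background pairs are never filtered
  expect_true("rare" %in% out$pt[out$drug == "other"])
  # min_count = 1 is the identity; below 1 is an error
  expect_equal(nrow(apply_min_count_filter(pairs, "target", 1)), nrow(pairs))
  expect_error(apply_min_count_filter(pairs, "target", 0), "min_count")
})

test_that("PT to SOC mapping follows the unmapped policy and conserves counts", {
  map <- data.frame(pt = c("Rash", "Pyrexia"),
                    soc = c("Skin and subcutaneous tissue disorders",
                            "General disorders and administration site conditions"))
  pairs <- data.frame(primaryid = as.character(1:5), drug = "d",
                      pt = c("Rash", "Rash", "Pyrexia", "Mystery", "Rash"))
  kept <- map_to_soc(pairs, map, "keep_flagged")
  expect_equal(kept$soc[1], "Skin and subcutaneous tissue disorders")
  expect_equal(attr(kept, "n_unmapped"), 1L)
  expect_true(is.na(kept$soc[4]))
  dropped <- map_to_soc(pairs, map, "drop")
  expect_equal(nrow(dropped), 4L)
  # SOC pair counts sum to the mapped pair total
  expect_equal(sum(table(dropped$soc)), nrow(pairs) - 1L)
  expect_error(map_to_soc(pairs, map[0, ]), "empty")
  expect_error(map_to_soc(pairs, rbind(map, map[1, ])), "more than one")
})
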
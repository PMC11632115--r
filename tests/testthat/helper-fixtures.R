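# Fixture builders shared across test files. Everything is generated in code.

# A pair corpus whose contingency table for drugX/E1 is a=5, b=10, c=20, d=100.
toy_pairs <- function() {
  data.frame(
    primaryid = as.character(seq_len(135)),
    drug = rep(c("drugX", "other"), c(15, 120)),
    pt = c(rep(c("E1", "E2"), c(5, 10)), rep(c("E1", "E2"), c(20, 100))),
    stringsAsFactors = FALSE
  )
}

# Random 2x2 tables with all cells positive.
random_tables <- function(n, seed = 1, max_cell = 500) {
  set.seed(seed)
  data.frame(a = sample(max_cell, n, TRUE), b = sample(max_cell, n, TRUE),
             c = sample(max_cell, n, TRUE), d = sample(max_cell, n, TRUE))
}

# Report cohort with the composition of a published drug-safety first table:
# 1182 reports; years 19/209/193/254/326/181 over 2018-2023; reporters
# 722 pharmacists, 240 physicians, 161 other health-professionals,
# 58 consumers, 1 unknown; countries US 694, JP 211, FR 98, other 179;
# outcomes (one most-severe each on 1012 reports) HO 225, DE 197, LT 35,
# DS 9, OT 546; 170 reports carry no outcome.
cohort_fixture <- function() {
  n <- 1182
  data.frame(
    primaryid = as.character(seq_len(n)),
    caseid = as.character(seq_len(n)),
    receipt_year = rep(2018:2023, c(19, 209, 193, 254, 326, 181)),
    occp_cod = rep(c("PH", "MD", "OT", "CN", ""), c(722, 240, 161, 58, 1)),
    reporter_country = rep(c("US", "JP", "FR", "CA", "GB", "DE"),
                           c(694, 211, 98, 60, 60, 59)),
    outcomes = rep(c("HO", "DE", "LT", "DS", "OT", ""),
                   c(225, 197, 35, 9, 546, 170)),
    stringsAsFactors = FALSE
  )
}

# Random FAERS-shaped record sets for round-trip tests.
random_record_sets <- function(n = 50, seed = 99) {
  set.seed(seed)
  rnd <- function(k) vapply(seq_len(k), function(i)
    paste(sample(c(LETTERS, letters, 0:9, " ", "-"), sample(0:12, 1), TRUE),
          collapse = ""), character(1))
  ids <- as.character(sample(1e6, n))
  list(
    DEMO = data.frame(PRIMARYID = ids, CASEID = as.character(sample(1e6, n)),
                      CASEVERSION = as.character(sample(3, n, TRUE)),
                      FDA_DT = rep("20200101", n), EVENT_DT = rep("202001", n),
                      AGE = rnd(n), AGE_COD = rep("YR", n),
                      SEX = sample(c("M", "F", ""), n, TRUE),
                      OCCP_COD = sample(c("MD", "PH", ""), n, TRUE),
                      REPORTER_COUNTRY = rnd(n), stringsAsFactors = FALSE),
    DRUG = data.frame(PRIMARYID = ids, DRUG_SEQ = as.character(sample(5, n, TRUE)),
                      ROLE_COD = sample(c("PS", "SS", "C", "I"), n, TRUE),
                      DRUGNAME = rnd(n), PROD_AI = rnd(n),
                      stringsAsFactors = FALSE),
    REAC = data.frame(PRIMARYID = ids, PT = rnd(n), stringsAsFactors = FALSE),
    OUTC = data.frame(PRIMARYID = ids,
                      OUTC_COD = sample(c("DE", "HO", "OT"), n, TRUE),
                      stringsAsFactors = FALSE),
    THER = data.frame(PRIMARYID = ids, DSG_DRUG_SEQ = rep("1", n),
                      START_DT = rep("20190501", n), stringsAsFactors = FALSE)
  )
}

# Gamma-mixture CDF, used to measure Kolmogorov distance between priors.
prior_cdf <- function(p, x) {
  p$w * pgamma(x, p$alpha1, rate = p$beta1) +
    (1 - p$w) * pgamma(x, p$alpha2, rate = p$beta2)
}
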
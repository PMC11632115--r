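#' @name synthetic_faers
#' @title Synthetic FAERS corpus with known ground truth
#'
#' @description
#' A seeded generator of FAERS-format quarterly tables that emulates the
#' structural features the pipeline must cope with — multi-table reports
#' keyed by a report identifier, duplicate case versions, a designated
#' suspect drug written under brand/generic/suffixed name variants,
#' Poisson-thinned event draws with planted rate multipliers, demographic,
#' outcome and country fields with missingness, and full or partial therapy
#' and event dates — while emitting the ground truth (planted signals,
#' duplicate map, onset intervals) separately, so every processing stage can
#' be checked against what was generated.
NULL

#' Canonical MedDRA system organ class names
#'
#' The 27 top-level system organ classes, used by the generator's synthetic
#' PT-to-SOC map and available for user maps.
#' @return Character vector of SOC names.
#' @export
meddra_socs <- function() c(
  "Blood and lymphatic system disorders", "Cardiac disorders",
  "Congenital, familial and genetic disorders", "Ear and labyrinth disorders",
  "Endocrine disorders", "Eye disorders", "Gastrointestinal disorders",
  "General disorders and administration site conditions",
  "Hepatobiliary disorders", "Immune system disorders",
  "Infections and infestations",
  "Injury, poisoning and procedural complications", "Investigations",
  "Metabolism and nutrition disorders",
  "Musculoskeletal and connective tissue disorders",
  "Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
  "Nervous system disorders", "Pregnancy, puerperium and perinatal conditions",
  "Product issues", "Psychiatric disorders", "Renal and urinary disorders",
  "Reproductive system and breast disorders",
  "Respiratory, thoracic and mediastinal disorders",
  "Skin and subcutaneous tissue disorders",
  "Social circumstances", "Surgical and medical procedures",
  "Vascular disorders")

#' Configuration for the synthetic FAERS generator
#'
#' Defaults encode the reporting-cohort mix of a mogamulizumab-sized
#' pharmacovigilance cohort: receipt years 2018-2023, reporters dominated by
#' healthcare professionals, countries led by the United States, Japan and
#' France, about 86% of reports outcome-classified, and log-normal onset
#' intervals with median 21 days.
#'
#' @param seed Integer seed; the generated corpus is reproducible bit for
#'   bit given the seed.
#' @param n_reports Number of unique cases.
#' @param n_drugs Number of distinct suspect drugs (including the target).
#' @param n_events Number of distinct preferred terms.
#' @param background_rate Mean number of PTs per report (at least one PT is
#'   always drawn).
#' @param target_drug Canonical name of the study drug.
#' @param target_share Probability that a report's primary-suspect drug is
#'   the target.
#' @param planted_signals Data frame `drug`, `event`, `lambda` of planted
#'   rate multipliers (`lambda > 1` enriches the pair above background).
#' @param prior_for_multipliers Optional [mgps_prior()]; when supplied, every
#'   (drug, event) combination receives a random multiplier drawn from this
#'   gamma mixture (used for prior-recovery validation) before planted
#'   signals are applied.
#' @param duplicate_fraction Fraction of cases re-emitted as a later case
#'   version.
#' @param partial_date_fraction Fraction of therapy start dates degraded to
#'   `YYYYMM`.
#' @param negative_gap_fraction Fraction of reports given an event date
#'   before therapy start (for exclusion testing).
#' @param onset_meanlog,onset_sdlog Log-normal onset-gap parameters (days);
#'   the defaults give median `exp(meanlog) = 21` days.
#' @param power_exponent Power-law exponent of background event popularity
#'   (rank^-exponent), so that rare events are represented.
#' @param year_probs,reporter_probs,country_probs Named probability vectors
#'   for receipt year, reporter occupation code and country.
#' @param outcome_share Probability a report carries any outcome code.
#' @param outcome_probs Named probabilities over outcome codes given one is
#'   present.
#' @return Object of class `faers_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_reports = 2000L,
                       n_drugs = 25L,
                       n_events = 150L,
                       background_rate = 3,
                       target_drug = "mogamulizumab",
                       target_share = 0.05,
                       planted_signals = NULL,
                       prior_for_multipliers = NULL,
                       duplicate_fraction = 0.1,
                       partial_date_fraction = 0.1,
                       negative_gap_fraction = 0.02,
                       onset_meanlog = log(21),
                       onset_sdlog = 2.6,
                       power_exponent = 1.5,
                       year_probs = c("2018" = 19, "2019" = 209, "2020" = 193,
                                      "2021" = 254, "2022" = 326, "2023" = 181) / 1182,
                       reporter_probs = c(PH = 722, MD = 240, OT = 161,
                                          CN = 58, UNK = 1) / 1182,
                       country_probs = c(US = 694, JP = 211, FR = 98, CA = 60,
                                         GB = 60, DE = 59) / 1182,
                       outcome_share = 1012 / 1182,
                       outcome_probs = c(HO = 225, DE = 197, LT = 35, DS = 9,
                                         OT = 546) / 1012) {
  if (is.null(planted_signals))
    planted_signals <- data.frame(drug = character(), event = character(),
                                  lambda = numeric(), stringsAsFactors = FALSE)
  probs <- c(target_share, duplicate_fraction, partial_date_fraction,
             negative_gap_fraction, outcome_share)
  stopifnot(n_reports >= 1, n_drugs >= 2, n_events >= 1,
            background_rate > 0, all(probs >= 0), all(probs <= 1),
            all(planted_signals$lambda > 0), onset_sdlog > 0)
  structure(as.list(environment()), class = "faers_sim_config")
}

sim_date_str <- function(d) format(d, "%Y%m%d")

#' Draw onset gaps from the configured distribution
#'
#' Log-normal therapy-start-to-onset intervals, rounded to whole days.
#'
#' @param n Number of gaps.
#' @param meanlog,sdlog Log-normal parameters; the default median is 21 days.
#' @return Integer vector of non-negative days.
#' @export
simulate_onset_gaps <- function(n, meanlog = log(21), sdlog = 2.6) {
  as.integer(round(stats::rlnorm(n, meanlog, sdlog)))
}

#' Generate a synthetic FAERS corpus
#'
#' Produces the five FAERS tables for one synthetic quarter plus the ground
#' truth. Each unique case gets one DEMO row, a primary-suspect DRUG row
#' (the target drug written under a random name variant) plus occasional
#' concomitant rows, REAC rows whose PTs are drawn with probability
#' proportional to a power-law background popularity times any planted
#' multiplier for (suspect drug, PT), an optional OUTC row, and a THER row
#' with the therapy start date. A `duplicate_fraction` of cases is re-emitted
#' with case version 2 and a later receipt date.
#'
#' @param config A [sim_config()].
#' @return List with `tables` (named list `DEMO`, `DRUG`, `REAC`, `OUTC`,
#'   `THER`), `synonyms` (variant-to-ingredient table covering all drugs),
#'   `pt_soc_map`, and `truth` (list: `report` per-case frame with suspect
#'   drug, onset gap, date-degradation flags; `duplicate_map`;
#'   `planted_signals`; `multipliers` when a prior was supplied).
#' @export
simulate_faers <- function(config = sim_config()) {
  stopifnot(inherits(config, "faers_sim_config"))
  set.seed(config$seed)
  n <- config$n_reports

  drugs <- c(config$target_drug,
             sprintf("backgrounddrug%02d", seq_len(config$n_drugs - 1L)))
  events <- sprintf("Synthetic reaction %03d", seq_len(config$n_events))
  mu <- seq_len(config$n_events)^(-config$power_exponent)
  mu <- mu / sum(mu)

  # per-(drug,event) rate multipliers: prior draws, then planted overrides
  lam <- matrix(1, nrow = config$n_drugs, ncol = config$n_events,
                dimnames = list(drugs, events))
  if (!is.null(config$prior_for_multipliers)) {
    p <- config$prior_for_multipliers
    stopifnot(inherits(p, "mgps_prior"))
    comp <- stats::runif(length(lam)) < p$w
    lam[] <- ifelse(comp,
                    stats::rgamma(length(lam), p$alpha1, rate = p$beta1),
                    stats::rgamma(length(lam), p$alpha2, rate = p$beta2))
  }
  ps <- config$planted_signals
  for (i in seq_len(nrow(ps))) {
    if (!(ps$drug[i] %in% drugs) || !(ps$event[i] %in% events))
      stopf("planted signal (%s, %s) names an unknown drug or event",
            ps$drug[i], ps$event[i])
    lam[ps$drug[i], ps$event[i]] <- ps$lambda[i]
  }

  # target drug name variants exercising standardization
  variants <- unique(c(toupper(config$target_drug), config$target_drug,
                       paste0(config$target_drug, "-kpkc"), "POTELIGEO"))
  synonyms <- rbind(
    data.frame(variant = variants, ingredient = config$target_drug,
               stringsAsFactors = FALSE),
    data.frame(variant = toupper(drugs[-1]), ingredient = drugs[-1],
               stringsAsFactors = FALSE))
  pt_soc_map <- data.frame(
    pt = events,
    soc = rep_len(meddra_socs()[1:23], config$n_events),
    stringsAsFactors = FALSE)

  caseid <- sprintf("CASE%06d", seq_len(n))
  primaryid <- paste0(caseid, "-1")
  year <- sample(names(config$year_probs), n, replace = TRUE,
                 prob = config$year_probs)
  fda_date <- as.Date(paste0(year, "-01-01")) + sample(0:349, n, replace = TRUE)
  suspect <- ifelse(stats::runif(n) < config$target_share,
                    drugs[1], sample(drugs[-1], n, replace = TRUE))
  written_name <- ifelse(suspect == drugs[1],
                         sample(variants, n, replace = TRUE),
                         toupper(suspect))

  gaps <- simulate_onset_gaps(n, config$onset_meanlog, config$onset_sdlog)
  negative <- stats::runif(n) < config$negative_gap_fraction
  gaps[negative] <- -sample(1:30, sum(negative), replace = TRUE)
  start_date <- fda_date - sample(30:400, n, replace = TRUE)
  event_date <- start_date + gaps
  start_str <- sim_date_str(start_date)
  partial <- stats::runif(n) < config$partial_date_fraction
  start_str[partial] <- substr(start_str[partial], 1, 6)

  occp <- sample(names(config$reporter_probs), n, replace = TRUE,
                 prob = config$reporter_probs)
  occp[occp == "UNK"] <- ""
  country <- sample(names(config$country_probs), n, replace = TRUE,
                    prob = config$country_probs)
  sex <- sample(c("M", "F", ""), n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  age <- ifelse(stats::runif(n) < 0.4,
                as.character(sample(18:90, n, replace = TRUE)), "")

  demo <- data.frame(
    PRIMARYID = primaryid, CASEID = caseid, CASEVERSION = "1",
    FDA_DT = sim_date_str(fda_date), EVENT_DT = sim_date_str(event_date),
    AGE = age, AGE_COD = ifelse(nzchar(age), "YR", ""), SEX = sex,
    OCCP_COD = occp, REPORTER_COUNTRY = country, stringsAsFactors = FALSE)

  drug_rows <- data.frame(
    PRIMARYID = primaryid, DRUG_SEQ = "1", ROLE_COD = "PS",
    DRUGNAME = written_name, PROD_AI = toupper(suspect),
    stringsAsFactors = FALSE)
  conc <- stats::runif(n) < 0.5
  if (any(conc)) {
    drug_rows <- rbind(drug_rows, data.frame(
      PRIMARYID = primaryid[conc], DRUG_SEQ = "2", ROLE_COD = "C",
      DRUGNAME = toupper(sample(drugs, sum(conc), replace = TRUE)),
      PROD_AI = "", stringsAsFactors = FALSE))
  }

  k <- 1L + stats::rpois(n, max(config$background_rate - 1, 0))
  k <- pmin(k, config$n_events)
  reac_list <- vector("list", n)
  for (i in seq_len(n)) {
    w <- mu * lam[suspect[i], ]
    reac_list[[i]] <- sample(events, k[i], prob = w)
  }
  reac <- data.frame(PRIMARYID = rep(primaryid, k),
                     PT = unlist(reac_list), stringsAsFactors = FALSE)

  has_outc <- stats::runif(n) < config$outcome_share
  outc <- data.frame(
    PRIMARYID = primaryid[has_outc],
    OUTC_COD = sample(names(config$outcome_probs), sum(has_outc),
                      replace = TRUE, prob = config$outcome_probs),
    stringsAsFactors = FALSE)

  ther <- data.frame(PRIMARYID = primaryid, DSG_DRUG_SEQ = "1",
                     START_DT = start_str, stringsAsFactors = FALSE)

  # duplicate case versions: same case, version 2, later receipt date
  n_dup <- floor(config$duplicate_fraction * n)
  dup_idx <- if (n_dup > 0) sort(sample(n, n_dup)) else integer(0)
  duplicate_map <- data.frame(
    caseid = caseid[dup_idx],
    primaryid_keep = if (n_dup > 0) paste0(caseid[dup_idx], "-2") else character(0),
    stringsAsFactors = FALSE)
  if (n_dup > 0) {
    old <- primaryid[dup_idx]
    new <- duplicate_map$primaryid_keep
    demo2 <- demo[dup_idx, ]
    demo2$PRIMARYID <- new
    demo2$CASEVERSION <- "2"
    demo2$FDA_DT <- sim_date_str(fda_date[dup_idx] +
                                   sample(10:200, n_dup, replace = TRUE))
    demo <- rbind(demo, demo2)
    relabel <- function(df, idcol = "PRIMARYID") {
      sub <- df[df[[idcol]] %in% old, , drop = FALSE]
      sub[[idcol]] <- new[match(sub[[idcol]], old)]
      rbind(df, sub)
    }
    drug_rows <- relabel(drug_rows)
    reac <- relabel(reac)
    outc <- relabel(outc)
    ther <- relabel(ther)
  }

  truth_report <- data.frame(
    caseid = caseid, suspect_drug = suspect, onset_days = gaps,
    start_partial = partial, negative_gap = negative,
    receipt_year = as.integer(year), stringsAsFactors = FALSE)

  list(tables = list(DEMO = demo, DRUG = drug_rows, REAC = reac,
                     OUTC = outc, THER = ther),
       synonyms = synonyms, pt_soc_map = pt_soc_map,
       truth = list(report = truth_report, duplicate_map = duplicate_map,
                    planted_signals = ps,
                    multipliers = if (!is.null(config$prior_for_multipliers)) lam,
                    config = config))
}
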
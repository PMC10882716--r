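#' Default synthetic PT catalog
#'
#' A synthetic MedDRA-like catalog (not the licensed dictionary): the twelve
#' psychiatric preferred terms tracked by the analysis plus 40 null PTs
#' spread over other organ classes, each with a background per-report
#' reporting rate. Rates are chosen so that a scaled-down universe still
#' yields co-report counts in the regime where the positivity rule (a >= 5)
#' operates.
#'
#' @return tibble: `pt`, `soc_name`, `soc_code`, `rate`
#' @export
synth_pt_catalog <- function() {
  psych <- tibble::tibble(
    pt = c("INSOMNIA", "ANXIETY", "NERVOUSNESS", "DEPRESSION", "STRESS",
           "CONFUSIONAL STATE", "EATING DISORDER", "FEAR OF INJECTION",
           "SLEEP DISORDER DUE TO GENERAL MEDICAL CONDITION-INSOMNIA TYPE",
           "BINGE EATING", "FEAR OF EATING", "SELF-INDUCED VOMITING"),
    soc_name = "Psychiatric disorders",
    soc_code = PSYCHIATRIC_SOC,
    rate = c(0.030, 0.028, 0.012, 0.020, 0.010, 0.015, 0.008, 0.006,
             0.005, 0.005, 0.004, 0.004)
  )
  null_socs <- tibble::tribble(
    ~soc_name, ~soc_code,
    "Gastrointestinal disorders", "10017947",
    "Nervous system disorders", "10029205",
    "General disorders", "10018065",
    "Skin disorders", "10040785",
    "Metabolism disorders", "10027433"
  )
  set_null <- function(i) {
    soc <- null_socs[((i - 1L) %% nrow(null_socs)) + 1L, ]
    tibble::tibble(pt = sprintf("NULL PT %02d", i),
                   soc_name = soc$soc_name, soc_code = soc$soc_code,
                   rate = c(0.030, 0.015, 0.008, 0.004)[((i - 1L) %% 4L) + 1L])
  }
  dplyr::bind_rows(psych, dplyr::bind_rows(lapply(1:40, set_null)))
}

#' Default planted drug-event association strengths
#'
#' The eight psychiatric PTs treated as class-level signals, with planted
#' log reporting odds ratios matching the effect sizes the analysis is
#' designed to detect (ROR 1.28-3.77).
#'
#' @return tibble: `pt`, `log_ror`
#' @export
synth_planted_defaults <- function() {
  tibble::tibble(
    pt = c("NERVOUSNESS", "STRESS", "EATING DISORDER", "FEAR OF INJECTION",
           "SLEEP DISORDER DUE TO GENERAL MEDICAL CONDITION-INSOMNIA TYPE",
           "BINGE EATING", "FEAR OF EATING", "SELF-INDUCED VOMITING"),
    log_ror = log(c(1.97, 1.28, 1.57, 1.96, 2.01, 2.70, 3.35, 3.77))
  )
}

# per-regimen log-normal onset parameters: medians follow the reported
# regimen profile (exenatide much later than the rest), heavy right tails
synth_onset_defaults <- function() {
  tibble::tibble(
    group = c("exenatide", "liraglutide", "lixisenatide", "dulaglutide",
              "semaglutide", "tirzepatide", "comparator"),
    meanlog = log(c(45, 16, 20, 7, 12, 10, 20)),
    sdlog = c(2.2, 1.8, 1.5, 1.2, 1.7, 1.6, 1.5)
  )
}

#' Configuration for the synthetic FAERS-like generator
#'
#' Defines the generative study conditions: universe size, the target-drug
#' share of reports, the per-regimen mix (proportional to the reported
#' all-AE case mix of the six regimens), background PT reporting rates,
#' planted class-level log-RORs, duplicate-version rate, missing/partial/
#' invalid date rates, and demographic/outcome distributions echoing the
#' reported case profile.
#'
#' @param seed RNG seed (integer)
#' @param n_cases unique cases in the universe
#' @param duplicate_rate fraction of cases receiving a second report version
#' @param drug_share probability a case is a target-drug (cohort) report
#' @param regimen_mix named per-regimen probabilities (normalized)
#' @param pt_catalog tibble as [synth_pt_catalog()]
#' @param planted tibble (`pt`, `log_ror`) of class-level planted
#'   associations; PTs must exist in the catalog
#' @param missing_event_dt,missing_start_dt probability the date is absent
#' @param partial_month,partial_year probability a present date is truncated
#'   to month / year precision
#' @param invalid_order_rate probability the event date lands before the
#'   therapy start (dirty data)
#' @param same_day_rate probability of a zero-day onset
#' @param sex_probs,occp_probs,country_probs,outcome_probs,indication_probs
#'   named categorical distributions; the sentinel names UNK (unknown code)
#'   and NONE (no OUTC row) cover missingness
#' @param age_known_rate probability the age field is filled
#' @param age_mean,age_sd normal age model (years)
#' @param onset_params tibble (`group`, `meanlog`, `sdlog`) per regimen plus
#'   a "comparator" row
#' @param year_range calendar years over which receipt dates are drawn
#' @return a validated `synth_config` list
#' @export
synth_config <- function(seed = 20040101,
                         n_cases = 50000,
                         duplicate_rate = 0.10,
                         drug_share = 0.02,
                         regimen_mix = c(exenatide = 0.399, liraglutide = 0.160,
                                         lixisenatide = 0.002, dulaglutide = 0.288,
                                         semaglutide = 0.098, tirzepatide = 0.053),
                         pt_catalog = synth_pt_catalog(),
                         planted = synth_planted_defaults(),
                         missing_event_dt = 0.35,
                         missing_start_dt = 0.45,
                         partial_month = 0.10,
                         partial_year = 0.05,
                         invalid_order_rate = 0.02,
                         same_day_rate = 0.02,
                         sex_probs = c(F = 0.659, M = 0.310, UNK = 0.031),
                         age_known_rate = 0.035,
                         age_mean = 57, age_sd = 13,
                         country_probs = c(US = 0.931, GB = 0.012, DE = 0.012,
                                           FR = 0.012, JP = 0.008, CN = 0.008,
                                           BR = 0.008, AU = 0.006, ZA = 0.001,
                                           UNK = 0.002),
                         occp_probs = c(CN = 0.798, MD = 0.084, HP = 0.020,
                                        OT = 0.025, PH = 0.017, LW = 0.002,
                                        UNK = 0.054),
                         outcome_probs = c(HO = 0.107, OT = 0.129, DE = 0.010,
                                           LT = 0.005, DS = 0.013, RI = 0.002,
                                           CA = 0.001, NONE = 0.733),
                         indication_probs = c("TYPE 2 DIABETES MELLITUS" = 0.64,
                                              "WEIGHT CONTROL" = 0.04,
                                              "BLOOD GLUCOSE ABNORMAL" = 0.01,
                                              "HYPERTENSION" = 0.03,
                                              "PRODUCT USED FOR UNKNOWN INDICATION" = 0.28),
                         onset_params = synth_onset_defaults(),
                         year_range = 2010:2023) {
  cfg <- list(seed = seed, n_cases = as.integer(n_cases),
              duplicate_rate = duplicate_rate, drug_share = drug_share,
              regimen_mix = regimen_mix / sum(regimen_mix),
              pt_catalog = tibble::as_tibble(pt_catalog),
              planted = tibble::as_tibble(planted),
              missing_event_dt = missing_event_dt,
              missing_start_dt = missing_start_dt,
              partial_month = partial_month, partial_year = partial_year,
              invalid_order_rate = invalid_order_rate,
              same_day_rate = same_day_rate,
              sex_probs = sex_probs / sum(sex_probs),
              age_known_rate = age_known_rate,
              age_mean = age_mean, age_sd = age_sd,
              country_probs = country_probs / sum(country_probs),
              occp_probs = occp_probs / sum(occp_probs),
              outcome_probs = outcome_probs / sum(outcome_probs),
              indication_probs = indication_probs / sum(indication_probs),
              onset_params = tibble::as_tibble(onset_params),
              year_range = year_range)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  rates <- c(cfg$duplicate_rate, cfg$drug_share, cfg$missing_event_dt,
             cfg$missing_start_dt, cfg$partial_month, cfg$partial_year,
             cfg$invalid_order_rate, cfg$same_day_rate, cfg$age_known_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$n_cases < 1L) stop("n_cases must be positive")
  if (!all(is.finite(cfg$planted$log_ror))) stop("planted log-RORs must be finite")
  if (!all(cfg$planted$pt %in% cfg$pt_catalog$pt)) {
    stop("every planted PT must exist in the PT catalog")
  }
  if (!all(cfg$pt_catalog$rate > 0 & cfg$pt_catalog$rate < 1)) {
    stop("PT background rates must lie in (0, 1)")
  }
  # planted odds must still be a probability
  r <- cfg$pt_catalog$rate[match(cfg$planted$pt, cfg$pt_catalog$pt)]
  p_drug <- stats::plogis(stats::qlogis(r) + cfg$planted$log_ror)
  if (any(p_drug >= 1 - 1e-12)) {
    stop("planted association makes an event (numerically) certain; infeasible")
  }
  need <- setdiff(names(cfg$regimen_mix), cfg$onset_params$group)
  if (length(need) > 0L) stop("onset_params missing groups: ",
                              paste(need, collapse = ", "))
  invisible(cfg)
}

#' SOC map corresponding to the synthetic PT catalog
#'
#' @param catalog a catalog tibble, default [synth_pt_catalog()]
#' @return a [pt_soc_map()] covering the catalog PTs
#' @export
synth_soc_map <- function(catalog = synth_pt_catalog()) {
  pt_soc_map(catalog[, c("pt", "soc_name", "soc_code")])
}

# background (non-cohort) suspect drugs for comparator reports
synth_background_drugs <- c(
  "METFORMIN", "ATORVASTATIN", "LISINOPRIL", "OMEPRAZOLE", "AMLODIPINE",
  "LEVOTHYROXINE", "ADALIMUMAB", "IBUPROFEN", "WARFARIN", "PREDNISONE"
)

#' Plant duplicate report versions
#'
#' Gives a random fraction of cases a second version with a distinct,
#' strictly higher primaryid and a later-or-equal FDA receipt date (equal
#' with probability one half, forcing the primaryid tie-break), and records
#' which version must survive de-duplication.
#'
#' @param cases tibble with columns `caseid`, `primaryid`, `fda_dt`
#'   (day-precision YYYYMMDD)
#' @param rate fraction of cases duplicated, in \[0, 1\]
#' @param seed RNG seed
#' @return list: `versions` (tibble of all versions: `caseid`, `primaryid`,
#'   `fda_dt`, `is_kept`), `truth` (tibble `caseid`, `kept_primaryid`,
#'   `expected_rule`)
#' @export
plant_duplicates <- function(cases, rate, seed = 1) {
  stopifnot(rate >= 0, rate <= 1,
            all(c("caseid", "primaryid", "fda_dt") %in% names(cases)))
  set.seed(seed)
  n <- nrow(cases)
  dup <- stats::runif(n) < rate
  tie <- stats::runif(n) < 0.5
  lag_days <- 1L + stats::rpois(n, 30)

  base <- dplyr::mutate(cases, version = 1L, is_kept = !dup)
  extra <- cases[dup, , drop = FALSE]
  if (nrow(extra) > 0L) {
    d0 <- as.Date(extra$fda_dt, format = "%Y%m%d")
    later <- format(d0 + lag_days[dup], "%Y%m%d")
    extra$fda_dt <- ifelse(tie[dup], extra$fda_dt, later)
    extra$primaryid <- paste0(extra$caseid, "2")
    extra$version <- 2L
    extra$is_kept <- TRUE
  }
  versions <- dplyr::bind_rows(base, extra) |>
    dplyr::arrange(.data$caseid, .data$version)
  truth <- tibble::tibble(
    caseid = cases$caseid,
    kept_primaryid = ifelse(dup, paste0(cases$caseid, "2"), cases$primaryid),
    expected_rule = dplyr::case_when(
      !dup ~ "singleton",
      tie ~ "max_primaryid",
      TRUE ~ "latest_fda_dt"
    )
  )
  list(versions = versions, truth = truth)
}

#' Generate a synthetic FAERS-like quarterly bundle with ground truth
#'
#' Draws a report universe under the configured study conditions, optionally
#' writes it as a dollar-delimited quarterly file bundle, and returns exact
#' ground truth for every downstream stage: the surviving version per case,
#' cohort membership per regimen, the realized 2x2 cells per planted
#' association (over kept reports), and every pre-censoring onset value
#' with its expected inclusion status. Identical configurations produce
#' identical output.
#'
#' Duplicate versions are content-identical apart from primaryid and
#' receipt date, so ground-truth counts over cases equal counts over kept
#' reports.
#'
#' @param config a [synth_config()]
#' @param dir optional directory; when given the six tables are written via
#'   [write_faers_quarter()]
#' @return list: `data` (a `faers_data` of all versions), `truth` (list:
#'   `dedup`, `cohort`, `planted`, `onset`), `dir`
#' @export
generate_faers <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cases
  caseid <- as.character(seq(10000001L, length.out = n))
  primaryid <- paste0(caseid, "1")

  ## drug assignment
  is_drug <- stats::runif(n) < config$drug_share
  regimen <- rep(NA_character_, n)
  regimen[is_drug] <- sample(names(config$regimen_mix), sum(is_drug),
                             replace = TRUE, prob = config$regimen_mix)

  ## PT assignment: independent Bernoulli per catalog PT, with planted
  ## log-odds shifts on drug reports
  cat <- config$pt_catalog
  npts <- nrow(cat)
  theta <- stats::setNames(rep(0, npts), cat$pt)
  theta[config$planted$pt] <- config$planted$log_ror
  p_bg <- cat$rate
  p_drug <- stats::plogis(stats::qlogis(p_bg) + theta[cat$pt])
  u <- matrix(stats::runif(n * npts), nrow = n)
  pmat <- matrix(rep(p_bg, each = n), nrow = n)
  pmat[is_drug, ] <- matrix(rep(p_drug, each = sum(is_drug)), nrow = sum(is_drug))
  has_pt <- u < pmat
  # guarantee at least one reaction per report
  none <- rowSums(has_pt) == 0L
  if (any(none)) {
    fill <- sample.int(npts, sum(none), replace = TRUE, prob = p_bg)
    has_pt[cbind(which(none), fill)] <- TRUE
  }

  ## dates
  fda_d <- as.Date(sprintf("%d-01-01", min(config$year_range))) +
    sample.int(365L * length(config$year_range), n, replace = TRUE) - 1L
  fda_dt <- format(fda_d, "%Y%m%d")

  onset_group <- ifelse(is_drug, regimen, "comparator")
  op <- config$onset_params
  meanlog <- op$meanlog[match(onset_group, op$group)]
  sdlog <- op$sdlog[match(onset_group, op$group)]
  onset_true <- pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
  same_day <- stats::runif(n) < config$same_day_rate
  onset_true[same_day] <- 0L
  invalid <- !same_day & stats::runif(n) < config$invalid_order_rate
  onset_true[invalid] <- -pmax(1L, as.integer(round(stats::rlnorm(
    sum(invalid), log(10), 1))))

  start_d <- fda_d - 365L - onset_true - sample.int(200L, n, replace = TRUE)
  event_d <- start_d + onset_true

  truncate_date <- function(dt, cfg) {
    u <- stats::runif(length(dt))
    out <- format(dt, "%Y%m%d")
    out[u < cfg$partial_year] <- format(dt[u < cfg$partial_year], "%Y")
    sel <- u >= cfg$partial_year & u < cfg$partial_year + cfg$partial_month
    out[sel] <- format(dt[sel], "%Y%m")
    out
  }
  start_missing <- stats::runif(n) < config$missing_start_dt
  event_missing <- stats::runif(n) < config$missing_event_dt
  start_dt <- truncate_date(start_d, config)
  event_dt <- truncate_date(event_d, config)
  start_dt[start_missing] <- ""
  event_dt[event_missing] <- ""

  start_day_prec <- !start_missing & nchar(start_dt) == 8L
  event_day_prec <- !event_missing & nchar(event_dt) == 8L
  onset_status <- dplyr::case_when(
    !start_day_prec | !event_day_prec ~ "excluded_missing",
    onset_true < 0L ~ "excluded_invalid_order",
    onset_true == 0L ~ "excluded_nonpositive",
    TRUE ~ "included"
  )

  ## demographics
  sex <- sample(names(config$sex_probs), n, replace = TRUE,
                prob = config$sex_probs)
  age_known <- stats::runif(n) < config$age_known_rate
  age <- ifelse(age_known,
                as.character(pmin(95L, pmax(18L, as.integer(round(
                  stats::rnorm(n, config$age_mean, config$age_sd)))))), "")
  age_cod <- ifelse(age_known, "YR", "")
  country <- sample(names(config$country_probs), n, replace = TRUE,
                    prob = config$country_probs)
  occp <- sample(names(config$occp_probs), n, replace = TRUE,
                 prob = config$occp_probs)
  outcome <- sample(names(config$outcome_probs), n, replace = TRUE,
                    prob = config$outcome_probs)
  indication <- sample(names(config$indication_probs), n, replace = TRUE,
                       prob = config$indication_probs)

  ## duplicates (content-identical, new primaryid / receipt date)
  cases <- tibble::tibble(caseid = caseid, primaryid = primaryid,
                          fda_dt = fda_dt)
  dup <- plant_duplicates(cases, config$duplicate_rate,
                          seed = config$seed + 1L)

  ## assemble tables (base content keyed by caseid, replicated per version)
  content <- tibble::tibble(
    caseid = caseid, event_dt = event_dt, sex = sex, age = age,
    age_cod = age_cod, reporter_country = country, occp_cod = occp,
    outcome = outcome, indication = indication, start_dt = start_dt,
    is_drug = is_drug, regimen = regimen
  )
  versions <- dup$versions |>
    dplyr::left_join(content, by = "caseid")

  demo <- versions |>
    dplyr::transmute(.data$primaryid, .data$caseid, .data$fda_dt,
                     .data$event_dt, .data$sex, .data$age, .data$age_cod,
                     .data$reporter_country, .data$occp_cod)

  drug_name_for <- function(reg, is_drug) {
    ifelse(is_drug, toupper(reg),
           synth_background_drugs[1L + (seq_along(reg) - 1L) %%
                                    length(synth_background_drugs)])
  }
  # concomitant rows exercise the PS-only rule
  conco <- sample(synth_background_drugs, nrow(versions), replace = TRUE)
  drug <- dplyr::bind_rows(
    versions |>
      dplyr::transmute(.data$primaryid, drug_seq = "1",
                       drugname = drug_name_for(.data$regimen, .data$is_drug),
                       prod_ai = drug_name_for(.data$regimen, .data$is_drug),
                       role_cod = "PS"),
    versions |>
      dplyr::transmute(.data$primaryid, drug_seq = "2", drugname = conco,
                       prod_ai = conco, role_cod = "C")
  ) |> dplyr::arrange(.data$primaryid, .data$drug_seq)

  pt_idx <- which(has_pt, arr.ind = TRUE)
  reac_case <- tibble::tibble(caseid = caseid[pt_idx[, 1L]],
                              pt = cat$pt[pt_idx[, 2L]])
  reac <- versions |>
    dplyr::select("primaryid", "caseid") |>
    dplyr::inner_join(reac_case, by = "caseid",
                      relationship = "many-to-many") |>
    dplyr::select("primaryid", "pt") |>
    dplyr::arrange(.data$primaryid, .data$pt)

  outc <- versions |>
    dplyr::filter(.data$outcome != "NONE") |>
    dplyr::transmute(.data$primaryid, outc_cod = .data$outcome)

  ther <- versions |>
    dplyr::transmute(.data$primaryid, dsg_drug_seq = "1",
                     start_dt = .data$start_dt, end_dt = "")

  indi <- versions |>
    dplyr::transmute(.data$primaryid, indi_drug_seq = "1",
                     indi_pt = .data$indication)

  data <- faers_data(demo = demo, drug = drug, reac = reac, outc = outc,
                     ther = ther, indi = indi)

  ## ground truth over kept versions (content is per case)
  kept_pid <- dup$truth$kept_primaryid
  drug_case_ids <- kept_pid[is_drug]
  planted_truth <- NULL
  if (nrow(config$planted) > 0L) {
    planted_truth <- dplyr::bind_rows(lapply(seq_len(nrow(config$planted)),
                                             function(i) {
      j <- match(config$planted$pt[i], cat$pt)
      ev <- has_pt[, j]
      tibble::tibble(
        pt = config$planted$pt[i],
        log_ror = config$planted$log_ror[i],
        a = sum(ev & is_drug), b = sum(!ev & is_drug),
        c = sum(ev & !is_drug), d = sum(!ev & !is_drug)
      )
    }))
  }
  onset_truth <- tibble::tibble(
    primaryid = kept_pid, caseid = caseid,
    regimen = regimen, is_drug = is_drug,
    onset_days_true = onset_true,
    status = factor(onset_status, levels = onset_statuses)
  )
  truth <- list(
    dedup = dup$truth,
    cohort = tibble::tibble(primaryid = drug_case_ids,
                            regimen = regimen[is_drug]),
    planted = planted_truth,
    onset = onset_truth
  )
  if (!is.null(dir)) write_faers_quarter(data, dir)
  list(data = data, truth = truth, dir = dir)
}
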
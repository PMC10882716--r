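test_that("configuration validation rejects infeasible settings before generation", {
  expect_error(synth_config(duplicate_rate = 1.5), "rates")
  expect_error(synth_config(planted = tibble::tibble(pt = "NOT A PT", log_ror = 1)),
               "catalog")
  expect_error(synth_config(planted = tibble::tibble(pt = "STRESS", log_ror = Inf)),
               "finite")
  expect_error(synth_config(planted = tibble::tibble(pt = "STRESS", log_ror = 40)),
               "infeasible")
})

test_that("zero duplicate rate makes de-duplication the identity", {
  g <- generate_faers(synth_config(seed = 51, n_cases = 800, duplicate_rate = 0))
  dd <- deduplicate(g$data)
  expect_equal(n_reports(dd$data), n_reports(g$data))
  expect_true(all(dd$decisions$rule_used == "singleton"))
})

test_that("forced receipt-date ties make every survivor the max-primaryid version", {
  cases <- tibble::tibble(caseid = as.character(1:200),
                          primaryid = paste0(1:200, "1"),
                          fda_dt = "20200601")
  out <- plant_duplicates(cases, rate = 1, seed = 3)
  # force ties by construction: keep only tie versions
  tied <- out$truth$expected_rule == "max_primaryid"
  expect_true(any(tied))
  v <- faers_data(demo = out$versions[, c("primaryid", "caseid", "fda_dt")])
  dd <- deduplicate(v)
  expect_equal(sort(dd$decisions$kept_primaryid), sort(out$truth$kept_primaryid))
  expect_equal(dd$decisions$rule_used[match(out$truth$caseid[tied],
                                            dd$decisions$caseid)],
               rep("max_primaryid", sum(tied)))
})

test_that("survivor count is conserved under duplication", {
  cases <- tibble::tibble(caseid = as.character(1:1000),
                          primaryid = paste0(1:1000, "1"),
                          fda_dt = format(as.Date("2019-01-01") + 0:999, "%Y%m%d"))
  out <- plant_duplicates(cases, rate = 0.5, seed = 11)
  dd <- deduplicate(faers_data(demo = out$versions[, c("primaryid", "caseid", "fda_dt")]))
  expect_equal(nrow(dd$decisions), 1000L)
})

test_that("dedup recovers the ground-truth survivor on randomized cases", {
  set.seed(606)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    cases <- tibble::tibble(
      caseid = as.character(sample(1e6, n)),
      fda_dt = format(as.Date("2015-01-01") + sample(0:3000, n, TRUE), "%Y%m%d")
    )
    cases$primaryid <- paste0(cases$caseid, "1")
    out <- plant_duplicates(cases, rate = runif(1), seed = i)
    dd <- deduplicate(faers_data(
      demo = out$versions[, c("primaryid", "caseid", "fda_dt")]))
    expect_equal(sort(dd$decisions$kept_primaryid),
                 sort(out$truth$kept_primaryid), info = paste("case", i))
  }
})

test_that("identical configurations produce byte-identical files", {
  cfg <- synth_config(seed = 61, n_cases = 300)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_faers(cfg, dir = d1)
  generate_faers(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), info = f)
  }
})

test_that("ground truth matches the emitted rows by construction", {
  g <- generate_faers(synth_config(seed = 62, n_cases = 1000, drug_share = 0.2))
  dd <- deduplicate(g$data)
  # planted cells recount exactly from the kept reports
  lex <- glp1_lexicon()
  drug_ids <- unique(dd$data$drug$primaryid[
    dd$data$drug$role_cod == "PS" &
      lengths(match_drug(dd$data$drug$drugname, lexicon = lex)) > 0])
  n_univ <- n_reports(dd$data)
  for (i in seq_len(nrow(g$truth$planted))) {
    tr <- g$truth$planted[i, ]
    ev_ids <- unique(dd$data$reac$primaryid[toupper(dd$data$reac$pt) == tr$pt])
    tab <- build_contingency(dd$data$demo$primaryid, drug_ids, ev_ids)
    expect_equal(unlist(tab[, c("a", "b", "c", "d")], use.names = FALSE),
                 unlist(tr[, c("a", "b", "c", "d")], use.names = FALSE),
                 info = tr$pt)
  }
})

test_that("a null planted association is covered by the 95% interval at nominal rate", {
  covered <- logical(120)
  for (i in seq_along(covered)) {
    cfg <- synth_config(seed = 7000 + i, n_cases = 1200, drug_share = 0.2,
                        duplicate_rate = 0,
                        planted = tibble::tibble(pt = "INSOMNIA", log_ror = 0))
    g <- generate_faers(cfg)
    tr <- g$truth$planted
    est <- compute_ror(tr$a, tr$b, tr$c, tr$d, z = qnorm(0.975))
    covered[i] <- isTRUE(est$ci_low <= 1 && est$ci_high >= 1)
  }
  # 95% nominal; binomial 99.7% band at n=120 is ±0.06
  expect_gte(mean(covered), 0.88)
})

test_that("planted onset medians are recovered through the pipeline", {
  cfg <- synth_config(seed = 63, n_cases = 6000, drug_share = 0.35,
                      duplicate_rate = 0, missing_event_dt = 0,
                      missing_start_dt = 0, partial_month = 0, partial_year = 0,
                      invalid_order_rate = 0, same_day_rate = 0,
                      regimen_mix = c(exenatide = 0.5, semaglutide = 0.5),
                      onset_params = tibble::tibble(
                        group = c("exenatide", "semaglutide", "comparator"),
                        meanlog = log(c(45, 31, 20)), sdlog = c(1, 1, 1)))
  g <- generate_faers(cfg)
  dd <- deduplicate(g$data)
  cohort <- build_cohort(dd$data, glp1_lexicon(), synth_soc_map())
  rec <- compute_onset(cohort, dd$data)
  s <- summarize_onset(rec)
  n_sema <- s$n_included[s$stratum == "semaglutide"]
  med <- s$median[s$stratum == "semaglutide"]
  # the order-statistic 99% confidence interval for the population median,
  # built from the included onsets, must contain the planted median 31
  qs <- qbinom(c(0.005, 0.995), n_sema, 0.5)
  v <- sort(rec$onset_days[rec$regimen == "semaglutide" &
                             rec$status == "included"])
  expect_gte(31, v[max(qs[1], 1)])
  expect_lte(31, v[min(qs[2] + 1, n_sema)])
  # the pipeline's reported median sits inside the same interval
  expect_gte(med, v[max(qs[1], 1)])
  expect_lte(med, v[min(qs[2] + 1, n_sema)])
})
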
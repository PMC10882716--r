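onset_fixture <- function(start_dt, event_dt) {
  x <- faers_data(
    demo = data.frame(primaryid = "1", caseid = "1", fda_dt = "20210101",
                      event_dt = event_dt),
    drug = data.frame(primaryid = "1", drug_seq = "1", drugname = "OZEMPIC",
                      role_cod = "PS"),
    reac = data.frame(primaryid = "1", pt = "Insomnia"),
    ther = data.frame(primaryid = "1", dsg_drug_seq = "1",
                      start_dt = start_dt, end_dt = "")
  )
  cohort <- build_cohort(x, glp1_lexicon(), mini_soc_map())
  compute_onset(cohort, x)
}

test_that("onset is day arithmetic with the three exclusion rules as statuses", {
  ok <- onset_fixture("20200101", "20200201")
  expect_equal(ok$onset_days, 31L)
  expect_equal(as.character(ok$status), "included")
  expect_equal(ok$regimen, "semaglutide")

  same <- onset_fixture("20200101", "20200101")
  expect_equal(as.character(same$status), "excluded_nonpositive")
  expect_true(is.na(same$onset_days))

  inverted <- onset_fixture("20200301", "20200101")
  expect_equal(as.character(inverted$status), "excluded_invalid_order")

  missing <- onset_fixture("", "20200101")
  expect_equal(as.character(missing$status), "excluded_missing")
  # partial precision on either side is unusable
  partial <- onset_fixture("202001", "20200115")
  expect_equal(as.character(partial$status), "excluded_missing")
})

test_that("the earliest start date across therapy rows defines initiation", {
  x <- faers_data(
    demo = data.frame(primaryid = "1", caseid = "1", fda_dt = "20210101",
                      event_dt = "20200301"),
    drug = data.frame(primaryid = c("1", "1"), drug_seq = c("1", "2"),
                      drugname = "OZEMPIC", role_cod = "PS"),
    reac = data.frame(primaryid = "1", pt = "Insomnia"),
    ther = data.frame(primaryid = c("1", "1"), dsg_drug_seq = c("1", "2"),
                      start_dt = c("20200201", "20200101"), end_dt = "")
  )
  cohort <- build_cohort(x, glp1_lexicon(), mini_soc_map())
  rec <- compute_onset(cohort, x)
  expect_equal(rec$onset_days, 60L)
})

test_that("every cohort report lands in exactly one status class and bins conserve", {
  g <- generate_faers(synth_config(seed = 31, n_cases = 3000, drug_share = 0.15))
  dd <- deduplicate(g$data)
  cohort <- build_cohort(dd$data, glp1_lexicon(), synth_soc_map())
  rec <- compute_onset(cohort, dd$data)
  expect_equal(nrow(rec), nrow(cohort))
  expect_false(any(is.na(rec$status)))
  # agreement with generator bookkeeping
  tr <- g$truth$onset[g$truth$onset$is_drug, ]
  m <- merge(rec, tr, by = "primaryid")
  expect_equal(as.character(m$status.x), as.character(m$status.y))
  inc <- m$status.x == "included"
  expect_equal(m$onset_days[inc], m$onset_days_true[inc])
  # bin conservation per stratum
  s <- summarize_onset(rec)
  bins <- as.matrix(s[, grep("^bin_", names(s))])
  expect_equal(unname(rowSums(bins)), s$n_included)
})

test_that("hand-countable onset summaries and insufficiency flagging", {
  rec <- tibble::tibble(
    primaryid = as.character(1:4),
    regimen = c("a", "a", "a", "b"),
    onset_days = c(10L, 20L, 40L, 5L),
    status = factor("included", levels = levels(factor(
      c("included", "excluded_nonpositive", "excluded_invalid_order",
        "excluded_missing"))))
  )
  s <- summarize_onset(rec)
  a <- s[s$stratum == "a", ]
  expect_equal(a$median, 20)
  expect_equal(a$`bin_0-30`, 2L)
  expect_equal(a$`bin_30-60`, 1L)
  # regimen with a single included record is insufficient: quantiles withheld
  b <- s[s$stratum == "b", ]
  expect_true(b$insufficient)
  expect_true(is.na(b$median))
  expect_equal(b$`bin_0-30`, 1L)
})

test_that("cumulative onset curves are monotone and end at 1", {
  g <- generate_faers(synth_config(seed = 32, n_cases = 2000, drug_share = 0.2))
  dd <- deduplicate(g$data)
  cohort <- build_cohort(dd$data, glp1_lexicon(), synth_soc_map())
  rec <- compute_onset(cohort, dd$data)
  cur <- onset_curves(rec)
  for (s in unique(cur$stratum)) {
    f <- cur$cum_fraction[cur$stratum == s]
    expect_true(all(diff(f) >= 0))
    expect_equal(f[length(f)], 1)
  }
})

test_that("identical samples compare as no difference", {
  v <- c(3, 8, 15, 40, 90, 200, 7, 12)
  cmp <- compare_onset(list(a = v, b = v), logrank = TRUE)
  expect_gt(cmp$global$p, 0.9)
  expect_gt(cmp$pairwise$p[1], 0.9)
  expect_gt(cmp$logrank$p, 0.9)
})

test_that("a three-fold scale shift at n=500 is detected and matches a permutation oracle", {
  set.seed(55)
  x <- rlnorm(500, log(10), 0.8)
  y <- rlnorm(500, log(30), 0.8)
  cmp <- compare_onset(list(a = x, b = y))
  expect_lt(cmp$pairwise$p[1], 0.001)
  expect_lt(cmp$global$p, 0.001)
  # permutation agreement on a moderate shift, where p is away from 0
  x2 <- rlnorm(60, log(10), 0.8)
  y2 <- rlnorm(60, log(14), 0.8)
  cmp2 <- compare_onset(list(a = x2, b = y2))
  p_perm <- perm_test_ranksum(x2, y2, B = 10000, seed = 7)
  expect_lt(abs(cmp2$pairwise$p[1] - p_perm), 0.02)
})

test_that("three identical-distribution groups keep the nominal type-I error", {
  set.seed(99)
  n_rep <- 1000
  sig <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    g <- lapply(1:3, function(j) rlnorm(25, log(20), 1))
    names(g) <- c("a", "b", "c")
    sig[i] <- compare_onset(g, logrank = FALSE)$global$p < 0.05
  }
  expect_gte(mean(!sig), 0.94)
})

test_that("degenerate groups are skipped with a reason", {
  cmp <- compare_onset(list(a = c(1, 5, 9, 13), b = c(2, 6, 11, 20), c = 4))
  expect_equal(cmp$skipped$group, "c")
  expect_equal(cmp$skipped$reason, "too_few_values")
  all_tied <- compare_onset(list(a = c(5, 5), b = c(5, 5)))
  expect_true(all(all_tied$skipped$reason == "all_ties"))
  expect_true(is.na(all_tied$global$p))
  expect_error(compare_onset(list(a = 1, b = 2)), "two usable groups")
})
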
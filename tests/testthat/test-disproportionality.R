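test_that("an exhaustive four-report universe fills each cell once", {
  x <- tiny_universe()
  ids <- x$demo$primaryid
  drug_ids <- c("11", "21")   # semaglutide PS reports
  event_ids <- c("11", "31")  # insomnia reports
  tab <- build_contingency(ids, drug_ids, event_ids)
  expect_equal(unlist(tab[, c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 1L, 1L, 1L))
  expect_error(build_contingency(character(0), "1", "1"), "empty")
})

test_that("the ROR closed form matches an independent oracle", {
  # frozen from statsmodels Table2x2.oddsratio_confint (Wald, alpha = 0.05)
  est <- compute_ror(10, 10, 10, 10, z = qnorm(0.975))
  expect_equal(est$ror, 1)
  expect_equal(est$ci_low, 0.289503, tolerance = 1e-5)
  expect_equal(est$ci_high, 3.454197, tolerance = 1e-5)

  est2 <- compute_ror(7, 993, 1860, 997140, z = qnorm(0.975))
  expect_equal(est2$ror, 3.779131, tolerance = 1e-6)
  expect_equal(est2$ci_low, 1.794454, tolerance = 1e-5)
  expect_equal(est2$ci_high, 7.958876, tolerance = 1e-5)
  expect_gt(est2$ci_low, 1)

  est3 <- compute_ror(50, 950, 500, 98500, z = qnorm(0.975))
  expect_equal(est3$ror, 10.368421, tolerance = 1e-6)
  expect_equal(est3$ci_low, 7.699197, tolerance = 1e-5)
  expect_equal(est3$ci_high, 13.963034, tolerance = 1e-5)
})

test_that("proportional tables give ROR exactly 1", {
  est <- compute_ror(20, 180, 200, 1800)
  expect_identical(est$ror, 1)
  est2 <- compute_ror(7, 21, 55, 165)
  expect_identical(est2$ror, 1)
})

test_that("zero cells are not computable unless the Haldane correction is on", {
  est <- compute_ror(0, 10, 10, 10)
  expect_false(est$computable)
  expect_true(is.na(est$ror))
  esth <- compute_ror(0, 10, 10, 10, haldane = TRUE)
  expect_true(esth$computable)
  expect_equal(esth$ror, (0.5 * 10.5) / (10.5 * 10.5))
})

test_that("swapping event columns inverts the ROR and mirrors the CI", {
  set.seed(13)
  for (i in 1:25) {
    cells <- 1 + rpois(4, lambda = sample(c(5, 50, 500), 4, TRUE))
    est <- compute_ror(cells[1], cells[2], cells[3], cells[4])
    swp <- compute_ror(cells[2], cells[1], cells[4], cells[3])
    expect_equal(swp$ror, 1 / est$ror)
    expect_equal(swp$ci_low, 1 / est$ci_high)
    expect_equal(swp$ci_high, 1 / est$ci_low)
  }
})

test_that("increasing a strictly increases the ROR", {
  base <- compute_ror(10, 90, 100, 900)$ror
  more <- compute_ror(11, 90, 100, 900)$ror
  expect_gt(more, base)
})

test_that("the 95% interval covers the true odds ratio at nominal rate", {
  set.seed(2024)
  n_sim <- 1500
  true_or <- 2
  n_drug <- 400
  n_comp <- 8000
  p_comp <- 0.1
  p_drug <- plogis(qlogis(p_comp) + log(true_or))
  a <- rbinom(n_sim, n_drug, p_drug)
  c <- rbinom(n_sim, n_comp, p_comp)
  est <- compute_ror(a, n_drug - a, c, n_comp - c, z = qnorm(0.975))
  covered <- est$ci_low <= true_or & est$ci_high >= true_or
  expect_gte(mean(covered, na.rm = TRUE), 0.93)
  expect_lte(mean(covered, na.rm = TRUE), 0.97)
})

test_that("scan applies both positivity criteria with reasons", {
  g <- generate_faers(synth_config(seed = 41, n_cases = 4000, drug_share = 0.12))
  dd <- deduplicate(g$data)
  sg <- scan_signals(dd$data, glp1_lexicon())
  overall <- sg[sg$drug_set == "overall", ]
  # cell conservation against the universe
  expect_true(all(overall$a + overall$b + overall$c + overall$d ==
                    n_reports(dd$data)))
  # report-level counting: a+b equals the drug-set report count for every row
  expect_equal(length(unique(overall$a + overall$b)), 1L)
  # criteria: below-threshold rows are never signals regardless of CI
  low <- overall[overall$a < 5, ]
  expect_true(all(!low$is_signal & low$reason == "below_count_threshold"))
  pos <- overall[overall$is_signal, ]
  expect_true(all(pos$a >= 5 & pos$ci_low > 1))
  # signals sorted first, by descending ROR
  expect_true(all(diff(as.integer(sg$is_signal)) <= 0))
  if (nrow(pos) > 1) expect_true(all(diff(pos$ror) <= 0))
})

test_that("a report with two target PTs contributes once to cell a", {
  x <- faers_data(
    demo = data.frame(primaryid = c("1", "2"), caseid = c("1", "2"),
                      fda_dt = "20200101"),
    drug = data.frame(primaryid = c("1", "2"), drug_seq = "1",
                      drugname = c("OZEMPIC", "ASPIRIN"), role_cod = "PS"),
    reac = data.frame(primaryid = c("1", "1", "2"),
                      pt = c("Binge eating", "Self-induced vomiting", "Nausea"))
  )
  g <- grouped_ror(x, glp1_lexicon(),
                   pt_group = c("BINGE EATING", "SELF-INDUCED VOMITING"),
                   min_count = 1)
  expect_equal(g$a, 1L)
})

test_that("grouped categories behave like unions of report sets", {
  g <- generate_faers(synth_config(seed = 43, n_cases = 3000, drug_share = 0.15))
  dd <- deduplicate(g$data)
  # degenerate one-PT group equals the per-PT scan row
  sg <- scan_signals(dd$data, glp1_lexicon(),
                     drug_sets = list(overall = names(glp1_lexicon())),
                     event_pts = "NERVOUSNESS", min_count = 5)
  gr <- grouped_ror(dd$data, glp1_lexicon(), pt_group = "NERVOUSNESS",
                    min_count = 5)
  expect_equal(gr$a, sg$a[sg$event == "NERVOUSNESS"])
  expect_equal(gr$ror, sg$ror[sg$event == "NERVOUSNESS"])
  # additivity without overlap: grouped a equals the union of report sets
  reac <- dd$data$reac
  ids1 <- unique(reac$primaryid[toupper(reac$pt) == "BINGE EATING"])
  ids2 <- unique(reac$primaryid[toupper(reac$pt) == "FEAR OF EATING"])
  grp <- grouped_ror(dd$data, glp1_lexicon(),
                     pt_group = c("BINGE EATING", "FEAR OF EATING"),
                     min_count = 1)
  drug_ids <- dd$data$drug$primaryid[dd$data$drug$role_cod == "PS" &
    lengths(match_drug(dd$data$drug$drugname, lexicon = glp1_lexicon())) > 0]
  expect_equal(grp$a, length(intersect(union(ids1, ids2), unique(drug_ids))))
})

test_that("planted positives are flagged and null PTs rarely fire", {
  # strong planted signals among nulls: all planted PTs whose realized table
  # qualifies (a >= 5, ci_low > 1 by independent Wald arithmetic) are flagged
  n_rep <- 30
  n_false <- 0L
  n_null_rows <- 0L
  for (s in 1:n_rep) {
    cfg <- synth_config(seed = 1000 + s, n_cases = 2500, drug_share = 0.15,
                        duplicate_rate = 0)
    g <- generate_faers(cfg)
    sg <- scan_signals(g$data, glp1_lexicon(),
                       drug_sets = list(overall = names(glp1_lexicon())))
    tr <- g$truth$planted
    se <- sqrt(1 / tr$a + 1 / tr$b + 1 / tr$c + 1 / tr$d)
    or <- (tr$a * tr$d) / (tr$b * tr$c)
    qualifies <- tr$a >= 5 & is.finite(or) & exp(log(or) - 1.96 * se) > 1
    flagged <- sg$event[sg$is_signal]
    expect_true(all(tr$pt[qualifies] %in% flagged),
                info = paste("seed", 1000 + s))
    null_rows <- sg[!(sg$event %in% tr$pt), ]
    n_null_rows <- n_null_rows + nrow(null_rows)
    n_false <- n_false + sum(null_rows$is_signal)
  }
  # one-sided 95% CI at 2.5% per-PT false-positive rate: nulls fire rarely
  expect_lt(n_false / n_null_rows, 0.06)
})
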
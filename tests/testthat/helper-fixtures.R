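# shared fixtures built in code

# four-report universe covering every 2x2 cell exactly once:
# r1 drug+event, r2 drug only, r3 event only, r4 neither
tiny_universe <- function() {
  faers_data(
    demo = data.frame(
      primaryid = c("11", "21", "31", "41"),
      caseid = c("1", "2", "3", "4"),
      fda_dt = "20200101",
      event_dt = c("20200201", "", "", ""),
      sex = c("F", "M", "F", "M")
    ),
    drug = data.frame(
      primaryid = c("11", "21", "31", "41"),
      drug_seq = "1",
      drugname = c("OZEMPIC", "SEMAGLUTIDE", "METFORMIN", "ASPIRIN"),
      prod_ai = "",
      role_cod = "PS"
    ),
    reac = data.frame(
      primaryid = c("11", "31", "41"),
      pt = c("Insomnia", "Insomnia", "Headache")
    ),
    ther = data.frame(
      primaryid = "11", dsg_drug_seq = "1",
      start_dt = "20200101", end_dt = ""
    )
  )
}

mini_lexicon <- function() {
  drug_lexicon(list(semaglutide = c("semaglutide", "OZEMPIC")))
}

mini_soc_map <- function() {
  pt_soc_map(data.frame(
    pt = c("Insomnia", "Headache"),
    soc_name = c("Psychiatric disorders", "Nervous system disorders"),
    soc_code = c("10037175", "10029205")
  ))
}

# independent two-sample permutation test on the rank-sum statistic
perm_test_ranksum <- function(x, y, B = 10000, seed = 1) {
  set.seed(seed)
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  null <- replicate(B, sum(r[sample.int(length(pooled), n1)]))
  # two-sided p by symmetry around the mean rank sum
  mu <- n1 * (length(pooled) + 1) / 2
  (1 + sum(abs(null - mu) >= abs(obs - mu))) / (B + 1)
}

# expand the reported per-regimen counts into a cohort-shaped tibble
cohort_from_regimen_counts <- function(counts) {
  regimens <- rep(counts$regimen, counts$n_all)
  target <- unlist(mapply(function(np, na) c(rep(TRUE, np), rep(FALSE, na - np)),
                          counts$n_psych, counts$n_all, SIMPLIFY = FALSE))
  cohort <- tibble::tibble(
    primaryid = as.character(seq_along(regimens)),
    regimens = as.list(regimens),
    target_soc = target
  )
  attr(cohort, "regimens") <- counts$regimen
  cohort
}

# expand the reported overall case characteristics into a cohort-shaped tibble
cohort_from_characteristics <- function(chars) {
  expand <- function(block) {
    sub <- chars[chars$block == block, ]
    rep(sub$level, sub$n)
  }
  sex <- expand("sex")
  region <- expand("region")
  outcome <- expand("outcome")
  n <- length(sex)
  stopifnot(length(region) == n, length(outcome) == n)
  tibble::tibble(
    primaryid = as.character(seq_len(n)),
    caseid = as.character(seq_len(n)),
    fda_dt = "20200101",
    event_dt = NA_character_,
    sex = ifelse(sex == "UNK", NA_character_, sex),
    age = NA_character_,
    age_cod = NA_character_,
    reporter_country = ifelse(region == "UNK", NA_character_, region),
    occp_cod = NA_character_,
    regimens = as.list(rep("glp1", n)),
    matched_seqs = as.list(rep("1", n)),
    pts = as.list(rep("X", n)),
    target_soc = TRUE,
    n_unmapped_pts = 0L,
    indication = "Unknown",
    outcome = ifelse(outcome == "NONE", "Unknown", outcome)
  )
}

read_reported <- function(file) {
  readr::read_csv(system.file("extdata", file, package = "rorscan"),
                  show_col_types = FALSE, progress = FALSE)
}

# onset records realizing given bin counts (values placed inside each bin)
onset_records_from_bins <- function(bins) {
  vals <- unlist(mapply(function(lo, hi, n) {
    rep(if (is.infinite(hi)) lo + 10 else floor((lo + hi + 1) / 2), n)
  }, bins$lo, bins$hi, bins$n, SIMPLIFY = FALSE))
  rec <- tibble::tibble(
    primaryid = as.character(seq_along(vals)),
    regimen = "all",
    onset_days = as.integer(vals),
    status = factor("included", levels = c("included", "excluded_nonpositive",
                                           "excluded_invalid_order",
                                           "excluded_missing"))
  )
  class(rec) <- c("onset_records", class(rec))
  rec
}
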
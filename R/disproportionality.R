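#' Build a 2x2 contingency table from report-id sets
#'
#' Report-level counting over a de-duplicated report universe: a report
#' counts once in exactly one cell. Drug membership means the report is in
#' `drug_ids`; event membership means it is in `event_ids`; the comparator
#' is everything else in the universe.
#'
#' \tabular{lcc}{
#'   \tab event \tab no event \cr
#'   drug \tab a \tab b \cr
#'   comparator \tab c \tab d \cr
#' }
#'
#' @param universe_ids all report identifiers in the analysis universe
#' @param drug_ids report identifiers with the target drug (primary suspect)
#' @param event_ids report identifiers listing at least one target-event PT
#' @return a `contingency_table`: one-row tibble with columns a, b, c, d
#' @export
build_contingency <- function(universe_ids, drug_ids, event_ids) {
  universe_ids <- unique(universe_ids)
  if (length(universe_ids) == 0L) stop("empty report universe")
  drug_ids <- intersect(unique(drug_ids), universe_ids)
  event_ids <- intersect(unique(event_ids), universe_ids)
  a <- length(intersect(drug_ids, event_ids))
  b <- length(drug_ids) - a
  c <- length(event_ids) - a
  d <- length(universe_ids) - a - b - c
  out <- tibble::tibble(a = a, b = b, c = c, d = d)
  class(out) <- c("contingency_table", class(out))
  out
}

#' Reporting odds ratio with Wald confidence interval
#'
#' ROR = (a d) / (b c); the two-sided interval is
#' exp(ln ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d)). Any zero cell makes the
#' estimate not computable (no continuity correction by default; the
#' Haldane-Anscombe +0.5 correction is available behind a flag).
#'
#' @param a,b,c,d cell counts, or a one-row data frame / `contingency_table`
#'   in `a` with b, c, d missing
#' @param z normal quantile for the interval (default 1.96, a 95% CI)
#' @param haldane apply the +0.5 continuity correction to every cell when
#'   any cell is zero (off by default)
#' @return tibble with `a`..`d`, `ror`, `ci_low`, `ci_high`, `computable`
#' @export
#' @examples
#' compute_ror(10, 10, 10, 10)
compute_ror <- function(a, b = NULL, c = NULL, d = NULL, z = 1.96,
                        haldane = FALSE) {
  if (is.data.frame(a)) {
    tab <- a
    a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  }
  stopifnot(length(a) == length(b), length(b) == length(c),
            length(c) == length(d), all(c(a, b, c, d) >= 0, na.rm = TRUE))
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  zero <- (a == 0 | b == 0 | c == 0 | d == 0)
  aa <- a; bb <- b; cc <- c; dd <- d
  if (haldane) {
    aa[zero] <- a[zero] + 0.5; bb[zero] <- b[zero] + 0.5
    cc[zero] <- c[zero] + 0.5; dd[zero] <- d[zero] + 0.5
    zero <- rep(FALSE, length(a))
  }
  ror <- ci_low <- ci_high <- rep(NA_real_, length(a))
  ok <- !zero
  ror[ok] <- (aa[ok] * dd[ok]) / (bb[ok] * cc[ok])
  se <- sqrt(1 / aa[ok] + 1 / bb[ok] + 1 / cc[ok] + 1 / dd[ok])
  ci_low[ok] <- exp(log(ror[ok]) - z * se)
  ci_high[ok] <- exp(log(ror[ok]) + z * se)
  tibble::tibble(a = a, b = b, c = c, d = d, ror = ror,
                 ci_low = ci_low, ci_high = ci_high, computable = ok)
}

# report-id sets per drug set, from a de-duplicated faers_data
drug_report_sets <- function(x, lexicon, drug_sets,
                             match_fields = c("drugname", "prod_ai")) {
  drug <- x$drug
  ps <- drug[!is.na(drug$role_cod) & norm_ws_upper(drug$role_cod) == "PS", ,
             drop = FALSE]
  m <- match_drug(ps$drugname, ps$prod_ai, lexicon, fields = match_fields)
  long <- tibble::tibble(
    primaryid = rep(ps$primaryid, lengths(m)),
    regimen = unlist(m)
  )
  lapply(drug_sets, function(regs) unique(long$primaryid[long$regimen %in% regs]))
}

#' Scan a report universe for drug-event signals
#'
#' For each (drug set, event PT) pair with at least one co-report, builds
#' the 2x2 table against the full de-duplicated universe, computes the ROR
#' with its 95% CI, and applies the positivity criteria: a signal requires
#' at least `min_count` co-reports (a >= 5 by default) and a lower CI bound
#' above 1. Counting is per report: a report listing a PT twice, or two PTs
#' of a grouped event, still contributes one to cell a.
#'
#' The comparator defaults to all other reports in the universe ("full"
#' background), so when scanning one regimen the remaining regimens sit in
#' the comparator; `comparator = "class_exclusive"` instead drops every
#' lexicon-matched report from the comparator as a sensitivity analysis.
#'
#' @param x a de-duplicated `faers_data` (the full report universe)
#' @param lexicon a [drug_lexicon()]
#' @param drug_sets named list of regimen-name vectors; default: "overall"
#'   (all regimens) plus one set per regimen
#' @param event_pts PTs to scan; default all PTs reported for the drug sets
#' @param min_count minimum a for positivity (default 5)
#' @param z normal quantile for the CI (default 1.96)
#' @param comparator "full" or "class_exclusive"
#' @param haldane passed to [compute_ror()]
#' @param match_fields fields used by [match_drug()]
#' @return a `signal_table` tibble: `drug_set`, `event`, `a`..`d`, `ror`,
#'   `ci_low`, `ci_high`, `is_signal`, `reason` (positive /
#'   below_count_threshold / ci_spans_one / not_computable), signals first,
#'   sorted by descending ROR
#' @export
scan_signals <- function(x, lexicon, drug_sets = NULL, event_pts = NULL,
                         min_count = 5, z = 1.96,
                         comparator = c("full", "class_exclusive"),
                         haldane = FALSE,
                         match_fields = c("drugname", "prod_ai")) {
  stopifnot(inherits(x, "faers_data"), inherits(lexicon, "drug_lexicon"))
  comparator <- match.arg(comparator)
  if (n_reports(x) == 0L) stop("empty report universe")
  if (is.null(drug_sets)) {
    drug_sets <- c(list(overall = names(lexicon)),
                   stats::setNames(as.list(names(lexicon)), names(lexicon)))
  }
  sets <- drug_report_sets(x, lexicon, drug_sets, match_fields)
  class_ids <- unique(unlist(drug_report_sets(
    x, lexicon, list(all = names(lexicon)), match_fields)))

  reac <- x$reac
  reac$ptkey <- norm_ws_upper(reac$pt)
  rows <- list()
  for (ds in names(drug_sets)) {
    d_ids <- sets[[ds]]
    universe <- x$demo$primaryid
    if (comparator == "class_exclusive") {
      universe <- setdiff(universe, setdiff(class_ids, d_ids))
    }
    n_universe <- length(unique(universe))
    n_drug <- length(d_ids)
    sub <- reac[reac$primaryid %in% universe, , drop = FALSE]
    pts <- event_pts
    if (is.null(pts)) {
      pts <- sort(unique(sub$ptkey[sub$primaryid %in% d_ids]))
    } else {
      pts <- norm_ws_upper(pts)
    }
    ev <- sub[sub$ptkey %in% pts, c("primaryid", "ptkey")]
    ev <- dplyr::distinct(ev)
    ev$in_drug <- ev$primaryid %in% d_ids
    counts <- ev |>
      dplyr::group_by(.data$ptkey) |>
      dplyr::summarise(n_event = dplyr::n(), a = sum(.data$in_drug),
                       .groups = "drop")
    counts <- counts[counts$a >= 1L, , drop = FALSE]
    if (nrow(counts) == 0L) next
    tab <- tibble::tibble(
      drug_set = ds, event = counts$ptkey, a = counts$a,
      b = n_drug - counts$a, c = counts$n_event - counts$a,
      d = n_universe - n_drug - (counts$n_event - counts$a)
    )
    rows[[ds]] <- tab
  }
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0L) {
    out <- tibble::tibble(drug_set = character(), event = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), ror = numeric(), ci_low = numeric(),
                          ci_high = numeric(), is_signal = logical(),
                          reason = character())
    class(out) <- c("signal_table", class(out))
    return(out)
  }
  est <- compute_ror(tab$a, tab$b, tab$c, tab$d, z = z, haldane = haldane)
  out <- dplyr::bind_cols(tab, est[, c("ror", "ci_low", "ci_high", "computable")])
  out$reason <- dplyr::case_when(
    out$a < min_count ~ "below_count_threshold",
    !out$computable ~ "not_computable",
    out$ci_low > 1 ~ "positive",
    TRUE ~ "ci_spans_one"
  )
  out$is_signal <- out$reason == "positive"
  out$computable <- NULL
  out <- out[order(-out$is_signal, -ifelse(is.na(out$ror), -Inf, out$ror)), ,
             drop = FALSE]
  class(out) <- c("signal_table", class(out))
  out
}

#' ROR for a grouped event category
#'
#' Treats a set of PTs as one event category: a report is an event case when
#' it lists any PT of the group (report-level de-duplication, so co-reported
#' PTs count once). Otherwise identical to [scan_signals()] counting.
#'
#' @param x a de-duplicated `faers_data`
#' @param lexicon a [drug_lexicon()]
#' @param pt_group non-empty character vector of PTs forming the category
#' @param drug_set regimen names (default all regimens in the lexicon)
#' @param label event label for the result row
#' @inheritParams scan_signals
#' @return a one-row `signal_table`
#' @export
grouped_ror <- function(x, lexicon, pt_group, drug_set = names(lexicon),
                        label = "grouped", min_count = 5, z = 1.96,
                        comparator = c("full", "class_exclusive"),
                        haldane = FALSE,
                        match_fields = c("drugname", "prod_ai")) {
  stopifnot(length(pt_group) > 0L)
  comparator <- match.arg(comparator)
  sets <- drug_report_sets(x, lexicon, list(ds = drug_set), match_fields)
  d_ids <- sets$ds
  universe <- x$demo$primaryid
  if (comparator == "class_exclusive") {
    class_ids <- unique(unlist(drug_report_sets(
      x, lexicon, list(all = names(lexicon)), match_fields)))
    universe <- setdiff(universe, setdiff(class_ids, d_ids))
  }
  ptkeys <- norm_ws_upper(pt_group)
  reac <- x$reac
  ev_ids <- unique(reac$primaryid[norm_ws_upper(reac$pt) %in% ptkeys])
  tab <- build_contingency(universe, d_ids, ev_ids)
  est <- compute_ror(tab, z = z, haldane = haldane)
  out <- dplyr::bind_cols(
    tibble::tibble(drug_set = paste(drug_set, collapse = "+"), event = label),
    est[, c("a", "b", "c", "d", "ror", "ci_low", "ci_high", "computable")]
  )
  out$reason <- dplyr::case_when(
    out$a < min_count ~ "below_count_threshold",
    !out$computable ~ "not_computable",
    out$ci_low > 1 ~ "positive",
    TRUE ~ "ci_spans_one"
  )
  out$is_signal <- out$reason == "positive"
  out$computable <- NULL
  class(out) <- c("signal_table", class(out))
  out
}

#' Write a signal table as delimited text
#'
#' @param x a `signal_table`
#' @param path output file
#' @param delim delimiter, default comma
#' @return invisibly, `path`
#' @export
write_signal_table <- function(x, path, delim = ",") {
  readr::write_delim(x, path, delim = delim, na = "")
  invisible(path)
}
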
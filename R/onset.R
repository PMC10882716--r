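#' Default time-to-onset bin edges (days)
#'
#' Bins are right-closed on integer days: (0,30], (30,60], ..., (180,360],
#' (360, Inf). With the positivity rule (onset strictly greater than 0 days)
#' the first bin is exactly days 1-30, so "within the initial 30 days" means
#' the first bin's share.
#' @export
onset_bin_edges <- c(0, 30, 60, 90, 120, 150, 180, 360, Inf)

onset_bin_labels <- function(edges = onset_bin_edges) {
  k <- length(edges) - 1L
  lab <- paste0(edges[-length(edges)], "-", edges[-1])
  lab[k] <- paste0(edges[k], "+")
  lab
}

onset_statuses <- c("included", "excluded_nonpositive",
                    "excluded_invalid_order", "excluded_missing")

#' Compute time to onset per cohort report
#'
#' Time to onset is the interval in days between initiation of the matched
#' suspect drug (the earliest day-precision start date among THER rows
#' linked to a lexicon-matched primary-suspect drug) and the event date
#' (DEMO event_dt). Only day-precision dates on both sides are usable.
#' Each report lands in exactly one status class:
#' \describe{
#'   \item{included}{onset strictly greater than 0 days}
#'   \item{excluded_nonpositive}{event on the start day (onset 0)}
#'   \item{excluded_invalid_order}{dosing after the event}
#'   \item{excluded_missing}{either date missing or not day-precise}
#' }
#' Exclusions are statuses, never exceptions. For reports naming several
#' regimens the regimen of the earliest-started matched drug is recorded.
#'
#' @param cohort a `faers_cohort` from [build_cohort()]
#' @param x the `faers_data` the cohort was built from (for THER rows)
#' @return an `onset_records` tibble: `primaryid`, `regimen`, `onset_days`
#'   (integer, NA unless included), `status`
#' @export
compute_onset <- function(cohort, x) {
  stopifnot(inherits(x, "faers_data"))
  seq_map <- tibble::tibble(
    primaryid = rep(cohort$primaryid, lengths(cohort$matched_seqs)),
    drug_seq = unlist(cohort$matched_seqs),
    regimen = rep(vapply(cohort$regimens, function(r) r[1] %||% NA_character_,
                         character(1)),
                  lengths(cohort$matched_seqs))
  )
  # regimen per matched drug_seq (a report can match several regimens)
  drug <- x$drug[x$drug$primaryid %in% cohort$primaryid, , drop = FALSE]
  seq_reg <- drug |>
    dplyr::inner_join(seq_map[, c("primaryid", "drug_seq")],
                      by = c("primaryid", "drug_seq"))

  ther <- x$ther |>
    dplyr::inner_join(seq_map[, c("primaryid", "drug_seq")],
                      by = c("primaryid", "dsg_drug_seq" = "drug_seq"))
  pstart <- parse_faers_date(ther$start_dt)
  ther$start_date <- pstart$date
  ther$start_day_prec <- pstart$precision == "day"
  usable <- ther[ther$start_day_prec, , drop = FALSE]
  if (nrow(usable) == 0L) {
    starts <- tibble::tibble(primaryid = character(0),
                             start_date = as.Date(character(0)),
                             start_seq = character(0))
  } else {
    starts <- usable |>
      dplyr::group_by(.data$primaryid) |>
      dplyr::summarise(start_date = min(.data$start_date),
                       start_seq = .data$dsg_drug_seq[which.min(.data$start_date)],
                       .groups = "drop")
  }

  pev <- parse_faers_date(cohort$event_dt)
  rec <- tibble::tibble(
    primaryid = cohort$primaryid,
    event_date = pev$date,
    event_day_prec = pev$precision == "day"
  ) |>
    dplyr::left_join(starts, by = "primaryid")

  onset <- as.integer(rec$event_date - rec$start_date)
  status <- dplyr::case_when(
    is.na(rec$start_date) | !rec$event_day_prec | is.na(rec$event_date) ~
      "excluded_missing",
    onset < 0L ~ "excluded_invalid_order",
    onset == 0L ~ "excluded_nonpositive",
    TRUE ~ "included"
  )

  # regimen of the earliest-started matched drug, else first matched regimen
  reg_by_seq <- seq_map |>
    dplyr::distinct(.data$primaryid, .data$drug_seq, .keep_all = TRUE)
  start_reg <- rec |>
    dplyr::left_join(reg_by_seq, by = c("primaryid", "start_seq" = "drug_seq"))
  fallback <- stats::setNames(
    vapply(cohort$regimens, function(r) r[1] %||% NA_character_, character(1)),
    cohort$primaryid
  )
  regimen <- dplyr::coalesce(start_reg$regimen, unname(fallback[rec$primaryid]))

  out <- tibble::tibble(
    primaryid = rec$primaryid,
    regimen = regimen,
    onset_days = ifelse(status == "included", onset, NA_integer_),
    status = factor(status, levels = onset_statuses)
  )
  class(out) <- c("onset_records", class(out))
  out
}

#' Summarize time-to-onset distributions per regimen
#'
#' Medians and IQR use the package quantile convention; bin counts use the
#' right-closed integer-day bins of [onset_bin_edges]. Regimens with fewer
#' than `min_n` included records are marked insufficient (their median/IQR
#' are withheld, mirroring how sparse regimens are reported), but their bin
#' counts are still tabulated. An "overall" row pools all regimens.
#'
#' @param records an `onset_records` tibble from [compute_onset()]
#' @param edges bin edges in days, right-closed
#' @param min_n minimum included records for quantile reporting (default 2)
#' @param quantile_type quantile convention
#' @return an `onset_summary` tibble: one row per stratum with `n_included`,
#'   `median`, `q1`, `q3`, `insufficient`, and one `bin_*` count column per
#'   bin; bin counts sum to `n_included` in every row
#' @export
summarize_onset <- function(records, edges = onset_bin_edges, min_n = 2,
                            quantile_type = 7) {
  inc <- records[records$status == "included", , drop = FALSE]
  labels <- onset_bin_labels(edges)
  strata <- c("overall", sort(unique(inc$regimen[!is.na(inc$regimen)])))
  rows <- lapply(strata, function(s) {
    v <- if (s == "overall") inc$onset_days else
      inc$onset_days[!is.na(inc$regimen) & inc$regimen == s]
    q <- quantile_summary(v, type = quantile_type)
    bins <- table(cut(v, breaks = edges, labels = labels, right = TRUE))
    insufficient <- q$n < min_n
    row <- tibble::tibble(
      stratum = s, n_included = q$n,
      median = ifelse(insufficient, NA_real_, q$median),
      q1 = ifelse(insufficient, NA_real_, q$q1),
      q3 = ifelse(insufficient, NA_real_, q$q3),
      insufficient = insufficient
    )
    for (i in seq_along(labels)) row[[paste0("bin_", labels[i])]] <- as.integer(bins[i])
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("onset_summary", class(out))
  out
}

#' Cumulative onset distribution curves
#'
#' Plot-ready empirical cumulative distributions of time to onset, per
#' regimen and overall: sorted onset values with cumulative fractions ending
#' at 1.
#'
#' @param records an `onset_records` tibble
#' @return tibble: `stratum`, `days`, `cum_fraction`
#' @export
onset_curves <- function(records) {
  inc <- records[records$status == "included" & !is.na(records$onset_days), ,
                 drop = FALSE]
  one <- function(v, s) {
    v <- sort(v)
    tibble::tibble(stratum = s, days = v,
                   cum_fraction = seq_along(v) / length(v))
  }
  out <- list(one(inc$onset_days, "overall"))
  for (s in sort(unique(inc$regimen[!is.na(inc$regimen)]))) {
    out[[length(out) + 1L]] <- one(inc$onset_days[inc$regimen == s &
                                                    !is.na(inc$regimen)], s)
  }
  dplyr::bind_rows(out)
}

#' Plot cumulative onset curves
#'
#' @param records an `onset_records` tibble
#' @return a ggplot object (requires the ggplot2 package)
#' @export
plot_onset_curves <- function(records) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_onset_curves requires ggplot2")
  }
  cur <- onset_curves(records)
  cur <- cur[cur$stratum != "overall", , drop = FALSE]
  ggplot2::ggplot(cur, ggplot2::aes(x = .data$days, y = .data$cum_fraction,
                                    colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Time to onset (days)", y = "Cumulative fraction",
                  colour = "Regimen") +
    ggplot2::theme_minimal()
}

#' Compare time-to-onset distributions between regimens
#'
#' Global Kruskal-Wallis test across regimens plus pairwise two-sided
#' Mann-Whitney (Wilcoxon rank-sum) tests with Holm adjustment, and an
#' optional log-rank test over the cumulative curves (all onsets treated as
#' events). Groups with fewer than `min_n` included values, or with all
#' values tied, are skipped with a reason rather than raising.
#'
#' @param records an `onset_records` tibble, or a named list of numeric
#'   onset vectors
#' @param adjust multiplicity adjustment for the pairwise tests
#'   (see [stats::p.adjust()]); default "holm"
#' @param min_n minimum group size (default 2)
#' @param logrank also run the log-rank comparison (default TRUE)
#' @return an `onset_comparison` list: `global` (Kruskal-Wallis), `pairwise`
#'   tibble (`group1`, `group2`, `statistic`, `p`, `p_adj`), `logrank`, and
#'   `skipped` tibble with reasons
#' @export
compare_onset <- function(records, adjust = "holm", min_n = 2, logrank = TRUE) {
  if (inherits(records, "onset_records") || is.data.frame(records)) {
    inc <- records[records$status == "included" & !is.na(records$regimen), ,
                   drop = FALSE]
    groups <- split(as.numeric(inc$onset_days), inc$regimen)
  } else {
    groups <- lapply(records, as.numeric)
  }
  skipped <- tibble::tibble(group = character(), reason = character())
  usable <- list()
  for (g in names(groups)) {
    v <- groups[[g]][!is.na(groups[[g]])]
    if (length(v) < min_n) {
      skipped <- dplyr::bind_rows(skipped,
                                  tibble::tibble(group = g, reason = "too_few_values"))
    } else {
      usable[[g]] <- v
    }
  }
  if (length(usable) < 2L) {
    stop("compare_onset needs at least two usable groups")
  }
  values <- unlist(usable, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    # every observation tied across all groups: the rank tests are undefined
    skipped <- dplyr::bind_rows(skipped, tibble::tibble(
      group = names(usable), reason = "all_ties"))
    return(structure(list(
      global = tibble::tibble(statistic = NA_real_, df = NA_integer_, p = NA_real_),
      pairwise = tibble::tibble(group1 = character(), group2 = character(),
                                statistic = numeric(), p = numeric(),
                                p_adj = numeric()),
      logrank = NULL, skipped = skipped
    ), class = "onset_comparison"))
  }
  grp <- factor(rep(names(usable), lengths(usable)))
  kw <- stats::kruskal.test(values, grp)
  global <- tibble::tibble(statistic = unname(kw$statistic),
                           df = unname(kw$parameter), p = kw$p.value)

  combs <- utils::combn(names(usable), 2L, simplify = FALSE)
  pw <- lapply(combs, function(pr) {
    wt <- suppressWarnings(stats::wilcox.test(usable[[pr[1]]], usable[[pr[2]]],
                                              alternative = "two.sided",
                                              exact = FALSE, correct = TRUE))
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   statistic = unname(wt$statistic), p = wt$p.value)
  })
  pairwise <- dplyr::bind_rows(pw)
  pairwise$p_adj <- stats::p.adjust(pairwise$p, method = adjust)

  lr <- NULL
  if (logrank) {
    sd <- survival::survdiff(survival::Surv(values, rep(1L, length(values))) ~ grp)
    lr <- tibble::tibble(statistic = unname(sd$chisq),
                         df = length(sd$n) - 1L,
                         p = stats::pchisq(sd$chisq, length(sd$n) - 1L,
                                           lower.tail = FALSE))
  }
  structure(list(global = global, pairwise = pairwise, logrank = lr,
                 skipped = skipped),
            class = "onset_comparison")
}

#' @export
print.onset_comparison <- function(x, ...) {
  cat("<onset_comparison>\n")
  cat(sprintf("  Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.4g\n",
              x$global$statistic, x$global$df, x$global$p))
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank chi-squared = %.3f, df = %d, p = %.4g\n",
                x$logrank$statistic, x$logrank$df, x$logrank$p))
  }
  cat(sprintf("  %d pairwise Mann-Whitney test(s), %s-adjusted\n",
              nrow(x$pairwise), "holm"))
  if (nrow(x$skipped) > 0L) {
    cat(sprintf("  skipped: %s\n",
                paste(x$skipped$group, x$skipped$reason, sep = " (",
                      collapse = "), ")))
  }
  invisible(x)
}
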
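#' De-duplicate report versions by case identifier
#'
#' FAERS carries every submitted version of a case; analysis keeps one
#' report per case. Two criteria are applied within each CASEID: (i) the
#' version with the most recent FDA receipt date (FDA_DT) is retained;
#' (ii) on ties, the version with the higher PRIMARYID. Primaryids are
#' compared numerically when every id is purely numeric, lexicographically
#' otherwise. Partial receipt dates compare by their known prefix, with a
#' day-precision date beating a month-precision date in the same month
#' (more information is treated as more recent knowledge).
#'
#' Reports without a usable caseid are quarantined and reported, never
#' silently kept. The operation is idempotent and invariant to input order.
#'
#' @param x a `faers_data` object (all versions)
#' @return a list with elements
#'   \describe{
#'     \item{data}{`faers_data` restricted to the kept version per case,
#'       DEMO sorted by caseid}
#'     \item{decisions}{tibble audit: `caseid`, `kept_primaryid`,
#'       `dropped_primaryids` (list-column), `rule_used` in
#'       latest_fda_dt / max_primaryid / singleton}
#'     \item{quarantined}{tibble of DEMO rows lacking a caseid}
#'   }
#' @export
deduplicate <- function(x) {
  stopifnot(inherits(x, "faers_data"))
  demo <- x$demo
  no_case <- is.na(demo$caseid) | !nzchar(demo$caseid)
  quarantined <- demo[no_case, , drop = FALSE]
  if (nrow(quarantined) > 0L) {
    message(sprintf("deduplicate: quarantined %d report(s) without a caseid",
                    nrow(quarantined)))
  }
  demo <- demo[!no_case, , drop = FALSE]

  numeric_ids <- all_numeric_ids(demo$primaryid)
  pid_key <- if (numeric_ids) as.numeric(demo$primaryid) else demo$primaryid

  ranked <- demo |>
    dplyr::mutate(.date_key = faers_date_key(.data$fda_dt), .pid_key = pid_key) |>
    dplyr::group_by(.data$caseid) |>
    dplyr::arrange(dplyr::desc(.data$.date_key),
                   dplyr::desc(.data$.pid_key), .by_group = TRUE)

  decisions <- ranked |>
    dplyr::summarise(
      kept_primaryid = .data$primaryid[1L],
      dropped_primaryids = list(.data$primaryid[-1L]),
      rule_used = if (dplyr::n() == 1L) "singleton"
        else if (.data$.date_key[2L] == .data$.date_key[1L]) "max_primaryid"
        else "latest_fda_dt",
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$caseid)

  kept_ids <- decisions$kept_primaryid
  out <- filter_faers(x, kept_ids)
  out$demo <- out$demo[order(out$demo$caseid), , drop = FALSE]
  list(data = out, decisions = decisions, quarantined = quarantined)
}

#' Write the de-duplication audit trail
#'
#' One delimited row per case: caseid, kept primaryid, dropped primaryids
#' (semicolon-joined), and the rule that decided.
#'
#' @param decisions the `decisions` tibble from [deduplicate()]
#' @param path output file
#' @param delim delimiter, default comma
#' @return invisibly, `path`
#' @export
write_dedup_audit <- function(decisions, path, delim = ",") {
  flat <- decisions |>
    dplyr::mutate(dropped_primaryids = vapply(
      .data$dropped_primaryids, paste, character(1), collapse = ";"
    ))
  readr::write_delim(flat, path, delim = delim, na = "")
  invisible(path)
}
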
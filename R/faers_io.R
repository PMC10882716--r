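#' @importFrom rlang .data
NULL

# canonical column sets, lower-cased FAERS names so real quarters drop in
faers_table_columns <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
           "age_cod", "reporter_country", "occp_cod"),
  drug = c("primaryid", "drug_seq", "drugname", "prod_ai", "role_cod"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

faers_role_codes <- c("PS", "SS", "C", "I")
faers_outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

empty_faers_table <- function(table) {
  cols <- faers_table_columns[[table]]
  out <- tibble::as_tibble(stats::setNames(
    replicate(length(cols), character(0), simplify = FALSE), cols
  ))
  out
}

#' Construct a FAERS quarterly data object from in-memory tables
#'
#' Bundles the six quarterly tables (DEMO, DRUG, REAC, OUTC, THER, INDI) into
#' a single `faers_data` object. All fields are kept as character, matching
#' the raw ASCII files; missing optional columns are added as NA. Reaction
#' preferred terms are whitespace-normalized and de-duplicated within each
#' report, since downstream signal counting is at report level.
#'
#' @param demo,drug,reac,outc,ther,indi data frames with (a subset of) the
#'   published FAERS column names, lower-cased
#' @return a `faers_data` object: a named list of six tibbles with a
#'   `quarantine` attribute recording rows dropped for an unusable primaryid
#' @export
faers_data <- function(demo, drug = NULL, reac = NULL, outc = NULL,
                       ther = NULL, indi = NULL) {
  tabs <- list(demo = demo, drug = drug, reac = reac, outc = outc,
               ther = ther, indi = indi)
  quarantine <- list()
  for (nm in names(tabs)) {
    tab <- tabs[[nm]]
    if (is.null(tab) || nrow(tab) == 0L || ncol(tab) == 0L) {
      tabs[[nm]] <- empty_faers_table(nm)
      next
    }
    tab <- tibble::as_tibble(tab)
    names(tab) <- tolower(names(tab))
    tab <- dplyr::mutate(tab, dplyr::across(dplyr::everything(),
                                            ~ dplyr::na_if(stringr::str_squish(as.character(.x)), "")))
    for (col in setdiff(faers_table_columns[[nm]], names(tab))) {
      tab[[col]] <- NA_character_
    }
    tab <- tab[, union(faers_table_columns[[nm]],
                       intersect(names(tab), names(tab)))]
    bad <- is.na(tab$primaryid) | !nzchar(tab$primaryid)
    if (any(bad)) {
      quarantine[[nm]] <- tibble::tibble(
        table = nm, row = which(bad), reason = "missing primaryid"
      )
      tab <- tab[!bad, , drop = FALSE]
    }
    tabs[[nm]] <- tab
  }
  # within-report PT de-dup (case-insensitive after whitespace normalization)
  if (nrow(tabs$reac) > 0L) {
    tabs$reac <- tabs$reac |>
      dplyr::filter(!is.na(.data$pt) & nzchar(.data$pt)) |>
      dplyr::distinct(.data$primaryid, ptkey = norm_ws_upper(.data$pt),
                      .keep_all = TRUE) |>
      dplyr::select(-"ptkey")
  }
  structure(tabs,
            quarantine = dplyr::bind_rows(quarantine),
            class = "faers_data")
}

#' @export
print.faers_data <- function(x, ...) {
  cat("<faers_data>\n")
  for (nm in names(faers_table_columns)) {
    cat(sprintf("  %-5s %8d rows\n", toupper(nm), nrow(x[[nm]])))
  }
  q <- attr(x, "quarantine")
  if (!is.null(q) && nrow(q) > 0L) {
    cat(sprintf("  %d row(s) quarantined (unusable primaryid)\n", nrow(q)))
  }
  cat(sprintf("  %d report(s)\n", nrow(x$demo)))
  invisible(x)
}

#' Rows quarantined while assembling a FAERS data object
#'
#' @param x a `faers_data` object
#' @return tibble with columns `table`, `row`, `reason`
#' @export
quarantined_rows <- function(x) {
  q <- attr(x, "quarantine")
  if (is.null(q)) tibble::tibble(table = character(), row = integer(),
                                 reason = character()) else q
}

#' Read one FAERS-style quarter from disk
#'
#' Reads the six dollar-delimited ASCII tables of a quarterly extract and
#' assembles a [faers_data()] object. Files are located either by an explicit
#' named list of `paths` or by scanning `dir` for files whose names start
#' with the table name (e.g. `DEMO23Q1.txt`). DEMO, DRUG and REAC are
#' mandatory; OUTC, THER and INDI default to empty tables when absent.
#'
#' @param dir directory containing the quarter's files
#' @param paths named list/vector overriding file discovery
#'   (names among demo, drug, reac, outc, ther, indi)
#' @param delim field delimiter; FAERS uses `"$"`
#' @return a `faers_data` object
#' @export
read_faers_quarter <- function(dir = NULL, paths = NULL, delim = "$") {
  if (is.null(paths)) {
    if (is.null(dir)) stop("supply `dir` or `paths`")
    found <- list.files(dir, full.names = TRUE)
    paths <- list()
    for (nm in names(faers_table_columns)) {
      hit <- found[grepl(paste0("^", nm), tolower(basename(found)))]
      if (length(hit) > 0L) paths[[nm]] <- hit[[1L]]
    }
  } else {
    paths <- as.list(paths)
    names(paths) <- tolower(names(paths))
  }
  for (nm in c("demo", "drug", "reac")) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      stop(sprintf("mandatory table file for %s not found", toupper(nm)))
    }
  }
  read_one <- function(nm) {
    p <- paths[[nm]]
    if (is.null(p) || !file.exists(p)) return(NULL)
    if (file.size(p) == 0L) return(NULL)
    readr::read_delim(p, delim = delim,
                      col_types = readr::cols(.default = readr::col_character()),
                      na = c("", "NA"), progress = FALSE,
                      show_col_types = FALSE)
  }
  tabs <- lapply(stats::setNames(nm = names(faers_table_columns)), read_one)
  x <- faers_data(demo = tabs$demo, drug = tabs$drug, reac = tabs$reac,
                  outc = tabs$outc, ther = tabs$ther, indi = tabs$indi)
  q <- quarantined_rows(x)
  if (nrow(q) > 0L) {
    message(sprintf("read_faers_quarter: quarantined %d row(s) with unusable primaryid",
                    nrow(q)))
  }
  x
}

#' Write a FAERS data object as a quarterly file bundle
#'
#' Emits one delimited file per table (DEMO.txt, DRUG.txt, ...) in the FAERS
#' dollar-delimited dialect with a single header line, so the output
#' round-trips through [read_faers_quarter()].
#'
#' @param x a `faers_data` object
#' @param dir output directory (created if needed)
#' @param delim field delimiter, default the FAERS dollar sign
#' @return invisibly, the named vector of file paths written
#' @export
write_faers_quarter <- function(x, dir, delim = "$") {
  stopifnot(inherits(x, "faers_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(faers_table_columns)) {
    p <- file.path(dir, paste0(toupper(nm), ".txt"))
    readr::write_delim(x[[nm]], p, delim = delim, na = "")
    paths[nm] <- p
  }
  invisible(paths)
}

#' Parse FAERS date strings with a precision flag
#'
#' FAERS dates are digit strings: `YYYYMMDD`, `YYYYMM` or `YYYY`. Partial
#' dates are retained (anchored at the first day of the period) with a
#' precision flag instead of being nulled; downstream rules decide whether a
#' given precision is usable. Garbled strings, zero sentinels and impossible
#' calendar dates parse to precision `"none"`. Never raises.
#'
#' @param x character vector of raw date strings
#' @return tibble with columns `date` (Date, NA when unparseable) and
#'   `precision` (factor: day, month, year, none)
#' @export
#' @examples
#' parse_faers_date(c("20040101", "2013", "00000000"))
parse_faers_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- gsub("[^0-9]", "", x)
  n <- nchar(x)
  date <- rep(as.Date(NA), length(x))
  precision <- rep("none", length(x))

  year_ok <- function(s) {
    y <- suppressWarnings(as.integer(substr(s, 1, 4)))
    !is.na(y) & y >= 1900 & y <= 2199
  }
  i8 <- n == 8L & year_ok(x)
  if (any(i8)) {
    d <- suppressWarnings(as.Date(x[i8], format = "%Y%m%d"))
    # as.Date rolls nothing over with %Y%m%d; invalid combos give NA
    ok <- !is.na(d)
    date[which(i8)[ok]] <- d[ok]
    precision[which(i8)[ok]] <- "day"
  }
  i6 <- n == 6L & year_ok(x)
  if (any(i6)) {
    d <- suppressWarnings(as.Date(paste0(x[i6], "01"), format = "%Y%m%d"))
    ok <- !is.na(d)
    date[which(i6)[ok]] <- d[ok]
    precision[which(i6)[ok]] <- "month"
  }
  i4 <- n == 4L & year_ok(x)
  if (any(i4)) {
    date[i4] <- as.Date(paste0(x[i4], "0101"), format = "%Y%m%d")
    precision[i4] <- "year"
  }
  tibble::tibble(
    date = date,
    precision = factor(precision, levels = c("day", "month", "year", "none"))
  )
}

# orderable key for partial dates: pad the known prefix, then a precision
# rank so that within the same prefix more-precise dates sort as more recent
# knowledge (day > month > year > none)
faers_date_key <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- gsub("[^0-9]", "", x)
  parsed <- parse_faers_date(x)
  pad <- dplyr::case_when(
    parsed$precision == "day" ~ x,
    parsed$precision == "month" ~ paste0(substr(x, 1, 6), "00"),
    parsed$precision == "year" ~ paste0(substr(x, 1, 4), "0000"),
    TRUE ~ "00000000"
  )
  rank <- c(day = 3L, month = 2L, year = 1L, none = 0L)[as.character(parsed$precision)]
  paste0(pad, rank)
}

#' Assemble per-case report bundles
#'
#' Joins the six tables into one row per report (per DEMO primaryid) with the
#' child records as list-columns of tibbles. Intended for inspection and for
#' small fixtures; the pipeline stages themselves work on the relational
#' tables directly.
#'
#' @param x a `faers_data` object
#' @return tibble with the DEMO columns plus list-columns `drug`, `reac`,
#'   `ther`, `outc`, `indi`
#' @export
report_bundles <- function(x) {
  stopifnot(inherits(x, "faers_data"))
  ids <- x$demo$primaryid
  split_tab <- function(tab) {
    f <- factor(tab$primaryid, levels = ids)
    keep <- !is.na(f)
    split(tab[keep, , drop = FALSE], f[keep])
  }
  out <- x$demo
  for (nm in c("drug", "reac", "ther", "outc", "indi")) {
    out[[nm]] <- unname(split_tab(x[[nm]]))
  }
  out
}

#' Number of reports in a FAERS data object
#'
#' @param x a `faers_data` object
#' @return integer count of DEMO rows (one per report version)
#' @export
n_reports <- function(x) nrow(x$demo)

# subset every table of a faers_data to the given primaryids, preserving the
# quarantine attribute
filter_faers <- function(x, keep_ids) {
  for (nm in names(faers_table_columns)) {
    x[[nm]] <- x[[nm]][x[[nm]]$primaryid %in% keep_ids, , drop = FALSE]
  }
  x
}
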
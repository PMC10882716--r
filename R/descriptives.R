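#' Convert FAERS age values to years
#'
#' FAERS stores age with a unit code; values are converted to years before
#' summarizing (decades x10, months /12, weeks /52, days /365.25, hours
#' /8766). Unknown units or unparseable values give NA.
#'
#' @param age character or numeric age values
#' @param age_cod unit codes (DEC, YR, MON, WK, DY, HR; case-insensitive)
#' @return numeric vector of ages in years
#' @export
age_in_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  u <- norm_ws_upper(age_cod)
  mult <- dplyr::case_when(
    u == "DEC" ~ 10,
    u == "YR" | u == "" | is.na(u) ~ 1,
    u == "MON" ~ 1 / 12,
    u == "WK" ~ 1 / 52,
    u == "DY" ~ 1 / 365.25,
    u == "HR" ~ 1 / 8766,
    TRUE ~ NA_real_
  )
  a * mult
}

# compact continent lookup covering the fixture and common report-country
# codes; anything else maps to Unknown
country_continent_table <- function() {
  tibble::tribble(
    ~country, ~continent,
    "US", "North America", "CA", "North America", "MX", "North America",
    "PR", "North America", "USA", "North America",
    "GB", "Europe", "DE", "Europe", "FR", "Europe", "IT", "Europe",
    "ES", "Europe", "NL", "Europe", "SE", "Europe", "DK", "Europe",
    "PL", "Europe", "IE", "Europe", "CH", "Europe", "BE", "Europe",
    "AT", "Europe", "PT", "Europe", "NO", "Europe", "FI", "Europe",
    "GR", "Europe", "CZ", "Europe", "RU", "Europe", "UA", "Europe",
    "CN", "Asia", "JP", "Asia", "IN", "Asia", "KR", "Asia", "TW", "Asia",
    "TH", "Asia", "PH", "Asia", "ID", "Asia", "MY", "Asia", "SG", "Asia",
    "IL", "Asia", "SA", "Asia", "TR", "Asia", "VN", "Asia", "PK", "Asia",
    "BR", "South America", "AR", "South America", "CO", "South America",
    "CL", "South America", "PE", "South America", "VE", "South America",
    "EC", "South America", "UY", "South America",
    "AU", "Oceania", "NZ", "Oceania",
    "ZA", "Africa", "NG", "Africa", "EG", "Africa", "KE", "Africa",
    "MA", "Africa", "TN", "Africa", "GH", "Africa"
  )
}

#' Map reporter country codes to continents
#'
#' @param country character vector of ISO-like country codes
#' @return character vector of continents; unrecognized or missing codes
#'   give "Unknown"
#' @export
country_to_continent <- function(country) {
  lut <- country_continent_table()
  idx <- match(norm_ws_upper(country), lut$country)
  out <- lut$continent[idx]
  out[is.na(out)] <- "Unknown"
  out
}

sex_labels <- c(F = "Women", M = "Men")

#' Characterize a cohort: the descriptive table
#'
#' Produces the per-stratum characterization used in spontaneous-report
#' studies: sex, age availability with median/IQR in years, reporting region
#' (continent), reporting year (from the FDA receipt date), reporter
#' occupation, indication group, and the single most-serious outcome per
#' report. Every categorical block carries an explicit Unknown row so counts
#' always sum to the stratum's case count; percentages are against that
#' count, rounded half-up to 2 decimals.
#'
#' Strata are "overall" plus one stratum per regimen; a report naming two
#' regimens as primary suspect appears in both regimen strata but once
#' overall.
#'
#' @param cohort a `faers_cohort` from [build_cohort()] (or any tibble with
#'   the same columns); usually pre-filtered to target-SOC cases when
#'   characterizing an adverse-event class
#' @param quantile_type quantile convention for the age summary
#' @return a `characteristics_table`: long tibble with columns `stratum`,
#'   `block`, `level`, `n`, `pct` plus an `age_summary` attribute
#' @export
summarize_cohort <- function(cohort, quantile_type = 7) {
  strata <- c(list(overall = rep(TRUE, nrow(cohort))),
              stats::setNames(lapply(
                attr(cohort, "regimens") %||% sort(unique(unlist(cohort$regimens))),
                function(r) vapply(cohort$regimens, function(v) r %in% v, logical(1))
              ), attr(cohort, "regimens") %||% sort(unique(unlist(cohort$regimens)))))

  one_block <- function(values, block, stratum, n_stratum, levels = NULL) {
    values[is.na(values) | !nzchar(values)] <- "Unknown"
    tab <- table(values)
    lv <- if (is.null(levels)) names(tab) else union(levels, names(tab))
    cnt <- as.integer(tab[lv])
    cnt[is.na(cnt)] <- 0L
    tibble::tibble(stratum = stratum, block = block, level = lv,
                   n = cnt, pct = pct(cnt, n_stratum))
  }

  rows <- list()
  age_rows <- list()
  for (s in names(strata)) {
    sub <- cohort[strata[[s]], , drop = FALSE]
    ns <- nrow(sub)
    sex <- sex_labels[norm_ws_upper(sub$sex)]
    rows[[length(rows) + 1L]] <- one_block(unname(sex), "sex", s, ns,
                                           c("Women", "Men", "Unknown"))
    ages <- age_in_years(sub$age, sub$age_cod)
    rows[[length(rows) + 1L]] <- one_block(
      ifelse(is.na(ages), "Unknown", "Known"), "age", s, ns, c("Known", "Unknown"))
    qs <- quantile_summary(ages, type = quantile_type)
    age_rows[[length(age_rows) + 1L]] <- dplyr::mutate(qs, stratum = s,
                                                       .before = 1L)
    rows[[length(rows) + 1L]] <- one_block(
      country_to_continent(sub$reporter_country), "region", s, ns,
      c("North America", "Europe", "Asia", "South America", "Oceania",
        "Africa", "Unknown"))
    yr <- substr(gsub("[^0-9]", "", ifelse(is.na(sub$fda_dt), "", sub$fda_dt)), 1, 4)
    yr[nchar(yr) < 4] <- "Unknown"
    rows[[length(rows) + 1L]] <- one_block(yr, "year", s, ns)
    occ <- occupation_label(sub$occp_cod)
    rows[[length(rows) + 1L]] <- one_block(occ, "occupation", s, ns)
    rows[[length(rows) + 1L]] <- one_block(sub$indication, "indication", s, ns)
    out_lab <- outcome_label(sub$outcome)
    rows[[length(rows) + 1L]] <- one_block(out_lab, "outcome", s, ns)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "age_summary") <- dplyr::bind_rows(age_rows)
  attr(out, "stratum_n") <- tibble::tibble(
    stratum = names(strata),
    n = unname(vapply(strata, sum, integer(1)))
  )
  class(out) <- c("characteristics_table", class(out))
  out
}

occupation_label <- function(occp_cod) {
  u <- norm_ws_upper(occp_cod)
  dplyr::case_when(
    u == "CN" ~ "Consumer",
    u == "MD" ~ "Physician",
    u == "PH" ~ "Pharmacist",
    u == "HP" ~ "Health professional",
    u == "OT" ~ "Other health professional",
    u == "LW" ~ "Lawyer",
    TRUE ~ "Unknown"
  )
}

outcome_label <- function(outc_cod) {
  u <- norm_ws_upper(outc_cod)
  dplyr::case_when(
    u == "DE" ~ "Death",
    u == "LT" ~ "Life threatening",
    u == "HO" ~ "Hospitalization",
    u == "DS" ~ "Disability",
    u == "CA" ~ "Congenital anomaly",
    u == "RI" ~ "Required intervention to prevent",
    u == "OT" ~ "Other medical event",
    TRUE ~ "Unknown"
  )
}

#' Age median and IQR per stratum
#'
#' @param x a `characteristics_table` from [summarize_cohort()]
#' @return tibble: stratum, n (ages known), median, q1, q3 (years)
#' @export
age_summary <- function(x) attr(x, "age_summary")

#' Write a characteristics table as delimited text
#'
#' @param x a `characteristics_table`
#' @param path output file
#' @param delim delimiter, default comma
#' @return invisibly, `path`
#' @export
write_characteristics <- function(x, path, delim = ",") {
  readr::write_delim(x, path, delim = delim, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
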
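#' MedDRA system organ class code for psychiatric disorders
#' @export
PSYCHIATRIC_SOC <- "10037175"

#' Build a drug name lexicon
#'
#' A lexicon maps each regimen (generic drug) to the set of generic and
#' brand names under which it appears in DRUG records. Matching is
#' case-insensitive after whitespace/punctuation normalization and uses
#' whole-word containment, so "OZEMPIC 0.5 MG PEN" matches the brand name
#' "OZEMPIC" but "metformin" matches nothing.
#'
#' @param x named list: regimen name -> character vector of names
#' @return a `drug_lexicon` object
#' @export
drug_lexicon <- function(x) {
  stopifnot(is.list(x), length(x) > 0L, !is.null(names(x)), all(nzchar(names(x))))
  x <- lapply(x, function(v) {
    v <- unique(norm_ws_upper(v))
    v <- v[nzchar(v)]
    if (length(v) == 0L) stop("every regimen needs at least one name")
    v
  })
  structure(x, class = "drug_lexicon")
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat(sprintf("<drug_lexicon> %d regimen(s)\n", length(x)))
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' The GLP-1 receptor agonist lexicon
#'
#' Generic plus FDA-approved brand names for the six marketed GLP-1 receptor
#' agonist regimens.
#'
#' @return a [drug_lexicon()] with six regimens
#' @export
glp1_lexicon <- function() {
  drug_lexicon(list(
    exenatide    = c("exenatide", "BYETTA", "BYDUREON"),
    liraglutide  = c("liraglutide", "VICTOZA", "SAXENDA"),
    lixisenatide = c("lixisenatide", "ADLYXIN", "SOLIQUA"),
    dulaglutide  = c("dulaglutide", "TRULICITY"),
    semaglutide  = c("semaglutide", "OZEMPIC", "RYBELSUS", "WEGOVY"),
    tirzepatide  = c("tirzepatide", "MOUNJARO")
  ))
}

#' Read a drug lexicon from a delimited file
#'
#' Expects columns `regimen` and `name`, one name per row.
#'
#' @param path file path
#' @param delim delimiter, default comma
#' @return a [drug_lexicon()]
#' @export
read_drug_lexicon <- function(path, delim = ",") {
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("regimen", "name") %in% names(tab)))
  drug_lexicon(split(tab$name, tab$regimen))
}

# uppercase, punctuation to space, squish — so whole-word regexes see tokens
normalize_drug_name <- function(x) {
  stringr::str_squish(gsub("[^A-Z0-9]+", " ", toupper(as.character(x))))
}

#' Match drug name fields against a lexicon
#'
#' A regimen matches when any of its lexicon names equals the normalized
#' name or appears as a whole word within it. Both the verbatim drugname and
#' the active-ingredient field are matched by default.
#'
#' @param drugname character vector of verbatim drug names
#' @param prod_ai optional character vector of active-ingredient strings
#' @param lexicon a [drug_lexicon()]
#' @param fields which fields participate in matching
#' @return a list (one element per record) of matched regimen name vectors;
#'   empty vector means no match
#' @export
#' @examples
#' match_drug("Ozempic 0.5 mg pen", lexicon = glp1_lexicon())
match_drug <- function(drugname, prod_ai = NULL, lexicon,
                       fields = c("drugname", "prod_ai")) {
  stopifnot(inherits(lexicon, "drug_lexicon"))
  fields <- match.arg(fields, several.ok = TRUE)
  n <- length(drugname)
  hay <- character(n)
  if ("drugname" %in% fields) hay <- normalize_drug_name(drugname)
  if ("prod_ai" %in% fields && !is.null(prod_ai)) {
    hay <- paste(hay, normalize_drug_name(prod_ai))
  }
  hits <- matrix(FALSE, nrow = n, ncol = length(lexicon),
                 dimnames = list(NULL, names(lexicon)))
  for (reg in names(lexicon)) {
    pat <- paste0("\\b(", paste(normalize_drug_name(lexicon[[reg]]),
                                collapse = "|"), ")\\b")
    hits[, reg] <- grepl(pat, hay)
  }
  apply(hits, 1L, function(r) names(lexicon)[r], simplify = FALSE)
}

#' Build a preferred-term to system-organ-class map
#'
#' @param x data frame with columns `pt`, `soc_name`, `soc_code`; each PT
#'   must map to exactly one SOC (MedDRA primary SOC convention)
#' @return a `pt_soc_map` tibble (PT keys whitespace-normalized, uppercase)
#' @export
pt_soc_map <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("pt", "soc_name", "soc_code") %in% names(x)))
  x <- dplyr::mutate(x, pt = norm_ws_upper(.data$pt),
                     soc_code = as.character(.data$soc_code)) |>
    dplyr::distinct()
  if (anyDuplicated(x$pt)) {
    stop("each PT must map to exactly one SOC: ",
         paste(unique(x$pt[duplicated(x$pt)]), collapse = ", "))
  }
  class(x) <- c("pt_soc_map", class(x))
  x
}

#' Read a PT to SOC map from a delimited file
#'
#' @param path file with columns `pt`, `soc_name`, `soc_code`
#' @param delim delimiter, default comma
#' @return a [pt_soc_map()]
#' @export
read_pt_soc_map <- function(path, delim = ",") {
  pt_soc_map(readr::read_delim(path, delim = delim, show_col_types = FALSE,
                               col_types = readr::cols(.default = readr::col_character())))
}

#' Extract the target-drug cohort and tag reactions with SOC membership
#'
#' A de-duplicated report enters the cohort when at least one of its DRUG
#' records matches the lexicon with role code PS (primary suspect). Each
#' cohort report is flagged a target-SOC case when at least one of its
#' reaction PTs maps to `target_soc` in the supplied map; PTs absent from
#' the map are tagged unmapped and counted, never dropped.
#'
#' @param x a de-duplicated `faers_data` object
#' @param lexicon a [drug_lexicon()]
#' @param soc_map a [pt_soc_map()]
#' @param target_soc SOC code defining the event class of interest
#'   (default psychiatric disorders, 10037175)
#' @param match_fields fields used by [match_drug()]
#' @return a `faers_cohort` tibble, one row per cohort report, with
#'   demographics, matched `regimens` and `matched_seqs` list-columns,
#'   reaction `pts` list-column, `target_soc` flag and `n_unmapped_pts`
#' @export
build_cohort <- function(x, lexicon, soc_map, target_soc = PSYCHIATRIC_SOC,
                         match_fields = c("drugname", "prod_ai")) {
  stopifnot(inherits(x, "faers_data"), inherits(lexicon, "drug_lexicon"),
            inherits(soc_map, "pt_soc_map"))
  drug <- x$drug
  ps <- drug[!is.na(drug$role_cod) & norm_ws_upper(drug$role_cod) == "PS", ,
             drop = FALSE]
  m <- match_drug(ps$drugname, ps$prod_ai, lexicon, fields = match_fields)
  hit <- lengths(m) > 0L
  matched <- ps[hit, , drop = FALSE]
  matched$regimens <- m[hit]

  if (nrow(matched) == 0L) {
    cohort_ids <- character(0)
  } else {
    cohort_ids <- unique(matched$primaryid)
  }

  per_report <- matched |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(
      regimens = list(sort(unique(unlist(.data$regimens)))),
      matched_seqs = list(unique(.data$drug_seq)),
      .groups = "drop"
    )

  reac <- x$reac |>
    dplyr::filter(.data$primaryid %in% cohort_ids) |>
    dplyr::mutate(ptkey = norm_ws_upper(.data$pt)) |>
    dplyr::left_join(dplyr::select(soc_map, "pt", "soc_code"),
                     by = c("ptkey" = "pt"))
  reac_sum <- reac |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(
      pts = list(.data$ptkey),
      target_soc = any(!is.na(.data$soc_code) & .data$soc_code == target_soc),
      n_unmapped_pts = sum(is.na(.data$soc_code)),
      .groups = "drop"
    )

  cohort <- x$demo |>
    dplyr::filter(.data$primaryid %in% cohort_ids) |>
    dplyr::inner_join(per_report, by = "primaryid") |>
    dplyr::left_join(reac_sum, by = "primaryid")
  cohort$pts[vapply(cohort$pts, is.null, logical(1))] <- list(character(0))
  cohort$target_soc[is.na(cohort$target_soc)] <- FALSE
  cohort$n_unmapped_pts[is.na(cohort$n_unmapped_pts)] <- 0L

  # indication group via INDI rows linked to the matched drug ordinals
  indi <- x$indi |>
    dplyr::filter(.data$primaryid %in% cohort_ids)
  seq_map <- per_report |>
    tidyr::unnest_longer("matched_seqs", values_to = "drug_seq") |>
    dplyr::select("primaryid", "drug_seq")
  indi <- indi |>
    dplyr::inner_join(seq_map, by = c("primaryid", "indi_drug_seq" = "drug_seq")) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(indication = indication_group(.data$indi_pt), .groups = "drop")
  cohort <- dplyr::left_join(cohort, indi, by = "primaryid")
  cohort$indication[is.na(cohort$indication)] <- "Unknown"

  # single outcome per report: the most serious listed code, if any
  outc <- x$outc |>
    dplyr::filter(.data$primaryid %in% cohort_ids) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(outcome = most_serious_outcome(.data$outc_cod), .groups = "drop")
  cohort <- dplyr::left_join(cohort, outc, by = "primaryid")
  cohort$outcome[is.na(cohort$outcome)] <- "Unknown"

  attr(cohort, "target_soc") <- target_soc
  attr(cohort, "regimens") <- names(lexicon)
  class(cohort) <- c("faers_cohort", class(cohort))
  cohort
}

# collapse indication PTs into the coarse groups used in report tables
indication_group <- function(indi_pt) {
  v <- norm_ws_upper(indi_pt)
  v <- v[nzchar(v)]
  if (length(v) == 0L) return("Unknown")
  if (any(grepl("DIABETES", v))) return("Diabetes mellitus")
  if (any(grepl("WEIGHT|OBESITY", v))) return("Weight control")
  if (any(grepl("BLOOD GLUCOSE", v))) return("Blood glucose abnormal")
  if (all(grepl("UNKNOWN INDICATION", v))) return("Unknown")
  "Others"
}

outcome_severity_order <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

most_serious_outcome <- function(codes) {
  codes <- norm_ws_upper(codes)
  codes <- codes[codes %in% outcome_severity_order]
  if (length(codes) == 0L) return("Unknown")
  outcome_severity_order[min(match(codes, outcome_severity_order))]
}

#' Per-regimen and overall cohort counts
#'
#' Counts cohort reports and target-SOC cases per regimen and overall, with
#' the target share as a percentage. A report naming two regimens as primary
#' suspect counts once overall and once in each regimen's row, so regimen
#' rows can sum to slightly more than the overall row.
#'
#' @param cohort a `faers_cohort` from [build_cohort()]
#' @return tibble: `stratum`, `n_reports`, `n_target`, `pct_target`
#' @export
cohort_counts <- function(cohort) {
  regs <- attr(cohort, "regimens")
  if (is.null(regs)) regs <- sort(unique(unlist(cohort$regimens)))
  long <- tibble::tibble(regimen = cohort$regimens,
                         target_soc = cohort$target_soc) |>
    tidyr::unnest_longer("regimen") |>
    dplyr::count(.data$regimen, wt = NULL, name = "n_reports_") |>
    dplyr::rename(stratum = "regimen", n_reports = "n_reports_")
  tgt <- tibble::tibble(regimen = cohort$regimens,
                        target_soc = cohort$target_soc) |>
    tidyr::unnest_longer("regimen") |>
    dplyr::group_by(stratum = .data$regimen) |>
    dplyr::summarise(n_target = sum(.data$target_soc), .groups = "drop")
  per_reg <- tibble::tibble(stratum = regs) |>
    dplyr::left_join(long, by = "stratum") |>
    dplyr::left_join(tgt, by = "stratum") |>
    dplyr::mutate(n_reports = dplyr::coalesce(.data$n_reports, 0L),
                  n_target = dplyr::coalesce(.data$n_target, 0L))
  overall <- tibble::tibble(stratum = "overall",
                            n_reports = nrow(cohort),
                            n_target = sum(cohort$target_soc))
  dplyr::bind_rows(overall, per_reg) |>
    dplyr::mutate(pct_target = pct(.data$n_target, .data$n_reports))
}
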
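#' Assemble and validate a pipeline configuration
#'
#' A configuration names either an input quarter directory (`input_dir`) or
#' synthetic-generator settings (`synth`, a list of [synth_config()]
#' arguments), the drug lexicon and PT-to-SOC map (paths or in-memory
#' objects), the target SOC, signal thresholds and the output directory.
#'
#' @param out_dir output directory for pipeline artifacts
#' @param input_dir directory holding a quarterly file bundle (or NULL)
#' @param synth list of [synth_config()] arguments (used when `input_dir`
#'   is NULL)
#' @param lexicon a [drug_lexicon()] or a path readable by
#'   [read_drug_lexicon()]; default the GLP-1 lexicon
#' @param soc_map a [pt_soc_map()] or a path readable by
#'   [read_pt_soc_map()]; default the synthetic catalog's map
#' @param target_soc SOC code of interest
#' @param min_count positivity count threshold (a >= min_count)
#' @param z normal quantile for the ROR interval
#' @param quantile_type quantile convention for medians/IQRs
#' @param comparator "full" or "class_exclusive"
#' @param seed seed for the synthetic generator
#' @return a validated `pipeline_config` list
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            synth = list(),
                            lexicon = glp1_lexicon(),
                            soc_map = synth_soc_map(),
                            target_soc = PSYCHIATRIC_SOC,
                            min_count = 5,
                            z = 1.96,
                            quantile_type = 7,
                            comparator = "full",
                            seed = 1L) {
  if (is.character(lexicon)) {
    if (!file.exists(lexicon)) stop("lexicon path does not exist: ", lexicon)
    lexicon <- read_drug_lexicon(lexicon)
  }
  if (is.character(soc_map)) {
    if (!file.exists(soc_map)) stop("PT-to-SOC map path does not exist: ", soc_map)
    soc_map <- read_pt_soc_map(soc_map)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  stopifnot(min_count > 0, z > 0)
  structure(list(out_dir = out_dir, input_dir = input_dir, synth = synth,
                 lexicon = lexicon, soc_map = soc_map,
                 target_soc = as.character(target_soc),
                 min_count = min_count, z = z, quantile_type = quantile_type,
                 comparator = match.arg(comparator,
                                        c("full", "class_exclusive")),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `lexicon` and
#' `soc_map` are file paths, `synth` a mapping of generator arguments.
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("out_dir", "input_dir", "synth", "lexicon",
                          "soc_map", "target_soc", "min_count", "z",
                          "quantile_type", "comparator", "seed"))]
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Stages run in order: read (or generate) the quarter, de-duplicate,
#' extract the cohort, then characterize, compute time-to-onset and scan
#' for signals. Every artifact is written under `out_dir` and listed in a
#' JSON manifest with row counts and a configuration hash; the attrition
#' flow (raw report versions, de-duplicated reports, cohort reports,
#' target-SOC cases) is logged and recorded in the manifest.
#'
#' @param config a `pipeline_config`
#' @param quiet suppress progress messages
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (!is.null(config$input_dir)) {
    say("reading quarter from %s", config$input_dir)
    x <- read_faers_quarter(config$input_dir)
  } else {
    say("generating synthetic quarter (seed %d)", config$seed)
    scfg <- do.call(synth_config, c(list(seed = config$seed), config$synth))
    x <- generate_faers(scfg)$data
  }
  n_raw <- n_reports(x)
  say("raw report versions: %d", n_raw)

  dd <- deduplicate(x)
  n_dedup <- n_reports(dd$data)
  say("after de-duplication: %d", n_dedup)
  write_dedup_audit(dd$decisions, file.path(out_dir, "dedup_audit.csv"))

  cohort <- build_cohort(dd$data, config$lexicon, config$soc_map,
                         target_soc = config$target_soc)
  n_cohort <- nrow(cohort)
  n_target <- sum(cohort$target_soc)
  say("cohort reports: %d (target-SOC cases: %d)", n_cohort, n_target)
  counts <- cohort_counts(cohort)
  readr::write_csv(counts, file.path(out_dir, "cohort_counts.csv"), na = "")

  target_cases <- cohort[cohort$target_soc, , drop = FALSE]
  attr(target_cases, "regimens") <- attr(cohort, "regimens")
  chars <- summarize_cohort(target_cases, quantile_type = config$quantile_type)
  write_characteristics(chars, file.path(out_dir, "characteristics.csv"))

  onset <- compute_onset(target_cases, dd$data)
  readr::write_csv(onset, file.path(out_dir, "onset_records.csv"), na = "")
  osum <- summarize_onset(onset, quantile_type = config$quantile_type)
  readr::write_csv(osum, file.path(out_dir, "onset_summary.csv"), na = "")
  readr::write_csv(onset_curves(onset), file.path(out_dir, "onset_curves.csv"),
                   na = "")

  signals <- scan_signals(dd$data, config$lexicon,
                          min_count = config$min_count, z = config$z,
                          comparator = config$comparator)
  write_signal_table(signals, file.path(out_dir, "signal_table.csv"))

  files <- c("dedup_audit.csv", "cohort_counts.csv", "characteristics.csv",
             "onset_records.csv", "onset_summary.csv", "onset_curves.csv",
             "signal_table.csv")
  manifest <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    attrition = list(raw_versions = n_raw, deduplicated = n_dedup,
                     cohort = n_cohort, target_soc_cases = n_target),
    files = lapply(stats::setNames(nm = files), function(f) {
      list(path = f,
           rows = nrow(readr::read_csv(file.path(out_dir, f),
                                       show_col_types = FALSE,
                                       progress = FALSE)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("manifest written to %s", file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
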
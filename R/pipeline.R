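# End-to-end orchestration: load quarters -> deduplicate -> extract cases ->
# normalize drug names -> disproportionality -> descriptive strata, with a
# validated configuration, stage logging and a JSON run summary.

pipeline_defaults <- function() {
  list(input_dir = NULL, quarters = NULL,
       pt = "nephrolithiasis", pt_code = 10029148,
       drug_dict = NULL, label_risk = NULL,
       top_n = 50, min_a = 3, roles = NULL, continuity = "off",
       out_dir = "pvsignal-output")
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; unknown fields are rejected,
#' missing fields take documented defaults (target PT nephrolithiasis,
#' top-50, `min_a = 3`). All problems are collected, not just the first.
#'
#' @param config YAML path or named list.
#' @return list with elements `config` (defaults merged), `errors`
#'   (character vector, empty when valid) and `ok`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      return(list(config = NULL,
                  errors = paste("config file not found:", config),
                  ok = FALSE))
    }
    config <- tryCatch(yaml::read_yaml(config), error = function(e) {
      e
    })
    if (inherits(config, "error")) {
      return(list(config = NULL,
                  errors = paste("config file unreadable:",
                                 conditionMessage(config)),
                  ok = FALSE))
    }
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    errors <- c(errors, paste("unknown config field(s):",
                              paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[names(config) %in% names(defaults)])

  if (is.null(cfg$input_dir)) {
    errors <- c(errors, "input_dir: required, none given")
  } else if (!dir.exists(cfg$input_dir)) {
    errors <- c(errors, paste("input_dir: directory not found:", cfg$input_dir))
  }
  if (!is.null(cfg$quarters)) {
    bad <- !grepl("^[0-9]{4}Q[1-4]$", cfg$quarters)
    if (any(bad)) {
      errors <- c(errors, paste("quarters: malformed label(s):",
                                paste(cfg$quarters[bad], collapse = ", ")))
    } else if (length(cfg$quarters) == 2 &&
               cfg$quarters[1] > cfg$quarters[2]) {
      errors <- c(errors, "quarters: range is not well-ordered")
    }
  }
  if (is.null(cfg$pt) || !any(nzchar(trimws(cfg$pt)))) {
    if (is.null(cfg$pt_code)) {
      errors <- c(errors, "pt: a target preferred term or pt_code is required")
    }
  }
  for (f in c("drug_dict", "label_risk")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      errors <- c(errors, paste0(f, ": file not found: ", cfg[[f]]))
    }
  }
  if (!is.numeric(cfg$top_n) || cfg$top_n < 1) {
    errors <- c(errors, "top_n: must be a number >= 1")
  }
  if (!is.numeric(cfg$min_a) || cfg$min_a < 0) {
    errors <- c(errors, "min_a: must be a non-negative number")
  }
  if (!cfg$continuity %in% c("off", "on")) {
    errors <- c(errors, "continuity: must be 'off' or 'on'")
  }
  if (is.null(cfg$out_dir) || !nzchar(cfg$out_dir)) {
    errors <- c(errors, "out_dir: required, none given")
  }
  list(config = cfg, errors = errors, ok = length(errors) == 0)
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[pvsignal] %-12s %6.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full signal-detection pipeline
#'
#' Reads the configured quarters, deduplicates the pooled DEMO stream,
#' extracts the target-PT case set, normalizes drug mentions, builds 2x2
#' tables, computes RORs and signal flags for the top-`top_n` drugs, flags
#' label gaps, and writes all stage outputs to `out_dir`: `ror_table.csv`,
#' `strata_<dimension>.csv` for every dimension, `dedup_log.csv`, and
#' `run_summary.json` recording the record counts at every stage.
#'
#' @param config YAML path or named list; see [validate_config()]. If
#'   `quarters` has exactly two elements they are treated as an inclusive
#'   range; `NULL` autodetects quarters from DEMO filenames.
#' @return invisibly, a list with `ror_table` (unrounded), `strata`,
#'   `trend`, `dedup` and `summary`.
#' @export
run_pipeline <- function(config) {
  v <- validate_config(config)
  if (!v$ok) {
    stop("invalid configuration:\n  ", paste(v$errors, collapse = "\n  "),
         call. = FALSE)
  }
  cfg <- v$config

  quarters <- cfg$quarters
  if (is.null(quarters)) {
    hits <- list.files(cfg$input_dir, pattern = "^demo[0-9]{4}q[1-4]\\.txt$",
                       ignore.case = TRUE)
    quarters <- sort(unique(toupper(sub("\\.txt$", "",
                                        sub("^demo", "", hits,
                                            ignore.case = TRUE),
                                        ignore.case = TRUE))))
    if (length(quarters) == 0) {
      stop("no DEMO tables found in ", cfg$input_dir,
           " (DEMO is required for deduplication)", call. = FALSE)
    }
  } else if (length(quarters) == 2) {
    quarters <- quarter_seq(quarters[1], quarters[2])
  }

  bundles <- run_stage("load", lapply(quarters, function(q) {
    faers_read_quarter(cfg$input_dir, q)
  }))
  demo <- do.call(rbind, lapply(bundles, `[[`, "demo"))
  drug <- do.call(rbind, lapply(bundles, `[[`, "drug"))
  reac <- do.call(rbind, lapply(bundles, `[[`, "reac"))
  outc <- do.call(rbind, lapply(bundles, `[[`, "outc"))

  demo <- run_stage("normalize", normalize_demo(demo))
  dd <- run_stage("dedup", deduplicate(demo))
  cases <- run_stage("cases",
                     extract_cases(dd$reports, reac, pt = cfg$pt,
                                   pt_code = cfg$pt_code))
  dict <- read_drug_dictionary(cfg$drug_dict %||% starter_drug_dictionary())
  risk <- read_label_risk(cfg$label_risk %||% starter_label_risk())
  mentions <- run_stage("drugmap",
                        normalize_mentions(drug, dict, roles = cfg$roles))
  results <- run_stage("dispro", {
    ct <- build_contingency(cases, dd$reports, mentions)
    res <- ror(ct, continuity = cfg$continuity, min_a = cfg$min_a)
    res$atc_class <- assign_atc(res$drug, dict)
    flag_label_gaps(rank_drugs(res, cfg$top_n), risk)
  })
  strata <- run_stage("describe", {
    dims <- c("age", "sex", "reporter", "country", "year", "outcome")
    stats::setNames(lapply(dims, function(d) {
      stratify(cases, d, outcomes = if (d == "outcome") outc)
    }), dims)
  })
  trend <- yearly_trend(cases)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ror_table(results, file.path(cfg$out_dir, "ror_table.csv"))
  write_dedup_log(dd, file.path(cfg$out_dir, "dedup_log.csv"))
  for (d in names(strata)) {
    utils::write.csv(strata[[d]],
                     file.path(cfg$out_dir, paste0("strata_", d, ".csv")),
                     row.names = FALSE)
  }
  gap <- attr(results, "label_gap_counts")
  summary <- list(
    quarters = quarters,
    reports_read = nrow(demo),
    deduplicated = dd$log$kept,
    removed = dd$log$removed,
    quarantined = dd$log$quarantined,
    cases = length(cases$case_ids),
    drugs_with_event = nrow(results),
    signals = unname(gap["signals"]),
    known_risk = unname(gap["known_risk"]),
    potential_new_signals = unname(gap["potential_new_signal"]),
    drug_name_match_rate = attr(mentions, "match_rate"))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[pvsignal] %d reports -> %d deduplicated -> %d cases -> %d drugs -> %d signals",
                  summary$reports_read, summary$deduplicated, summary$cases,
                  summary$drugs_with_event, summary$signals))
  invisible(list(ror_table = results, strata = strata, trend = trend,
                 dedup = dd, summary = summary))
}
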
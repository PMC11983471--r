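# Reading and writing FAERS-style quarterly ASCII tables.
#
# FAERS distributes each quarter as dollar-delimited text files with a header
# row (DEMO, DRUG, REAC, OUTC, THER, INDI, RPSR). The readers here map header
# names to one fixed modern schema through an alias table (legacy pre-2014
# headers such as ISR/CASE are renamed, not parsed separately), keep unknown
# columns as extras, and count malformed lines instead of failing on them.

#' Canonical column schemas for FAERS tables
#'
#' @return named list; each element has `required` and `optional` column
#'   names for one table kind.
#' @export
faers_schemas <- function() {
  list(
    demo = list(required = c("primaryid", "caseid", "fda_dt"),
                optional = c("event_dt", "age", "age_cod", "sex",
                             "occp_cod", "occr_country")),
    drug = list(required = c("primaryid", "drug_seq", "drugname"),
                optional = "role_cod"),
    reac = list(required = c("primaryid", "pt"),
                optional = "pt_cod"),
    outc = list(required = c("primaryid", "outc_cod"),
                optional = character()),
    ther = list(required = c("primaryid", "dsg_drug_seq"),
                optional = c("start_dt", "end_dt")),
    indi = list(required = c("primaryid", "indi_drug_seq"),
                optional = "indi_pt"),
    rpsr = list(required = c("primaryid", "rpsr_cod"),
                optional = character())
  )
}

# legacy / variant header names -> canonical names
faers_header_aliases <- function() {
  c(isr = "primaryid", "case" = "caseid", case_num = "caseid",
    gndr_cod = "sex", reporter_country = "occr_country",
    pt_name = "pt", drug_name = "drugname")
}

numeric_faers_cols <- function() {
  c(age = "double", drug_seq = "integer", dsg_drug_seq = "integer",
    indi_drug_seq = "integer", pt_cod = "double")
}

# split delimited lines into fields, preserving trailing empties; lines
# containing the quote character fall back to scan() for quote handling
split_delim_lines <- function(lines, delim, quote) {
  out <- vector("list", length(lines))
  plain <- !grepl(quote, lines, fixed = TRUE)
  if (any(plain)) {
    parts <- strsplit(paste0(lines[plain], delim, "\x01"), delim, fixed = TRUE)
    out[plain] <- lapply(parts, function(p) p[-length(p)])
  }
  for (i in which(!plain)) {
    out[[i]] <- tryCatch(
      scan(text = lines[i], what = character(), sep = delim, quote = quote,
           quiet = TRUE, na.strings = character()),
      error = function(e) character()
    )
  }
  out
}

#' Read one FAERS-style delimited table
#'
#' Parses a dollar-delimited text file with a header row into a data frame.
#' Header names are lowercased and mapped through [faers_header_aliases()];
#' unknown columns are preserved. Lines whose field count does not match the
#' header are skipped and counted in the `malformed` attribute, so that
#' `nrow(result) + attr(result, "malformed")` equals the number of data lines.
#'
#' @param path path to the delimited text file.
#' @param schema one of `"demo"`, `"drug"`, `"reac"`, `"outc"`, `"ther"`,
#'   `"indi"`, `"rpsr"`.
#' @param delim field delimiter, `"$"` in FAERS distributions.
#' @param quote quote character for fields containing the delimiter.
#' @param verbose emit a message when malformed or invalid-encoding lines
#'   are encountered.
#' @return data frame with one row per well-formed data line, in file order.
#'   Attributes: `malformed` (skipped line count), `n_data_lines`,
#'   `encoding_replaced` (lines with invalid UTF-8 bytes replaced).
#' @export
faers_read_table <- function(path, schema, delim = "$", quote = "\"",
                             verbose = FALSE) {
  schemas <- faers_schemas()
  schema <- match.arg(schema, names(schemas))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  bad_enc <- !validUTF8(lines)
  if (any(bad_enc)) {
    lines[bad_enc] <- iconv(lines[bad_enc], "latin1", "UTF-8", sub = "?")
    if (verbose) message(sum(bad_enc), " line(s) had invalid UTF-8 bytes replaced")
  }
  if (length(lines) == 0) stop("file is empty (no header row): ", path)

  header <- split_delim_lines(lines[1], delim, quote)[[1]]
  header <- tolower(trimws(header))
  aliases <- faers_header_aliases()
  hit <- header %in% names(aliases)
  header[hit] <- aliases[header[hit]]

  required <- schemas[[schema]]$required
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    stop("table '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  body <- lines[-1]
  body <- body[nzchar(body)]
  ncol <- length(header)
  fields <- split_delim_lines(body, delim, quote)
  good <- lengths(fields) == ncol
  malformed <- sum(!good)
  if (malformed > 0 && verbose) {
    message(malformed, " malformed line(s) skipped in ", basename(path))
  }
  if (any(good)) {
    m <- matrix(unlist(fields[good], use.names = FALSE), ncol = ncol, byrow = TRUE)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(matrix(character(), ncol = ncol, nrow = 0),
                        stringsAsFactors = FALSE)
  }
  names(df) <- header
  df[] <- lapply(df, function(col) {
    col[!is.na(col) & col == ""] <- NA_character_
    col
  })
  num <- numeric_faers_cols()
  for (nm in intersect(names(num), names(df))) {
    df[[nm]] <- if (num[[nm]] == "integer") {
      suppressWarnings(as.integer(df[[nm]]))
    } else {
      suppressWarnings(as.numeric(df[[nm]]))
    }
  }
  attr(df, "malformed") <- malformed
  attr(df, "n_data_lines") <- length(body)
  attr(df, "encoding_replaced") <- sum(bad_enc)
  attr(df, "schema") <- schema
  df
}

#' Write a record stream as a FAERS-style delimited table
#'
#' Fields containing the delimiter or quote character are quoted (embedded
#' quotes doubled); `NA` is written as the empty field. Output is re-readable
#' by [faers_read_table()] with field equality (empty fields read back as
#' `NA`).
#'
#' @param records data frame of records sharing one schema.
#' @param path output path.
#' @param delim,quote as in [faers_read_table()].
#' @return `path`, invisibly.
#' @export
faers_write_table <- function(records, path, delim = "$", quote = "\"") {
  df <- as.data.frame(records)
  esc <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    needs <- grepl(delim, x, fixed = TRUE) | grepl(quote, x, fixed = TRUE)
    if (any(needs)) {
      x[needs] <- paste0(quote,
                         gsub(quote, paste0(quote, quote), x[needs], fixed = TRUE),
                         quote)
    }
    x
  }
  lines <- if (nrow(df) > 0) {
    do.call(paste, c(lapply(df, esc), list(sep = delim)))
  } else {
    character()
  }
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = delim), lines), con)
  invisible(path)
}

empty_faers_table <- function(schema) {
  sch <- faers_schemas()[[schema]]
  cols <- c(sch$required, sch$optional)
  df <- as.data.frame(matrix(character(), nrow = 0, ncol = length(cols)),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  num <- numeric_faers_cols()
  for (nm in intersect(names(num), cols)) {
    df[[nm]] <- if (num[[nm]] == "integer") integer() else numeric()
  }
  attr(df, "malformed") <- 0L
  attr(df, "n_data_lines") <- 0L
  df
}

#' Read one quarter's FAERS tables from a directory
#'
#' Looks for files named `<TABLE><quarter_label>.txt` (case-insensitive; the
#' source table accepts both `RPSR` and the `PRSP` spelling). DEMO is
#' mandatory — it carries the CASEID/FDA_DT/PRIMARYID triple needed for
#' deduplication; any other absent table yields an empty stream with a
#' warning. primaryids appearing in DRUG/REAC/OUTC/THER/INDI but not in DEMO
#' are counted per table in the `orphans` element (records are kept).
#'
#' @param dir directory containing the quarter's files.
#' @param quarter_label quarter label like `"2004Q1"`.
#' @param delim field delimiter.
#' @return object of class `quarter_bundle`: a list with the quarter label,
#'   one data frame per table (DEMO rows gain a `source_quarter` column),
#'   and named integer vectors `orphans` and `malformed`.
#' @export
faers_read_quarter <- function(dir, quarter_label, delim = "$") {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  stopifnot(grepl("^[0-9]{4}Q[1-4]$", quarter_label))
  find_file <- function(stems) {
    pat <- paste0("^(", paste(stems, collapse = "|"), ")", quarter_label,
                  "\\.txt$")
    hits <- list.files(dir, pattern = pat, ignore.case = TRUE)
    if (length(hits) == 0) return(NULL)
    file.path(dir, hits[1])
  }
  stems <- list(demo = "demo", drug = "drug", reac = "reac", outc = "outc",
                ther = "ther", indi = "indi", rpsr = c("rpsr", "prsp"))
  tables <- list()
  malformed <- integer()
  for (nm in names(stems)) {
    f <- find_file(stems[[nm]])
    if (is.null(f)) {
      if (nm == "demo") {
        stop("DEMO table for quarter ", quarter_label, " not found in ", dir,
             " (DEMO is required for deduplication)")
      }
      warning("no ", toupper(nm), " table for quarter ", quarter_label,
              "; using an empty stream", call. = FALSE)
      tables[[nm]] <- empty_faers_table(nm)
      malformed[nm] <- 0L
    } else {
      tables[[nm]] <- faers_read_table(f, nm, delim = delim)
      malformed[nm] <- attr(tables[[nm]], "malformed")
    }
  }
  tables$demo$source_quarter <- rep(quarter_label, nrow(tables$demo))
  demo_ids <- unique(as.character(tables$demo$primaryid))
  orphans <- vapply(c("drug", "reac", "outc", "ther", "indi", "rpsr"),
                    function(nm) {
                      sum(!as.character(tables[[nm]]$primaryid) %in% demo_ids)
                    }, integer(1))
  structure(c(list(quarter = quarter_label), tables,
              list(orphans = orphans, malformed = malformed)),
            class = "quarter_bundle")
}

#' @export
print.quarter_bundle <- function(x, ...) {
  cat("FAERS quarter bundle", x$quarter, "\n")
  for (nm in c("demo", "drug", "reac", "outc", "ther", "indi", "rpsr")) {
    cat(sprintf("  %-5s %7d records\n", toupper(nm), nrow(x[[nm]])))
  }
  if (any(x$orphans > 0)) {
    cat("  orphan primaryids:",
        paste(names(x$orphans)[x$orphans > 0],
              x$orphans[x$orphans > 0], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert reported age and unit code to years
#'
#' FAERS ages carry a unit code: `YR` years, `DEC` decades, `MON` months,
#' `WK` weeks, `DY` days, `HR` hours. Missing codes are assumed to be years;
#' unparseable combinations give `NA`.
#'
#' @param age numeric age values as reported.
#' @param age_cod character unit codes.
#' @return numeric vector of ages in years.
#' @export
age_to_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(age_cod)))
  cod[is.na(cod) | cod == ""] <- "YR"
  factor_map <- c(YR = 1, YEAR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365,
                  DY = 1 / 365, HR = 1 / 8760)
  f <- factor_map[cod]
  out <- age * as.numeric(f)
  out[is.na(f)] <- NA_real_
  out
}

#' Normalize demographic fields of a DEMO stream
#'
#' Adds derived analysis columns: `age_years` (via [age_to_years()]),
#' `sex` normalized to `F`/`M`/`NA`, `country` uppercased, and `event_year`
#' taken from the event date (first four digits) when present.
#'
#' @param demo data frame from [faers_read_table()] with schema `"demo"`.
#' @return the data frame with normalized/derived columns added.
#' @export
normalize_demo <- function(demo) {
  n <- nrow(demo)
  demo$age_years <- if (all(c("age", "age_cod") %in% names(demo))) {
    age_to_years(demo$age, demo$age_cod)
  } else {
    rep(NA_real_, n)
  }
  sx <- toupper(trimws(as.character(demo$sex %||% rep(NA_character_, n))))
  sx[!sx %in% c("F", "M")] <- NA_character_
  demo$sex <- sx
  demo$occp_cod <- as.character(demo$occp_cod %||% rep(NA_character_, n))
  demo$country <- toupper(trimws(as.character(
    demo$occr_country %||% rep(NA_character_, n))))
  ev <- as.character(demo$event_dt %||% rep(NA_character_, n))
  yr <- suppressWarnings(as.integer(substr(ev, 1, 4)))
  yr[is.na(yr) | yr < 1900 | yr > 2100] <- NA_integer_
  demo$event_year <- yr
  demo
}
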
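# Synthetic FAERS-style data with planted drug-event odds ratios.
#
# Each simulated report draws, independently per drug j, an exposure with
# probability p_j. With baseline event probability q, a report exposed to
# drug j has event probability q*rho_j / (1 - q + q*rho_j), which makes the
# report-level odds ratio of event vs exposure exactly rho_j; reports with
# several exposures use the maximal implied probability (a documented
# simplification — marginal per-drug odds ratios stay ~rho_j while exposure
# probabilities are small). Reports carry demographics, a target preferred
# term for events plus filler terms for realistic reaction multiplicity, and
# outcome codes. File emission injects duplicate case submissions (same
# CASEID, strictly newer FDA_DT, larger PRIMARYID) at rate dup_rate,
# exercising the keep-latest deduplication rule, and writes a ground-truth
# manifest.

#' Default planted drug panel for the synthetic generator
#'
#' Eleven generics with exposure probabilities and planted odds ratios
#' reflecting a plausible kidney-stone reporting mix: strong planted signals
#' for the protease-inhibitor / carbonic-anhydrase-inhibitor analogues,
#' moderate ones for the frequently reported biologics, and two null drugs.
#'
#' @return data frame with columns `generic`, `brand`, `p_drug`, `rho`.
#' @export
synth_drug_defaults <- function() {
  data.frame(
    generic = c("adalimumab", "infliximab", "interferon beta-1a",
                "sodium oxybate", "teriparatide", "atazanavir", "topiramate",
                "lansoprazole", "teduglutide", "metformin", "lisinopril"),
    brand = c("Humira", "Remicade", "Avonex", "Xyrem", "Forteo", "Reyataz",
              "Topamax", "Prevacid", "Gattex", "", ""),
    p_drug = c(0.035, 0.018, 0.012, 0.012, 0.011, 0.004, 0.006, 0.010,
               0.003, 0.030, 0.025),
    rho = c(1.8, 1.8, 2.0, 2.0, 2.3, 33.29, 8.35, 7.20, 5.54, 1.0, 1.0),
    stringsAsFactors = FALSE)
}

#' Default demographic distributions for the synthetic generator
#'
#' Probabilities emulate the marginal composition of kidney-stone case
#' reports in a large spontaneous-reporting database: age bands with a large
#' unknown share, a female majority among known sexes, consumer-heavy
#' reporter mix, US-dominated countries, and hospitalization as the dominant
#' serious outcome. Outcome codes are drawn independently (a report may
#' carry several).
#'
#' @return named list of probability vectors.
#' @export
synth_demographics_defaults <- function() {
  list(
    age_band_probs = c("le17" = 0.0154, "18-65" = 0.4234, "66-85" = 0.1707,
                       "ge86" = 0.0070, unknown = 0.3835),
    sex_probs = c(F = 0.5316, M = 0.3946, unknown = 0.0738),
    reporter_probs = c(MD = 0.06, PH = 0.03, OT = 0.0235, CN = 0.1879,
                       LW = 0.005, unknown = 0.6936),
    country_probs = c(US = 0.3743, CA = 0.0923, BR = 0.0123, GB = 0.0103,
                      DE = 0.0097, OTHER = 0.5011),
    outcome_probs = c(HO = 0.4179, DE = 0.0258, LT = 0.0168, DS = 0.0073,
                      OT = 0.10)
  )
}

default_filler_pts <- function(n = 20) {
  pool <- c("Nausea", "Headache", "Diarrhoea", "Fatigue", "Dizziness",
            "Vomiting", "Rash", "Pyrexia", "Arthralgia", "Dyspnoea",
            "Pruritus", "Insomnia", "Anaemia", "Hypertension",
            "Constipation", "Cough", "Oedema peripheral", "Abdominal pain",
            "Back pain", "Myalgia")
  stopifnot(n >= 1, n <= length(pool))
  pool[seq_len(n)]
}

#' Configuration for the synthetic report generator
#'
#' Validates all probabilities and rates before anything is generated.
#'
#' @param n_reports number of unique case reports.
#' @param quarters quarter labels the reports are spread over.
#' @param drugs data frame with columns `generic`, `p_drug` (per-report
#'   exposure probability) and `rho` (planted report-level odds ratio);
#'   optional `brand` synonyms.
#' @param q baseline event probability for unexposed reports.
#' @param dup_rate fraction of cases re-submitted with a newer receipt date
#'   and larger report id.
#' @param demographics list as in [synth_demographics_defaults()].
#' @param n_filler_pt number of filler preferred terms.
#' @param target_pt,target_pt_code the planted target event term and code.
#' @param seed integer RNG seed; identical seed and config give identical
#'   output bytes.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_reports = 10000,
                         quarters = c("2023Q1", "2023Q2", "2023Q3", "2023Q4"),
                         drugs = synth_drug_defaults(),
                         q = 0.0182,
                         dup_rate = 0.08,
                         demographics = synth_demographics_defaults(),
                         n_filler_pt = 20,
                         target_pt = "Nephrolithiasis",
                         target_pt_code = 10029148,
                         seed = 1L) {
  stopifnot(is.numeric(n_reports), n_reports >= 1)
  if (!all(grepl("^[0-9]{4}Q[1-4]$", quarters))) {
    stop("quarter labels must look like 2004Q1")
  }
  stopifnot(is.data.frame(drugs),
            all(c("generic", "p_drug", "rho") %in% names(drugs)))
  if (!"brand" %in% names(drugs)) drugs$brand <- ""
  if (any(drugs$p_drug < 0 | drugs$p_drug > 1)) {
    stop("exposure probabilities must lie in [0, 1]")
  }
  if (any(drugs$rho <= 0)) stop("planted odds ratios must be positive")
  if (q <= 0 || q >= 1) stop("baseline event probability q must lie in (0, 1)")
  if (dup_rate < 0 || dup_rate > 1) stop("dup_rate must lie in [0, 1]")
  p_implied <- q * drugs$rho / (1 - q + q * drugs$rho)
  if (any(p_implied < 0 | p_implied > 1)) {
    stop("implied event probabilities fall outside [0, 1]")
  }
  for (nm in names(demographics)) {
    pr <- demographics[[nm]]
    if (any(pr < 0) || (nm != "outcome_probs" && abs(sum(pr) - 1) > 1e-6)) {
      stop("demographic probabilities '", nm,
           "' must be non-negative and (except outcomes) sum to 1")
    }
  }
  structure(list(n_reports = as.integer(n_reports), quarters = quarters,
                 drugs = drugs, q = q, dup_rate = dup_rate,
                 demographics = demographics,
                 n_filler_pt = as.integer(n_filler_pt),
                 target_pt = target_pt, target_pt_code = target_pt_code,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# verbatim-name variants emitted for one drug (generic + noisy + brand)
drug_variants <- function(generic, brand) {
  v <- c(generic, toupper(generic), paste(toupper(generic), "40MG"))
  if (nzchar(brand)) v <- c(v, brand, toupper(brand))
  v
}

#' Dictionary covering every verbatim variant the generator emits
#'
#' @param config a `synth_config`.
#' @return data frame suitable for writing and re-reading with
#'   [read_drug_dictionary()] (columns `verbatim`, `generic`, `atc`).
#' @export
synth_dictionary <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  d <- config$drugs
  rows <- lapply(seq_len(nrow(d)), function(j) {
    data.frame(verbatim = drug_variants(d$generic[j], d$brand[j]),
               generic = d$generic[j], atc = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Simulate one synthetic report universe in memory
#'
#' Draws the unique (pre-duplication) reports: demographics, per-drug
#' exposures, the event indicator under the planted odds-ratio model, and
#' the DEMO/DRUG/REAC/OUTC record streams, together with a ground-truth
#' manifest holding per-report truth and per-drug realized 2x2 counts.
#' Duplicate injection and file emission are done by [synth_generate()].
#'
#' @param config a `synth_config`; its `seed` fixes the RNG.
#' @return list of class `synth_universe` with elements `demo`, `drug`,
#'   `reac`, `outc`, `quarter` (per-report quarter assignment) and
#'   `manifest`.
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_reports
  dem <- config$demographics
  drugs <- config$drugs
  k <- nrow(drugs)

  primaryid <- sprintf("1%08d", seq_len(n))
  caseid <- sprintf("2%08d", seq_len(n))
  quarter <- sample(config$quarters, n, replace = TRUE)
  qstart <- quarter_start_date(config$quarters)
  fda_date <- qstart[match(quarter, config$quarters)] +
    (sample.int(90, n, TRUE) - 1L)
  fda_dt <- format(fda_date, "%Y%m%d")
  event_date <- fda_date - (sample.int(61, n, TRUE) - 1L)
  event_dt <- format(event_date, "%Y%m%d")

  ab <- sample(names(dem$age_band_probs), n, TRUE, dem$age_band_probs)
  age_years <- rep(NA_real_, n)
  age_years[ab == "le17"] <- sample(0:17, sum(ab == "le17"), TRUE)
  age_years[ab == "18-65"] <- sample(18:65, sum(ab == "18-65"), TRUE)
  age_years[ab == "66-85"] <- sample(66:85, sum(ab == "66-85"), TRUE)
  age_years[ab == "ge86"] <- sample(86:99, sum(ab == "ge86"), TRUE)
  # a small share of known ages is reported in months to exercise unit codes
  age <- age_years
  age_cod <- ifelse(is.na(age_years), NA_character_, "YR")
  in_months <- !is.na(age_years) & stats::runif(n) < 0.03
  age[in_months] <- age_years[in_months] * 12
  age_cod[in_months] <- "MON"

  sex <- sample(names(dem$sex_probs), n, TRUE, dem$sex_probs)
  sex[sex == "unknown"] <- NA_character_
  occp <- sample(names(dem$reporter_probs), n, TRUE, dem$reporter_probs)
  occp[occp == "unknown"] <- NA_character_
  country <- sample(names(dem$country_probs), n, TRUE, dem$country_probs)

  expo <- matrix(stats::runif(n * k), n, k) <
    matrix(drugs$p_drug, n, k, byrow = TRUE)
  p_implied <- config$q * drugs$rho / (1 - config$q + config$q * drugs$rho)
  pe_mat <- expo * matrix(p_implied, n, k, byrow = TRUE)
  pe <- do.call(pmax, c(as.data.frame(pe_mat), list(0)))
  pe[pe == 0] <- config$q
  event <- stats::runif(n) < pe

  demo <- data.frame(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt,
                     event_dt = event_dt, age = as.character(age),
                     age_cod = age_cod, sex = sex, occp_cod = occp,
                     occr_country = country, stringsAsFactors = FALSE)

  # DRUG stream: one row per (report, drug) exposure, verbatim-name noise
  ridx <- integer(0); gname <- character(0)
  for (j in seq_len(k)) {
    ii <- which(expo[, j])
    if (length(ii) == 0) next
    vs <- drug_variants(drugs$generic[j], drugs$brand[j])
    ridx <- c(ridx, ii)
    gname <- c(gname, vs[sample.int(length(vs), length(ii), TRUE)])
  }
  ord <- order(ridx)
  ridx <- ridx[ord]; gname <- gname[ord]
  cnt <- tabulate(ridx, nbins = n)
  drug_df <- data.frame(primaryid = primaryid[ridx],
                        drug_seq = sequence(cnt[cnt > 0]),
                        drugname = gname,
                        role_cod = sample(c("PS", "SS", "C", "I"),
                                          length(ridx), TRUE,
                                          c(0.5, 0.2, 0.25, 0.05)),
                        stringsAsFactors = FALSE)

  # REAC stream: target PT for events, 1-2 filler PTs for every report
  pool <- default_filler_pts(config$n_filler_pt)
  pool_cod <- 10000000 + seq_along(pool)
  f1 <- sample.int(length(pool), n, TRUE)
  second <- which(stats::runif(n) < 0.4)
  f2 <- sample.int(length(pool), length(second), TRUE)
  ev <- which(event)
  r_ord <- order(c(ev, seq_len(n), second))
  reac <- data.frame(
    primaryid = c(primaryid[ev], primaryid, primaryid[second])[r_ord],
    pt = c(rep(config$target_pt, length(ev)), pool[f1], pool[f2])[r_ord],
    pt_cod = c(rep(config$target_pt_code, length(ev)), pool_cod[f1],
               pool_cod[f2])[r_ord],
    stringsAsFactors = FALSE)

  op <- dem$outcome_probs
  o_idx <- integer(0); o_cod <- character(0)
  for (code in names(op)) {
    ii <- which(stats::runif(n) < op[[code]])
    o_idx <- c(o_idx, ii)
    o_cod <- c(o_cod, rep(code, length(ii)))
  }
  o_ord <- order(o_idx, o_cod)
  outc <- data.frame(primaryid = primaryid[o_idx[o_ord]],
                     outc_cod = o_cod[o_ord], stringsAsFactors = FALSE)

  # ground truth
  n_case <- sum(event)
  tot <- colSums(expo)
  a <- as.integer(colSums(expo & event))
  per_drug <- data.frame(generic = drugs$generic, p_drug = drugs$p_drug,
                         rho = drugs$rho, a = a, b = as.integer(tot) - a,
                         c = n_case - a,
                         d = as.integer(n - tot - (n_case - a)),
                         stringsAsFactors = FALSE)
  per_report <- data.frame(primaryid = primaryid, caseid = caseid,
                           event = event, n_drugs = as.integer(rowSums(expo)),
                           age_band = ab, sex = sex, reporter = occp,
                           country = country,
                           event_year = as.integer(substr(event_dt, 1, 4)),
                           quarter = quarter, stringsAsFactors = FALSE)
  manifest <- list(n_reports = n, case_ids = primaryid[event],
                   per_report = per_report, per_drug = per_drug,
                   target_pt = config$target_pt,
                   target_pt_code = config$target_pt_code,
                   seed = config$seed)
  structure(list(demo = demo, drug = drug_df, reac = reac, outc = outc,
                 quarter = quarter, manifest = manifest),
            class = "synth_universe")
}

#' Generate synthetic FAERS quarter files with injected duplicates
#'
#' Simulates a universe with [simulate_reports()], injects
#' `round(dup_rate * n_reports)` duplicate case submissions — each copies a
#' report's rows under a fresh, numerically larger primaryid with an FDA
#' receipt date 1-90 days later — and writes per-quarter
#' DEMO/DRUG/REAC/OUTC/THER/INDI files parseable by [faers_read_quarter()],
#' plus a `manifest.json` ground-truth file. Identical seed and config give
#' byte-identical output.
#'
#' @param config a `synth_config`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly; its `duplicates` element maps each
#'   re-submitted caseid to the superseded and kept primaryids, and
#'   `expected_kept_primaryids` lists the ids deduplication must recover.
#' @export
synth_generate <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  u <- simulate_reports(config)
  n <- config$n_reports
  demo <- u$demo; drug <- u$drug; reac <- u$reac; outc <- u$outc
  quarter <- u$quarter
  manifest <- u$manifest

  n_dup <- round(config$dup_rate * n)
  if (n_dup > 0) {
    dup_idx <- sample.int(n, n_dup)
    new_pid <- sprintf("1%08d", n + seq_len(n_dup))
    old_pid <- demo$primaryid[dup_idx]
    lag <- sample.int(90, n_dup, TRUE)
    new_dt <- format(as.Date(demo$fda_dt[dup_idx], "%Y%m%d") + lag, "%Y%m%d")

    d_demo <- demo[dup_idx, , drop = FALSE]
    d_demo$primaryid <- new_pid
    d_demo$fda_dt <- new_dt
    demo <- rbind(demo, d_demo)

    remap <- function(tbl) {
      sel <- tbl[tbl$primaryid %in% old_pid, , drop = FALSE]
      if (nrow(sel) == 0) return(tbl)
      sel$primaryid <- new_pid[match(sel$primaryid, old_pid)]
      rbind(tbl, sel)
    }
    drug <- remap(drug); reac <- remap(reac); outc <- remap(outc)
    quarter <- c(quarter, quarter[dup_idx])

    kept <- manifest$per_report$primaryid
    kept[dup_idx] <- new_pid
    manifest$duplicates <- data.frame(
      caseid = demo$caseid[dup_idx], superseded_primaryid = old_pid,
      duplicate_primaryid = new_pid, fda_dt_resubmitted = new_dt,
      stringsAsFactors = FALSE)
    manifest$expected_kept_primaryids <- kept
    # after dedup the resubmitted id survives, so the ground-truth case ids
    # must name the kept report versions
    manifest$case_ids <- kept[manifest$per_report$event]
  } else {
    manifest$duplicates <- data.frame(caseid = character(),
                                      superseded_primaryid = character(),
                                      duplicate_primaryid = character(),
                                      fda_dt_resubmitted = character())
    manifest$expected_kept_primaryids <- manifest$per_report$primaryid
  }
  manifest$expected_demo_rows <- nrow(demo)

  # minimal THER / INDI derived from drug mentions
  ther <- data.frame(primaryid = drug$primaryid,
                     dsg_drug_seq = drug$drug_seq,
                     start_dt = NA_character_, end_dt = NA_character_,
                     stringsAsFactors = FALSE)
  indi <- data.frame(primaryid = drug$primaryid,
                     indi_drug_seq = drug$drug_seq,
                     indi_pt = "Product used for unknown indication",
                     stringsAsFactors = FALSE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  qt_of <- c(stats::setNames(quarter, demo$primaryid))
  rpsr <- data.frame(primaryid = character(), rpsr_cod = character(),
                     stringsAsFactors = FALSE)
  tables <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc,
                 THER = ther, INDI = indi, RPSR = rpsr)
  counts <- list()
  for (q in config$quarters) {
    for (nm in names(tables)) {
      tbl <- tables[[nm]]
      sub <- tbl[qt_of[tbl$primaryid] == q, , drop = FALSE]
      faers_write_table(sub, file.path(out_dir, paste0(nm, q, ".txt")))
      counts[[q]][[tolower(nm)]] <- nrow(sub)
    }
  }
  manifest$table_counts <- counts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(manifest)
}

#' Small packaged hand-checkable fixtures
#'
#' Fixture registry:
#' \describe{
#'   \item{`dedup-ties`}{6 DEMO rows over 3 caseids exercising the
#'     keep-latest rule: a recency decision, a receipt-date tie broken by
#'     the larger primaryid, and a missing receipt date losing to a dated
#'     record. The manifest names the primaryids deduplication must keep.}
#'   \item{`four-cell`}{the 4-report universe \{drug+event\}, \{drug\},
#'     \{event\}, \{\}: its single 2x2 table is a=b=c=d=1.}
#'   \item{`top5-ranking`}{five drugs with case counts in the fixed
#'     proportions 26:13:9:9:8 (65 single-drug case reports), exercising
#'     frequency ranking and the alphabetical tie-break.}
#' }
#'
#' @param name fixture name.
#' @return list with elements `demo`, `drug`, `reac`, `outc` and `manifest`.
#' @export
make_fixture <- function(name) {
  registry <- c("dedup-ties", "four-cell", "top5-ranking")
  if (!is.character(name) || length(name) != 1 || !name %in% registry) {
    stop("unknown fixture; available: ", paste(registry, collapse = ", "))
  }
  empty_outc <- data.frame(primaryid = character(), outc_cod = character(),
                           stringsAsFactors = FALSE)
  if (name == "dedup-ties") {
    demo <- data.frame(
      primaryid = c("1001", "1000", "2000", "2002", "3002", "3001"),
      caseid = c("100", "100", "200", "200", "300", "300"),
      fda_dt = c("20230101", "20230301", "20230301", "20230301", NA,
                 "20220101"),
      stringsAsFactors = FALSE)
    return(list(demo = demo,
                drug = data.frame(primaryid = character(),
                                  drug_seq = integer(),
                                  drugname = character()),
                reac = data.frame(primaryid = character(), pt = character()),
                outc = empty_outc,
                manifest = list(kept_primaryids = c("1000", "2002", "3001"),
                                n_cases = 3L)))
  }
  if (name == "four-cell") {
    demo <- data.frame(primaryid = as.character(1:4),
                       caseid = as.character(11:14),
                       fda_dt = rep("20230101", 4), stringsAsFactors = FALSE)
    drug <- data.frame(primaryid = c("1", "2"), drug_seq = c(1L, 1L),
                       drugname = c("drug d", "drug d"),
                       role_cod = c("PS", "PS"), stringsAsFactors = FALSE)
    reac <- data.frame(primaryid = c("1", "3", "1", "2", "3", "4"),
                       pt = c("Nephrolithiasis", "Nephrolithiasis",
                              "Nausea", "Nausea", "Nausea", "Nausea"),
                       stringsAsFactors = FALSE)
    return(list(demo = demo, drug = drug, reac = reac, outc = empty_outc,
                manifest = list(drug = "drug d", a = 1L, b = 1L, c = 1L,
                                d = 1L)))
  }
  # top5-ranking
  counts <- c("adalimumab" = 26L, "infliximab" = 13L,
              "interferon beta-1a" = 9L, "sodium oxybate" = 9L,
              "teriparatide" = 8L)
  n <- sum(counts)
  pid <- sprintf("%04d", seq_len(n))
  gen <- rep(names(counts), counts)
  demo <- data.frame(primaryid = pid, caseid = paste0("c", pid),
                     fda_dt = "20230101", stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = pid, drug_seq = 1L, drugname = gen,
                     role_cod = "PS", stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = pid, pt = "Nephrolithiasis",
                     stringsAsFactors = FALSE)
  list(demo = demo, drug = drug, reac = reac, outc = empty_outc,
       manifest = list(counts = counts,
                       expected_order = names(counts)))
}
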
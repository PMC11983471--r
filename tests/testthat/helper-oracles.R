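# Independent brute-force oracles and random-fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package paths
# they check).

# per-case argmax under (receipt date, report id): full 8-digit dates compare
# by value, partial/missing dates rank below all full dates; ids compare
# numerically
dedup_oracle_kept <- function(demo) {
  cid <- as.character(demo$caseid)
  ok <- !is.na(cid) & trimws(cid) != ""
  d <- demo[ok, , drop = FALSE]
  date_val <- function(x) {
    if (!is.na(x) && grepl("^[0-9]{8}$", x)) as.numeric(x) else -1
  }
  kept <- vapply(split(seq_len(nrow(d)), as.character(d$caseid)),
                 function(ii) {
                   dv <- vapply(as.character(d$fda_dt[ii]), date_val,
                                numeric(1))
                   pv <- as.numeric(as.character(d$primaryid[ii]))
                   best <- ii[order(dv, pv)][length(ii)]
                   as.character(d$primaryid[best])
                 }, character(1))
  unname(kept)
}

# per-report boolean counting of the 2x2 cells, one drug at a time
contingency_oracle <- function(case_ids, reports, mentions) {
  pids <- as.character(reports$primaryid)
  event <- pids %in% as.character(case_ids)
  gens <- sort(unique(as.character(mentions$generic)))
  rows <- lapply(gens, function(g) {
    has <- pids %in% as.character(mentions$primaryid[mentions$generic == g])
    data.frame(drug = g, a = sum(has & event), b = sum(has & !event),
               c = sum(!has & event), d = sum(!has & !event),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$a >= 1, , drop = FALSE]
}

# log-space arithmetic evaluation of the odds ratio and its Woolf interval
ror_oracle_log <- function(a, b, c, d) {
  lor <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = exp(lor), lo = exp(lor - 1.96 * se), hi = exp(lor + 1.96 * se))
}

# independent route: Wald odds ratio from a weighted binomial GLM
ror_oracle_glm <- function(a, b, c, d) {
  df <- data.frame(event = c(1, 0, 1, 0), drug = c(1, 1, 0, 0),
                   w = c(a, b, c, d))
  fit <- stats::glm(event ~ drug, family = stats::binomial, weights = w,
                    data = df,
                    control = stats::glm.control(epsilon = 1e-14,
                                                 maxit = 100))
  co <- summary(fit)$coefficients["drug", ]
  list(or = exp(co[["Estimate"]]),
       lo = exp(co[["Estimate"]] - 1.96 * co[["Std. Error"]]),
       hi = exp(co[["Estimate"]] + 1.96 * co[["Std. Error"]]))
}

# random DEMO stream with duplicate caseids, partial and missing dates
random_demo <- function(n, n_case_pool, seed) {
  set.seed(seed)
  dates <- format(as.Date("2004-01-01") + sample.int(7000, n, TRUE), "%Y%m%d")
  kind <- sample.int(4, n, TRUE, prob = c(0.85, 0.05, 0.05, 0.05))
  fda <- dates
  fda[kind == 2] <- NA
  fda[kind == 3] <- substr(dates[kind == 3], 1, 4)
  fda[kind == 4] <- substr(dates[kind == 4], 1, 6)
  data.frame(primaryid = as.character(sample.int(10 * n, n)),
             caseid = as.character(sample.int(n_case_pool, n, TRUE)),
             fda_dt = fda, stringsAsFactors = FALSE)
}

# random strictly-positive 2x2 tables
random_tables <- function(n, seed, max_cell = 500) {
  set.seed(seed)
  data.frame(a = sample.int(max_cell, n, TRUE),
             b = sample.int(max_cell, n, TRUE),
             c = sample.int(max_cell, n, TRUE),
             d = sample.int(max_cell, n, TRUE))
}

# one coverage replicate: simulate a universe and push it through the
# case-extraction / drug-normalization / disproportionality stages
ror_replicate <- function(cfg, dict, seed) {
  cfg$seed <- as.integer(seed)
  u <- simulate_reports(cfg)
  dd <- deduplicate(u$demo)
  cs <- extract_cases(dd$reports, u$reac, pt = cfg$target_pt)
  men <- normalize_mentions(u$drug, dict)
  ror(build_contingency(cs, dd$reports, men))
}

# dictionary object for a synth config without touching disk twice
synth_dict <- function(cfg) {
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(synth_dictionary(cfg), tf, row.names = FALSE)
  on.exit(unlink(tf))
  read_drug_dictionary(tf)
}

write_fixture_quarter <- function(fix, dir, quarter = "2023Q1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  faers_write_table(fix$demo, file.path(dir, paste0("DEMO", quarter, ".txt")))
  faers_write_table(fix$drug, file.path(dir, paste0("DRUG", quarter, ".txt")))
  faers_write_table(fix$reac, file.path(dir, paste0("REAC", quarter, ".txt")))
  faers_write_table(fix$outc, file.path(dir, paste0("OUTC", quarter, ".txt")))
  dir
}
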
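# Descriptive stratifications: age bands, the half-up percentage
# convention, stratum tables and the yearly trend.

test_that("age bands partition [0, Inf) with the stated boundaries", {
  expect_equal(band_age(c(0, 17.9, 18, 65, 65.9, 66, 85.9, 86, 120)),
               c("≤17", "≤17", "18-65", "18-65", "18-65",
                 "66-85", "66-85", "≥86", "≥86"))
  expect_equal(band_age(NA), "unknown")
  expect_warning(b <- band_age(-3), "negative")
  expect_equal(b, "unknown")
})

test_that("percentages round half-up to two decimals", {
  expect_equal(percentage(16219, 38307), 42.34)
  expect_equal(percentage(6540, 38307), 17.07)
  expect_equal(percentage(0, 38307), 0)
  # half-up, where banker's rounding would differ
  expect_equal(round_half_up(0.695, 2), 0.70)
  expect_equal(percentage(139, 20000), 0.70)  # 0.695% exactly
  expect_error(percentage(1, 0), "positive")
  expect_error(percentage(-1, 10), "non-negative")
})

make_case_set <- function(demo, reac_pt = "Nephrolithiasis") {
  reac <- data.frame(primaryid = demo$primaryid, pt = reac_pt)
  extract_cases(normalize_demo(demo), reac, pt = "nephrolithiasis")
}

test_that("single-valued strata cover all cases and sum to ~100%", {
  cfg <- synth_config(n_reports = 3000, quarters = "2022Q1", seed = 12)
  u <- simulate_reports(cfg)
  dd <- deduplicate(normalize_demo(u$demo))
  cs <- extract_cases(dd$reports, u$reac, pt = cfg$target_pt)
  for (dim in c("age", "sex", "reporter", "country", "year")) {
    st <- stratify(cs, dim)
    expect_equal(sum(st$count), length(cs$case_ids))
    expect_lt(abs(sum(st$percent) - 100), 0.05)
  }
})

test_that("stratum counts equal the generator's ground truth", {
  cfg <- synth_config(n_reports = 3000, quarters = "2022Q1", seed = 12)
  u <- simulate_reports(cfg)
  dd <- deduplicate(normalize_demo(u$demo))
  cs <- extract_cases(dd$reports, u$reac, pt = cfg$target_pt)
  truth <- u$manifest$per_report[u$manifest$per_report$event, ]

  st_sex <- stratify(cs, "sex")
  expect_equal(st_sex$count[st_sex$stratum == "F"],
               sum(truth$sex == "F", na.rm = TRUE))
  expect_equal(st_sex$count[st_sex$stratum == "unknown"],
               sum(is.na(truth$sex)))

  band_map <- c(le17 = "≤17", "18-65" = "18-65", "66-85" = "66-85",
                ge86 = "≥86", unknown = "unknown")
  st_age <- stratify(cs, "age")
  for (b in unique(truth$age_band)) {
    expect_equal(st_age$count[st_age$stratum == band_map[[b]]],
                 sum(truth$age_band == b))
  }
})

test_that("all-missing sex collapses into one unknown stratum", {
  demo <- data.frame(primaryid = as.character(1:10),
                     caseid = as.character(1:10), fda_dt = "20230101")
  cs <- make_case_set(demo)
  st <- stratify(cs, "sex")
  expect_equal(st$stratum, "unknown")
  expect_equal(st$count, 10)
  expect_equal(st$percent, 100)
})

test_that("the outcome dimension counts case-outcome pairs", {
  demo <- data.frame(primaryid = as.character(1:4),
                     caseid = as.character(1:4), fda_dt = "20230101")
  cs <- make_case_set(demo)
  outc <- data.frame(primaryid = rep(as.character(1:4), each = 2),
                     outc_cod = rep(c("HO", "DE"), 4))
  st <- stratify(cs, "outcome", outcomes = outc)
  expect_setequal(st$count, c(4, 4))  # both strata equal the case count
  expect_equal(sum(st$count), 8)     # multi-valued: exceeds total cases
})

test_that("unknown dimensions are rejected", {
  demo <- data.frame(primaryid = "1", caseid = "1", fda_dt = "20230101")
  cs <- make_case_set(demo)
  expect_error(stratify(cs, "zodiac"), "unknown dimension")
})

test_that("yearly trend counts by event year with receipt-date fallback", {
  demo <- data.frame(primaryid = as.character(1:4),
                     caseid = as.character(1:4),
                     fda_dt = c("20040601", "20050601", "20060601",
                                "20060701"),
                     event_dt = c("20040101", "20050101", "20060101", NA))
  cs <- make_case_set(demo)
  tr <- yearly_trend(cs)
  expect_equal(tr$year, c("2004", "2005", "2006"))
  expect_equal(tr$count, c(1, 1, 2))  # the NA event date falls back to fda_dt
})

test_that("an empty case set yields an empty trend", {
  demo <- data.frame(primaryid = "1", caseid = "1", fda_dt = "20230101")
  reac <- data.frame(primaryid = "1", pt = "Nausea")
  cs <- extract_cases(normalize_demo(demo), reac, pt = "nephrolithiasis")
  expect_equal(nrow(yearly_trend(cs)), 0)
  expect_equal(nrow(stratify(cs, "sex")), 0)
})
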
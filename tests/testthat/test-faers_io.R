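# FAERS table reading/writing: round trips, malformed-line accounting,
# header aliases, quarter bundles, age/date normalization.

demo_fixture <- function() {
  data.frame(primaryid = c("101", "102", "103"),
             caseid = c("11", "12", "13"),
             fda_dt = c("20230105", "20230210", NA),
             age = c("45", NA, "30"),
             age_cod = c("YR", NA, "YR"),
             sex = c("F", "M", NA),
             stringsAsFactors = FALSE)
}

test_that("write then read reproduces every field, in order", {
  tf <- tempfile(fileext = ".txt")
  df <- demo_fixture()
  faers_write_table(df, tf)
  back <- faers_read_table(tf, "demo")
  expect_equal(back$primaryid, df$primaryid)
  expect_equal(back$caseid, df$caseid)
  expect_equal(back$fda_dt, df$fda_dt)
  expect_equal(back$age, as.numeric(df$age))
  expect_equal(back$sex, df$sex)
  expect_identical(attr(back, "malformed"), 0L)
})

test_that("fields containing the delimiter survive a round trip", {
  tf <- tempfile(fileext = ".txt")
  df <- data.frame(primaryid = "1", drug_seq = 1L,
                   drugname = "ASPIRIN $ CAFFEINE", stringsAsFactors = FALSE)
  faers_write_table(df, tf)
  back <- faers_read_table(tf, "drug")
  expect_equal(back$drugname, "ASPIRIN $ CAFFEINE")
})

test_that("header-only files give an empty stream with zero malformed", {
  tf <- tempfile(fileext = ".txt")
  writeLines("primaryid$caseid$fda_dt", tf)
  back <- faers_read_table(tf, "demo")
  expect_equal(nrow(back), 0)
  expect_identical(attr(back, "malformed"), 0L)
})

test_that("short lines are skipped and counted; records are conserved", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$fda_dt",
               "1$11$20230101",
               "2$12",                # too few fields
               "3$13$20230301",
               "4$14$20230401"), tf)
  back <- faers_read_table(tf, "demo")
  expect_equal(nrow(back), 3)
  expect_identical(attr(back, "malformed"), 1L)
  expect_equal(nrow(back) + attr(back, "malformed"), attr(back, "n_data_lines"))
  expect_equal(back$primaryid, c("1", "3", "4"))  # order-preserving
})

test_that("missing files and missing required columns raise named errors", {
  expect_error(faers_read_table(tempfile(), "demo"), "not found")
  tf <- tempfile(fileext = ".txt")
  writeLines(c("primaryid$fda_dt", "1$20230101"), tf)
  expect_error(faers_read_table(tf, "demo"), "caseid")
})

test_that("legacy ISR/CASE headers map onto the modern schema", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c("ISR$CASE$FDA_DT$GNDR_COD", "900$90$20100101$F"), tf)
  back <- faers_read_table(tf, "demo")
  expect_equal(back$primaryid, "900")
  expect_equal(back$caseid, "90")
  expect_equal(back$sex, "F")
})

test_that("unknown columns are preserved as extras", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$fda_dt$mfr_sndr", "1$11$20230101$ACME"), tf)
  back <- faers_read_table(tf, "demo")
  expect_equal(back$mfr_sndr, "ACME")
})

test_that("a generated quarter reads back with manifest record counts", {
  cfg <- synth_config(n_reports = 400, quarters = "2021Q2", seed = 7)
  dir <- tempfile()
  m <- synth_generate(cfg, dir)
  b <- faers_read_quarter(dir, "2021Q2")
  expect_equal(nrow(b$demo), m$table_counts[["2021Q2"]]$demo)
  expect_equal(nrow(b$drug), m$table_counts[["2021Q2"]]$drug)
  expect_equal(nrow(b$reac), m$table_counts[["2021Q2"]]$reac)
  expect_equal(nrow(b$outc), m$table_counts[["2021Q2"]]$outc)
  expect_equal(unname(b$orphans), rep(0L, length(b$orphans)))
  expect_equal(unique(b$demo$source_quarter), "2021Q2")
})

test_that("a DEMO-only directory yields empty streams with warnings", {
  dir <- tempfile(); dir.create(dir)
  faers_write_table(demo_fixture(), file.path(dir, "DEMO2020Q1.txt"))
  expect_warning(b <- faers_read_quarter(dir, "2020Q1"), "DRUG")
  expect_equal(nrow(b$demo), 3)
  expect_equal(nrow(b$drug), 0)
  expect_equal(nrow(b$reac), 0)
})

test_that("a quarter without DEMO is an error naming the requirement", {
  dir <- tempfile(); dir.create(dir)
  faers_write_table(data.frame(primaryid = "1", pt = "Nausea"),
                    file.path(dir, "REAC2020Q1.txt"))
  expect_error(suppressWarnings(faers_read_quarter(dir, "2020Q1")), "DEMO")
})

test_that("age unit codes convert to years; junk gives NA", {
  expect_equal(age_to_years(c(45, 6, 4, 730, 18, 40),
                            c("YR", "MON", "DEC", "DY", NA, "XX")),
               c(45, 0.5, 40, 2, 18, NA))
})

test_that("normalize_demo derives age_years, sex, country and event_year", {
  demo <- data.frame(primaryid = "1", caseid = "2", fda_dt = "20230101",
                     event_dt = "20221115", age = "24", age_cod = "MON",
                     sex = "f", occp_cod = "MD", occr_country = "us",
                     stringsAsFactors = FALSE)
  nd <- normalize_demo(demo)
  expect_equal(nd$age_years, 2)
  expect_equal(nd$sex, "F")
  expect_equal(nd$country, "US")
  expect_equal(nd$event_year, 2022L)
})
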
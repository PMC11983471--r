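# Contingency construction, the reporting odds ratio with its Woolf
# interval, the signal rule, ranking, and label-gap flagging.

test_that("the four-cell universe gives a = b = c = d = 1", {
  fix <- make_fixture("four-cell")
  dd <- deduplicate(fix$demo)
  cs <- extract_cases(dd$reports, fix$reac, pt = "nephrolithiasis")
  mentions <- data.frame(primaryid = fix$drug$primaryid,
                         generic = fix$drug$drugname)
  ct <- build_contingency(cs, dd$reports, mentions)
  expect_equal(ct[ct$drug == "drug d", c("a", "b", "c", "d")],
               data.frame(a = 1L, b = 1L, c = 1L, d = 1L),
               ignore_attr = TRUE)
})

test_that("a drug listed twice in one report contributes once to a", {
  reports <- data.frame(primaryid = c("1", "2"), caseid = c("11", "12"),
                        fda_dt = "20230101")
  cs_ids <- "1"
  mentions <- data.frame(primaryid = c("1", "1", "2"),
                         generic = c("x", "x", "x"))
  ct <- build_contingency(cs_ids, reports, mentions)
  expect_equal(ct$a, 1L)
  expect_equal(ct$b, 1L)
})

test_that("mismatched universes raise an error", {
  reports <- data.frame(primaryid = "1", caseid = "11", fda_dt = "20230101")
  mentions <- data.frame(primaryid = "1", generic = "x")
  expect_error(build_contingency(c("1", "999"), reports, mentions),
               "mismatched")
})

test_that("contingency tables equal brute-force counting on 10^4 reports", {
  cfg <- synth_config(n_reports = 10000, quarters = "2022Q3", seed = 5)
  u <- simulate_reports(cfg)
  dd <- deduplicate(u$demo)
  cs <- extract_cases(dd$reports, u$reac, pt = cfg$target_pt)
  men <- normalize_mentions(u$drug, synth_dict(cfg))
  ct <- build_contingency(cs, dd$reports, men)
  oracle <- contingency_oracle(cs$case_ids, dd$reports, men)
  expect_equal(ct[, c("drug", "a", "b", "c", "d")], oracle,
               ignore_attr = TRUE)
  # marginals
  expect_true(all(ct$a + ct$c == length(cs$case_ids)))
  expect_true(all(ct$a + ct$b + ct$c + ct$d == nrow(dd$reports)))
})

test_that("worked ROR examples reproduce", {
  r1 <- ror(data.frame(a = 1, b = 1, c = 1, d = 1))
  expect_equal(r1$ror, 1)
  expect_false(r1$signal)  # balanced table: lower bound < 1

  r2 <- ror(data.frame(a = 10, b = 90, c = 100, d = 9900))
  expect_equal(round_half_up(r2$ror, 2), 11.00)
  expect_equal(round_half_up(r2$ci_low, 2), 5.56)
  expect_equal(round_half_up(r2$ci_high, 2), 21.76)
  expect_true(r2$signal)
})

test_that("the signal rule needs a >= 3 and a CI lower bound above 1", {
  # a = 3 with lower bound just above 1 -> signal
  r3 <- ror(data.frame(a = 3, b = 120, c = 160, d = 60000))
  expect_true(r3$ci_low > 1)
  expect_true(r3$signal)
  # same disproportion but a = 2 -> never a signal
  r2 <- ror(data.frame(a = 2, b = 80, c = 107, d = 40000))
  expect_false(r2$signal)
})

test_that("zero cells are undefined unless continuity-corrected", {
  off <- ror(data.frame(a = 5, b = 0, c = 3, d = 100))
  expect_true(off$undefined)
  expect_true(is.na(off$ror))
  expect_false(off$signal)

  on <- ror(data.frame(a = 5, b = 0, c = 3, d = 100), continuity = "on")
  expect_true(on$corrected)
  expect_false(on$undefined)
  expect_equal(on$ror, (5.5 * 100.5) / (0.5 * 3.5))
  # already-positive tables are untouched by the correction
  both <- ror(data.frame(a = c(5, 5), b = c(0, 2), c = c(3, 3),
                         d = c(100, 100)), continuity = "on")
  expect_equal(both$corrected, c(TRUE, FALSE))
  expect_equal(both$ror[2], (5 * 100) / (2 * 3))
})

test_that("ROR matches independent log-space and GLM evaluations", {
  tabs <- random_tables(120, seed = 99)
  res <- ror(tabs)
  for (i in seq_len(nrow(tabs))) {
    o <- ror_oracle_log(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(res$ror[i], o$or, tolerance = 1e-9)
    expect_equal(res$ci_low[i], o$lo, tolerance = 1e-9)
    expect_equal(res$ci_high[i], o$hi, tolerance = 1e-9)
  }
  for (i in 1:15) {  # independent route, looser numerical agreement
    g <- ror_oracle_glm(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i])
    expect_equal(res$ror[i], g$or, tolerance = 1e-6)
    expect_equal(res$ci_low[i], g$lo, tolerance = 1e-6)
    expect_equal(res$ci_high[i], g$hi, tolerance = 1e-6)
  }
})

test_that("ROR is log-symmetric, inversion-symmetric and cell-monotone", {
  tabs <- random_tables(60, seed = 7)
  res <- ror(tabs)
  # point estimate is the geometric mean of the CI bounds
  expect_equal(res$ror, sqrt(res$ci_low * res$ci_high), tolerance = 1e-9)
  # swapping (a<->c, b<->d) inverts the ROR and mirrors the CI
  swapped <- ror(data.frame(a = tabs$c, b = tabs$d, c = tabs$a, d = tabs$b))
  expect_equal(swapped$ror, 1 / res$ror, tolerance = 1e-9)
  expect_equal(swapped$ci_low, 1 / res$ci_high, tolerance = 1e-9)
  expect_equal(swapped$ci_high, 1 / res$ci_low, tolerance = 1e-9)
  # strict monotonicity in each cell
  base <- data.frame(a = 10, b = 20, c = 30, d = 40)
  r0 <- ror(base)$ror
  expect_gt(ror(transform(base, a = a + 1))$ror, r0)
  expect_gt(ror(transform(base, d = d + 1))$ror, r0)
  expect_lt(ror(transform(base, b = b + 1))$ror, r0)
  expect_lt(ror(transform(base, c = c + 1))$ror, r0)
})

test_that("ranking is by descending a with alphabetical tie-break", {
  res <- data.frame(drug = c("x", "y", "z"), a = c(5, 9, 5))
  expect_equal(rank_drugs(res, 2)$drug, c("y", "x"))
  expect_equal(rank_drugs(res, 10)$drug, c("y", "x", "z"))
  expect_error(rank_drugs(res, 0))
})

test_that("the top5-ranking fixture reproduces the expected order", {
  fix <- make_fixture("top5-ranking")
  dd <- deduplicate(fix$demo)
  cs <- extract_cases(dd$reports, fix$reac, pt = "nephrolithiasis")
  mentions <- data.frame(primaryid = fix$drug$primaryid,
                         generic = fix$drug$drugname)
  ct <- build_contingency(cs, dd$reports, mentions)
  ranked <- rank_drugs(ct, 5)
  expect_equal(ranked$drug, fix$manifest$expected_order)
  expect_equal(ranked$a, unname(fix$manifest$counts))
})

test_that("label gaps split signals into known risks and new signals", {
  res <- data.frame(drug = letters[1:6],
                    signal = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  risk <- data.frame(generic = c("a", "b", "f"),
                     risk_on_label = c(TRUE, TRUE, TRUE))
  out <- flag_label_gaps(res, risk)
  expect_equal(sum(out$label_status == "known-risk"), 2)
  expect_equal(sum(out$label_status == "potential-new-signal"), 3)
  expect_equal(out$label_status[out$drug == "f"], "no-signal")
  counts <- attr(out, "label_gap_counts")
  expect_equal(unname(counts["potential_new_signal"]), 3)
})
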
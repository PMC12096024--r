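test_that("instrument definitions carry the 30/40/30 and 5x20 structures", {
  p <- instrument_definition("PERSONALIZATION")
  expect_equal(unname(p$dimensions),
               c(30, 40, 30))
  expect_equal(p$total_max, 100)
  for (inst in c("COMPREHENSIVENESS", "SAFETY")) {
    d <- instrument_definition(inst)
    expect_length(d$dimensions, 5)
    expect_true(all(d$dimensions == 20))
    expect_equal(sum(d$dimensions), 100)
  }
})

test_that("sheet validation itemizes missing, non-integer and out-of-range points", {
  ok <- make_sheet(c(relevance = 25, individual_relevance = 35,
                     detail_level = 28))
  expect_true(validate_sheet(ok)$valid)
  over <- make_sheet(c(relevance = 31, individual_relevance = 35,
                       detail_level = 28))
  v <- validate_sheet(over)
  expect_false(v$valid)
  expect_match(v$problems, "relevance = 31", all = FALSE)
  frac <- make_sheet(c(relevance = 12.5, individual_relevance = 35,
                       detail_level = 28))
  expect_false(validate_sheet(frac)$valid)
  missing_dim <- score_sheet("D1", "SAFETY", "R1",
                             c(medication_treatment = 10,
                               nonmedication_treatment = 10,
                               lifestyle_advice = 10,
                               psychological_support = 10))
  v2 <- validate_sheet(missing_dim)
  expect_false(v2$valid)
  expect_match(v2$problems, "disease_management", all = FALSE)
})

test_that("totals sum dimensions and respect the 100-point bounds", {
  expect_equal(sheet_total(make_sheet(c(relevance = 25,
                                        individual_relevance = 35,
                                        detail_level = 28))), 88)
  expect_equal(sheet_total(make_sheet(c(relevance = 0,
                                        individual_relevance = 0,
                                        detail_level = 0))), 0)
  expect_equal(sheet_total(make_sheet(c(relevance = 30,
                                        individual_relevance = 40,
                                        detail_level = 30))), 100)
  expect_error(sheet_total(make_sheet(c(relevance = 31,
                                        individual_relevance = 40,
                                        detail_level = 30))), "invalid")
})

test_that("the adjudication trigger is strictly more-than-threshold", {
  r1 <- make_sheet(c(relevance = 20, individual_relevance = 40,
                     detail_level = 10))
  r2 <- make_sheet(c(relevance = 20, individual_relevance = 29,
                     detail_level = 20), rater = "R2")
  # diffs: 0, 11, 10 -> only the 11-point gap is flagged
  expect_equal(needs_adjudication(r1, r2), "individual_relevance")
  expect_equal(needs_adjudication(r1, r1), character(0))
  other_doc <- make_sheet(c(relevance = 20, individual_relevance = 40,
                            detail_level = 10), doc = "D2")
  expect_error(needs_adjudication(r1, other_doc), "different")
})

test_that("final scores mean agreeing dimensions and median flagged ones", {
  r1 <- make_sheet(c(relevance = 18, individual_relevance = 40,
                     detail_level = 20))
  r2 <- make_sheet(c(relevance = 20, individual_relevance = 29,
                     detail_level = 20), rater = "R2")
  r3 <- make_sheet(c(relevance = 19, individual_relevance = 38,
                     detail_level = 21), rater = "R3")
  fs <- final_score(r1, r2, r3)
  expect_equal(unname(fs$points["relevance"]), 19)     # mean of 18, 20
  expect_equal(unname(fs$points["individual_relevance"]), 38)  # median 40,29,38
  expect_equal(fs$flagged, "individual_relevance")
  expect_equal(fs$total, 19 + 38 + 20)
  # idempotence: three identical raters return the sheet unchanged
  same <- final_score(r1, make_sheet(r1$points, rater = "R2"),
                      make_sheet(r1$points, rater = "R3"))
  expect_equal(same$points, r1$points)
  # unresolved flag without r3 or consensus is an error
  expect_error(final_score(r1, r2), "third rater")
  fs2 <- final_score(r1, r2, resolution = "CONSENSUS_VALUE",
                     consensus = c(individual_relevance = 35))
  expect_equal(unname(fs2$points["individual_relevance"]), 35)
})

test_that("adjudication is exhaustively correct on a small score grid", {
  # single-dimension grid: every (r1, r2, r3) combination on 0..20 by 5s,
  # with a 20-point dimension and threshold 10
  grid <- seq(0, 20, by = 5)
  for (a in grid) for (b in grid) for (c3 in grid) {
    r1 <- score_sheet("D", "SAFETY", "R1",
                      c(medication_treatment = a, nonmedication_treatment = 0,
                        lifestyle_advice = 0, psychological_support = 0,
                        disease_management = 0))
    r2 <- score_sheet("D", "SAFETY", "R2",
                      c(medication_treatment = b, nonmedication_treatment = 0,
                        lifestyle_advice = 0, psychological_support = 0,
                        disease_management = 0))
    r3 <- score_sheet("D", "SAFETY", "R3",
                      c(medication_treatment = c3, nonmedication_treatment = 0,
                        lifestyle_advice = 0, psychological_support = 0,
                        disease_management = 0))
    flagged <- needs_adjudication(r1, r2)
    expect_equal(length(flagged) > 0, abs(a - b) > 10)
    fs <- final_score(r1, r2, r3)
    got <- unname(fs$points["medication_treatment"])
    if (abs(a - b) > 10) {
      expect_equal(got, median(c(a, b, c3)))
      expect_gte(got, min(a, b, c3))
      expect_lte(got, max(a, b, c3))
    } else {
      expect_equal(got, (a + b) / 2)
    }
    # rater-order invariance across all 2 x 1 primary orderings and r3 fixed
    fs_swapped <- final_score(r2, r1, r3)
    expect_equal(fs_swapped$points, fs$points)
    expect_gte(fs$total, 0)
    expect_lte(fs$total, 100)
  }
})

test_that("long-format adjudication reproduces per-sheet final scores", {
  ratings <- data.frame(
    doc_id = "D1", instrument = "PERSONALIZATION",
    rater_id = rep(c("R1", "R2", "R3"), each = 3),
    dimension = rep(c("relevance", "individual_relevance", "detail_level"), 3),
    points = c(18, 40, 20, 20, 29, 20, 19, 38, 21))
  adj <- adjudicate_ratings(ratings)
  expect_equal(adj$final_points[adj$dimension == "individual_relevance"], 38)
  expect_equal(adj$adjudication_flag,
               adj$dimension == "individual_relevance")
  tot <- rubric_totals(adj)
  expect_equal(tot$total, 77)
  expect_error(adjudicate_ratings(ratings[ratings$rater_id == "R1", ]),
               "fewer than 2")
})
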
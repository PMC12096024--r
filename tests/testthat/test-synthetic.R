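test_that("generated text round-trips its ledger through the tokenizer", {
  set.seed(202)
  for (i in 1:200) {
    g <- generate_text(sample(2:12, 1), sample(3:14, 1), runif(1, 1.05, 2.6))
    rt <- compute_token_stats(g$text)
    expect_identical(unclass(rt), unclass(g$stats))
  }
})

test_that("ledgered text is an oracle for the readability formulas", {
  g <- generate_text(10, 10, 1.5, seed = 1)
  expect_equal(g$stats$n_words, 100)
  expect_equal(g$stats$n_syllables, 150)
  expect_equal(flesch_kincaid_grade(g$stats), 6.01)
  mono <- generate_text(10, 8, 1, seed = 2)
  expect_equal(mono$stats$n_polysyllables, 0)
  expect_equal(suppressWarnings(smog_index(mono$stats)), 3.1291)
})

test_that("text generation is seed-deterministic with ledger-stable reshuffles", {
  a <- generate_text(6, 9, 1.7, seed = 33)
  b <- generate_text(6, 9, 1.7, seed = 33)
  c2 <- generate_text(6, 9, 1.7, seed = 34)
  expect_identical(a$text, b$text)
  expect_false(identical(a$text, c2$text))
  expect_identical(unclass(a$stats)[c("n_sentences", "n_words", "n_syllables")],
                   unclass(c2$stats)[c("n_sentences", "n_words", "n_syllables")])
})

test_that("unsatisfiable syllable targets are rejected", {
  expect_error(generate_text(5, 5, 20), "unsatisfiable")
  expect_error(generate_text(5, 5, 0.5), "unsatisfiable")
})

test_that("generated guideline tables span weight classes and reproduce by seed", {
  tab <- generate_guideline_table(12, seed = 5)
  expect_setequal(unique(tab$weight), c(1, 0.75, 0.5, 0.25))
  expect_identical(tab, generate_guideline_table(12, seed = 5))
  single <- generate_guideline_table(1, seed = 1)
  expect_equal(nrow(single), 1)
  expect_true(single$consensus_n >= 1)
})

test_that("noise-free raters reproduce the truth and never trigger adjudication", {
  truth <- make_sheet(c(relevance = 20, individual_relevance = 30,
                        detail_level = 15), rater = "TRUTH")
  rr <- simulate_raters(truth, noise_sd = 0, p_disagreement = 0, seed = 1)
  expect_equal(rr$r1$points, truth$points)
  expect_equal(rr$r2$points, truth$points)
  expect_equal(needs_adjudication(rr$r1, rr$r2), character(0))
})

test_that("forced disagreement always flags at least one dimension", {
  truth <- make_sheet(c(relevance = 15, individual_relevance = 20,
                        detail_level = 15), rater = "TRUTH")
  set.seed(7)
  for (i in 1:25) {
    rr <- simulate_raters(truth, noise_sd = 2, p_disagreement = 1)
    expect_gt(length(needs_adjudication(rr$r1, rr$r2)), 0)
  }
})

test_that("simulated raters are unbiased around the truth", {
  truth <- make_sheet(c(relevance = 15, individual_relevance = 20,
                        detail_level = 15), rater = "TRUTH")
  set.seed(99)
  tot <- replicate(1000, {
    rr <- simulate_raters(truth, noise_sd = 2, p_disagreement = 0)
    sheet_total(rr$r1)
  })
  expect_equal(mean(tot), 50, tolerance = 0.02)  # MC error ~0.1 points
})

test_that("a 50-profile cohort yields 100 documents with coherent files", {
  co <- generate_cohort(cohort_config(n_profiles = 50, seed = 17))
  expect_equal(nrow(co$documents), 100)
  expect_equal(length(unique(co$documents$profile_id)), 50)
  expect_setequal(unique(co$documents$arm), c("AI", "CLIN"))
  expect_true(all(co$documents$authoring_minutes > 0))
  expect_true(all(co$mentions$treatment_id %in% co$guidelines$treatment_id))
  expect_true(all(co$ratings$doc_id %in% co$documents$doc_id))
  # ledger matches retokenization for a sample of documents
  for (k in sample(nrow(co$documents), 5)) {
    expect_identical(unclass(compute_token_stats(co$documents$text[k])),
                     unclass(co$ledgers[[co$documents$doc_id[k]]]))
  }
})

test_that("cohorts are byte-identical under the same seed", {
  a <- generate_cohort(cohort_config(n_profiles = 4, seed = 23))
  b <- generate_cohort(cohort_config(n_profiles = 4, seed = 23))
  expect_identical(a$documents, b$documents)
  expect_identical(a$guidelines, b$guidelines)
  expect_identical(a$mentions, b$mentions)
  expect_identical(a$ratings, b$ratings)
  c2 <- generate_cohort(cohort_config(n_profiles = 4, seed = 24))
  expect_false(identical(a$documents$text, c2$documents$text))
})

test_that("cohort files survive a write/read round trip", {
  co <- generate_cohort(cohort_config(n_profiles = 3, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  docs <- read_docs_jsonl(paths[["docs"]])
  expect_equal(docs$doc_id, co$documents$doc_id)
  expect_equal(docs$text, co$documents$text)
  expect_equal(docs$authoring_minutes, co$documents$authoring_minutes)
  tab <- read_guidelines(paths[["guidelines"]])
  expect_equal(tab$weighted_score, co$guidelines$weighted_score)
})

test_that("configured arm effects are recovered by the pipeline's arm differences", {
  set.seed(61)
  tab <- generate_guideline_table(12, seed = 61)
  acc <- simulate_accuracy_pairs(tab, 400, delta = 0.5)
  expect_equal(mean(acc$acc_ai - acc$acc_clin), 0.5, tolerance = 0.1)
  rec <- estimate_recovery_rubric(n_reps = 40, n_pairs = 30, delta = 10,
                                  seed = 8)
  expect_equal(rec$mean_recovered_delta, 10, tolerance = 4 * rec$mc_se + 0.5)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_profiles = 1), "n_profiles")
  expect_error(cohort_config(rater_noise_sd = -1), "rater_noise_sd")
  expect_error(cohort_config(p_disagreement = 1.5), "p_disagreement")
})
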
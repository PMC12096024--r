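test_that("syllable counting follows the heuristic plus exception table", {
  expect_equal(count_syllables("a"), 1)
  expect_equal(count_syllables("knee"), 1)
  expect_equal(count_syllables("osteoarthritis"), 6)
  expect_equal(count_syllables("table"), 2)       # consonant + le keeps the e
  expect_equal(count_syllables("brace"), 1)       # silent trailing e
  expect_equal(count_syllables("Exercise"), 3)    # case-insensitive
  expect_equal(count_syllables("self-care"), 2)   # parts summed
  expect_error(count_syllables("123"), "alphabetic")
  # a user-supplied exception overrides the heuristic
  expect_equal(count_syllables("knee", exceptions = c(knee = 4L)), 4)
})

test_that("token statistics match a hand count on a known sentence pair", {
  st <- compute_token_stats("The knee hurts. Rest it.")
  expect_equal(st$n_sentences, 2)
  expect_equal(st$n_words, 5)
  expect_equal(st$n_syllables, 5)
  expect_equal(st$n_polysyllables, 0)
  expect_equal(st$n_complex, 0)
  expect_equal(st$n_letters, 18)  # 3 + 4 + 5 + 4 + 2
})

test_that("segmentation guards abbreviations, decimals and lowercase continuations", {
  expect_equal(compute_token_stats("Dr. Smith rested.")$n_sentences, 1)
  expect_equal(compute_token_stats("Take 1.5 tablets daily.")$n_sentences, 1)
  expect_equal(compute_token_stats("Walk daily. E.g. after lunch, rest.")$n_sentences, 2)
  expect_equal(compute_token_stats("Rest. then walk.")$n_sentences, 1)
  expect_equal(compute_token_stats("Rest! Walk? Sleep.")$n_sentences, 3)
  expect_equal(compute_token_stats("One word")$n_sentences, 1)
})

test_that("complex words exclude proper-noun proxies and hyphenated compounds", {
  # "exercise" complex; "Medication" mid-sentence capitalized -> excluded;
  # "anti-inflammatory" hyphenated -> excluded; all three are polysyllables
  st <- compute_token_stats("Do exercise with Medication and anti-inflammatory care.")
  expect_equal(st$n_polysyllables, 3)
  expect_equal(st$n_complex, 1)
  # sentence-initial capitalization is not a proper-noun signal
  st2 <- compute_token_stats("Medication helps.")
  expect_equal(st2$n_complex, 1)
})

test_that("degenerate text is rejected", {
  expect_error(compute_token_stats("   "), "empty")
  expect_error(compute_token_stats("..."), "no words")
})

test_that("readability formulas reproduce hand-computed values", {
  s <- function(S, W, Syll = W, C = 0, P = 0, L = W) {
    token_stats(S, W, Syll, C, P, L)
  }
  expect_equal(flesch_kincaid_grade(s(10, 100, Syll = 150)), 6.01)
  expect_equal(flesch_kincaid_grade(s(10, 10)), -3.40)   # one monosyllable per sentence
  expect_equal(gunning_fog_index(s(5, 100, C = 10, P = 10)), 12.0)
  expect_equal(gunning_fog_index(s(10, 100)), 4.0)
  expect_equal(gunning_fog_index(s(5, 100, C = 11, P = 11)) -
                 gunning_fog_index(s(5, 100, C = 10, P = 10)), 0.4)
  expect_equal(coleman_liau_index(s(5, 100, L = 500)), 12.12)
  expect_equal(coleman_liau_index(s(20, 100, L = 300)), -4.08)
  expect_equal(suppressWarnings(smog_index(s(10, 10))), 3.1291)
  expect_equal(smog_index(s(30, 900, Syll = 1000, P = 30, C = 30)),
               1.0430 * sqrt(30) + 3.1291)
  expect_equal(suppressWarnings(smog_index(s(10, 300, Syll = 400, P = 30, C = 30))),
               1.0430 * sqrt(90) + 3.1291)
})

test_that("formula preconditions reject degenerate counts", {
  bad <- token_stats(0, 0, 0, 0, 0, 0)
  expect_error(flesch_kincaid_grade(bad), "> 0")
  expect_error(gunning_fog_index(bad), "> 0")
  expect_error(coleman_liau_index(bad), "> 0")
  expect_error(smog_index(bad), "> 0")
  expect_warning(smog_index(token_stats(5, 50, 60, 0, 0, 200)), "30 sentences")
})

test_that("words per minute divides the word count by authoring time", {
  st <- token_stats(30, 600, 900, 10, 20, 3000)
  expect_equal(words_per_minute(st, 2), 300)
  expect_equal(words_per_minute(token_stats(30, 1060, 1500, 10, 20, 5000), 2),
               530)
  expect_equal(words_per_minute(st, 1), 2 * words_per_minute(st, 2))
  expect_error(words_per_minute(st, 0), "positive")
  expect_error(words_per_minute(st, -2), "positive")
})

test_that("indices are invariant to whitespace and sentence order", {
  txt <- "Gentle exercise helps the knee. Manage weight daily. Rest after activity."
  messy <- "  Gentle exercise helps the knee.\n\n  Manage weight daily.\tRest after activity.  "
  permuted <- "Manage weight daily. Rest after activity. Gentle exercise helps the knee."
  f <- function(t) {
    st <- compute_token_stats(t)
    c(flesch_kincaid_grade(st), gunning_fog_index(st),
      coleman_liau_index(st), suppressWarnings(smog_index(st)))
  }
  expect_equal(f(txt), f(messy))
  expect_equal(f(txt), f(permuted))
})

test_that("swapping a monosyllable for a 4-syllable word moves indices the right way", {
  base <- token_stats(10, 100, 130, 10, 12, 500)
  harder <- token_stats(10, 100, 133, 11, 13, 500)  # same letters, +3 syllables
  expect_gt(flesch_kincaid_grade(harder), flesch_kincaid_grade(base))
  expect_gt(suppressWarnings(smog_index(harder)),
            suppressWarnings(smog_index(base)))
  expect_gte(gunning_fog_index(harder), gunning_fog_index(base))
  expect_equal(coleman_liau_index(harder), coleman_liau_index(base))
})

test_that("every generated word contributes at least one syllable", {
  set.seed(42)
  for (i in 1:20) {
    g <- generate_text(sample(3:8, 1), sample(4:12, 1), runif(1, 1, 2.5))
    st <- compute_token_stats(g$text)
    expect_gte(st$n_syllables, st$n_words)
    expect_gte(st$n_letters, st$n_words)
  }
})
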
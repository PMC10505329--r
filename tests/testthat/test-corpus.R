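test_that("tokenize mirrors the lexicon normalization rules", {
  expect_equal(tokenize("Great BBQ!!")[[1]], c("great", "bbq"))
  expect_equal(tokenize("")[[1]], character(0))
  expect_equal(tokenize("sweet-potato fries")[[1]],
               c("sweet", "potato", "fries"))
  expect_equal(tokenize("Crème Brûlée!")[[1]], c("creme", "brulee"))
})

test_that("matching is greedy, longest-first and non-overlapping", {
  lex <- lexicon(data.frame(surface = c("sweet_potato_fries", "fries",
                                        "beer")))
  toks <- tokenize("the sweet potato fries were great")[[1]]
  m <- match_terms(toks, lex)
  expect_equal(m$surface, "sweet_potato_fries")
  expect_equal(m$n_words, 3L)
  expect_equal(match_terms(c("beer", "beer"), lex)$surface, c("beer", "beer"))
  expect_equal(nrow(match_terms(toks, lexicon(data.frame()))), 0L)
  # overlapping mode also counts the embedded sub-term
  mo <- match_terms(toks, lex, overlapping = TRUE)
  expect_setequal(mo$surface, c("sweet_potato_fries", "fries"))
})

test_that("matching is stable under lexicon reordering and monotone in it", {
  lex_df <- data.frame(surface = c("ice_cream", "cream", "ice", "cone"))
  toks <- tokenize("ice cream cone with cream on top")[[1]]
  base <- match_terms(toks, lexicon(lex_df))
  set.seed(71)
  for (i in 1:5) {
    shuffled <- lexicon(lex_df[sample(nrow(lex_df)), , drop = FALSE])
    expect_equal(match_terms(toks, shuffled), base)
  }
  subset_lex <- lexicon(data.frame(surface = c("cream", "cone")))
  expect_lte(nrow(match_terms(toks, subset_lex)), nrow(base))
})

test_that("percent increase reproduces the six district worked examples", {
  originals <- c(11838, 23667, 50057, 111668, 40179, 18379)
  expanded <- c(13969, 27715, 58452, 130185, 46991, 21763)
  printed <- c(8.26, 7.88, 7.74, 7.66, 7.81, 8.43)
  expect_equal(percent_increase(originals, expanded), printed,
               tolerance = 0.01 / mean(printed))
  expect_equal(percent_increase(500, 500), 0)
  expect_error(percent_increase(0, 0), "undefined")
  expect_equal(percent_increase_conventional(100, 150), 50)
  expect_error(percent_increase_conventional(0, 5), "zero baseline")
})

test_that("welch_t_test matches the textbook formula", {
  got <- welch_t_test(c(1, 2, 3), c(2, 4, 6))
  want <- welch_oracle(c(1, 2, 3), c(2, 4, 6))
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  # frozen hand values: t = -2/sqrt(5/3), df = 50/17
  expect_equal(got$t, -1.5491933, tolerance = 1e-6)
  expect_equal(got$df, 2.9411765, tolerance = 1e-6)
})

test_that("welch_t_test is antisymmetric and handles degenerate input", {
  set.seed(72)
  a <- rpois(20, 30); b <- rpois(25, 45)
  ab <- welch_t_test(a, b); ba <- welch_t_test(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$df, ba$df)
  expect_equal(ab$p, ba$p)
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("district_report recovers planted counts and layout", {
  lex_old <- lexicon(data.frame(
    surface = c("beer", "ice_cream"), ed_kcal_per_g = c(0.43, 2.1)))
  lex_new <- lexicon(data.frame(
    surface = c("beer", "ice_cream", "kale_salad_bowl"),
    ed_kcal_per_g = c(0.43, 2.1, 0.8)))
  corp <- generate_review_corpus(lex_new, n_outlets = 12,
                                 districts = c("east", "west"),
                                 mean_terms_per_outlet = 15, seed = 73)
  rep <- district_report(corp$reviews, lex_old, lex_new)
  expect_s3_class(rep, "district_report")
  expect_setequal(unique(rep$district), c("east", "west"))
  expect_setequal(unique(rep$n_words), c("all", "1", "2", "3", "4"))
  # planted bookkeeping equals matched totals under the full lexicon
  planted_tot <- sum(corp$planted$count)
  expect_equal(sum(rep$count_new[rep$n_words == "all"]), planted_tot)
  planted_by_len <- tapply(corp$planted$count, corp$planted$n_words, sum)
  for (nw in names(planted_by_len)) {
    expect_equal(sum(rep$count_new[rep$n_words == nw]),
                 unname(planted_by_len[nw]))
  }
  # ED-class bookkeeping: per-class counts sum to the total
  oc <- attr(rep, "outlet_counts")$new
  expect_equal(oc$L_ED + oc$H_ED, oc$total)
})

test_that("identical lexicons give zero increase and t = 0 everywhere", {
  lex <- lexicon(data.frame(surface = c("beer", "taco"),
                            ed_kcal_per_g = c(0.43, 2.2)))
  corp <- generate_review_corpus(lex, n_outlets = 8, districts = "solo",
                                 mean_terms_per_outlet = 10, seed = 74)
  rep <- district_report(corp$reviews, lex, lex)
  expect_equal(unique(rep$district), "solo")
  expect_true(all(rep$pct_increase[!is.na(rep$pct_increase)] == 0))
  expect_true(all(rep$t[!is.na(rep$t)] == 0))
})

test_that("districts with fewer than two outlets are noted, not tested", {
  lex <- lexicon(data.frame(surface = "beer", ed_kcal_per_g = 0.43))
  reviews <- data.frame(outlet_id = c("a", "b", "c"),
                        district = c("big", "big", "tiny"),
                        text = c("beer time", "no match", "beer beer"))
  rep <- district_report(reviews, lex, lex)
  expect_match(rep$note[rep$district == "tiny"][1], "fewer than 2")
  expect_true(all(is.na(rep$t[rep$district == "tiny"])))
  expect_error(district_report(
    data.frame(outlet_id = "a", district = "", text = "x"), lex, lex),
    "district label")
})

test_that("review readers accept CSV and JSONL", {
  df <- data.frame(outlet_id = c("o1", "o2"), district = c("d1", "d2"),
                   text = c("some beer", "kale salad"),
                   stringsAsFactors = FALSE)
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  expect_equal(read_reviews(csv), df)
  jsonl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(nrow(df)), function(i)
    jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), character(1)),
    jsonl)
  expect_equal(read_reviews(jsonl), df)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_reviews(bad), "must have fields")
})
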
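test_that("normalize_term applies the cleaning rules", {
  expect_equal(normalize_term("Sweet Potato Fries!"), "sweet_potato_fries")
  expect_equal(normalize_term("beer"), "beer")
  expect_equal(normalize_term("Crème Brûlée"), "creme_brulee")
  expect_equal(normalize_term("  A1  steak--sauce "), "a1_steak_sauce")
  expect_warning(out <- normalize_term(c("beer", "!!!")), "reduced to nothing")
  expect_equal(out, c("beer", NA))
  expect_error(normalize_term("   "), "empty")
  expect_error(normalize_term(character(0)), NA)
})

test_that("BNF thresholds sit at 0.6, 1.5 and 4 kcal/g", {
  expect_equal(classify_bnf(0.5), "very_low")
  expect_equal(classify_bnf(c(0.59999, 0.6)), c("very_low", "low"))
  expect_equal(classify_bnf(c(1.49, 1.5)), c("low", "medium"))
  expect_equal(classify_bnf(4.0), "medium")
  expect_equal(classify_bnf(4.2), "high")
  expect_error(classify_bnf(-0.1), "nonnegative")
})

test_that("binary ED class collapses the BNF scheme at 1.5", {
  expect_equal(classify_ed(c(1.49, 1.5, 0)), c("L_ED", "H_ED", "L_ED"))
  expect_error(classify_ed(-1), "nonnegative")
  # grid consistency over 0..10 kcal/g
  grid <- seq(0, 10, by = 0.01)
  expect_equal(classify_ed(grid),
               ifelse(classify_bnf(grid) %in% c("medium", "high"),
                      "H_ED", "L_ED"))
})

test_that("aggregate_synonyms averages energy densities", {
  beer <- aggregate_synonyms(data.frame(name = c("Beer A", "Beer B"),
                                        ed = c(0.40, 0.46)), "beer")
  expect_equal(beer$ed_kcal_per_g, 0.43)
  expect_equal(beer$ed_class, "L_ED")
  single <- aggregate_synonyms(1.2, "toast")
  expect_equal(single$ed_kcal_per_g, 1.2)
  crossing <- aggregate_synonyms(c(1.0, 2.2), "mix")
  expect_equal(crossing$ed_kcal_per_g, 1.6)
  expect_equal(crossing$ed_class, "H_ED")
  expect_error(aggregate_synonyms(numeric(0), "x"), "empty")
})

test_that("build_seed_lexicon filters, converts units and merges duplicates", {
  comp <- data.frame(
    name = c("Beer!", "beer", "Asparagus", "Chips", "Kale"),
    energy = c(40, 46, 20, NA, 500),
    unit = "kcal_per_100g", stringsAsFactors = FALSE)
  vocab <- c("beer", "asparagus", "kale", "other")
  expect_message(lex <- build_seed_lexicon(comp, vocab), "without an energy")
  expect_s3_class(lex, "food_lexicon")
  expect_equal(nrow(lex), 3L)
  expect_equal(lex$ed_kcal_per_g[lex$surface == "beer"], 0.43)
  asp <- lex[lex$surface == "asparagus", ]
  expect_equal(asp$ed_kcal_per_g, 0.2)
  expect_equal(asp$bnf_class, "very_low")
  expect_equal(asp$ed_class, "L_ED")
  expect_true(all(lex$surface %in% vocab))
  expect_true(all(!is.na(lex$bnf_class) & !is.na(lex$ed_class)))
})

test_that("kJ energies convert at 4.184 kJ/kcal", {
  comp <- data.frame(name = "Oil", energy = 4184, unit = "kJ_per_100g")
  lex <- build_seed_lexicon(comp, "oil")
  expect_equal(lex$ed_kcal_per_g, 10)
  expect_equal(lex$bnf_class, "high")
})

test_that("unknown units and empty intersections are handled", {
  comp <- data.frame(name = "x", energy = 1, unit = "calories")
  expect_error(build_seed_lexicon(comp, "x"), "unknown energy unit")
  comp2 <- data.frame(name = "Beer", energy = 43, unit = "kcal_per_100g")
  expect_warning(
    expect_message(lex <- build_seed_lexicon(comp2, "zzz"), "absent"),
    "empty seed lexicon")
  expect_equal(nrow(lex), 0L)
})

test_that("lexicon serialization round-trips and rebuild is idempotent", {
  comp <- data.frame(name = c("Beer", "Asparagus", "Sweet potato fries"),
                     energy = c(43, 20, 290), unit = "kcal_per_100g")
  vocab <- c("beer", "asparagus", "sweet_potato_fries")
  lex <- build_seed_lexicon(comp, vocab)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  back <- read_lexicon(path)
  expect_equal(as.data.frame(back), as.data.frame(lex))
  expect_equal(back$n_words[back$surface == "sweet_potato_fries"], 3L)
})

test_that("lexicon invariants are enforced", {
  expect_error(lexicon(data.frame(surface = c("beer", "beer"))), "duplicate")
  expect_error(food_term("Bad Surface"), "invalid surface")
  expect_error(food_term("a__b"), "invalid surface")
  ft <- food_term("sweet_potato_fries", 2.9)
  expect_equal(ft$n_words, 3L)
  # supplied class labels survive when no ED value is present
  lx <- lexicon(data.frame(surface = "newword", ed_kcal_per_g = NA,
                           ed_class = "H_ED", source = "expanded"))
  expect_equal(lx$ed_class, "H_ED")
})
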
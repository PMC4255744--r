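test_that("normalization folds unicode variants and whitespace", {
  expect_identical(normalize_text("Incubate at 30 °C."),
                   "Incubate at 30°C.")
  expect_identical(normalize_text("a\r\nb\rc"), "a\nb\nc")
  expect_identical(normalize_text("5 µL"), "5 μL")  # micro sign -> mu
  expect_identical(normalize_text("30℃"), "30°C")
  expect_identical(normalize_text("a\t\tb   c"), "a b c")
  # idempotence
  for (x in c("Adjust to 10% TCA. Incubate at 30°C overnight.",
              "Mix 5 μL for 2 h.\n")) {
    expect_identical(normalize_text(normalize_text(x)), normalize_text(x))
  }
})

test_that("sentence splitting respects decimals and abbreviations", {
  s <- split_sentences("Adjust to 10% TCA. Incubate at 30°C overnight.")
  expect_identical(nrow(s), 2L)
  expect_identical(s$text[1], "Adjust to 10% TCA.")
  expect_identical(s$text[2], "Incubate at 30°C overnight.")
  expect_identical(s$index, 0:1)

  expect_identical(nrow(split_sentences("")), 0L)
  expect_identical(nrow(split_sentences("   \n ")), 0L)
  expect_identical(nrow(split_sentences("Dilute to 0.1% BSA.")), 1L)
  expect_identical(nrow(split_sentences("Mix well (see e.g. the manual).")), 1L)
  expect_identical(nrow(split_sentences("Stop! Then mix.")), 2L)
  expect_identical(nrow(split_sentences("Mix well\nIncubate overnight")), 2L)
})

test_that("sentence spans tile the document's non-whitespace exactly once", {
  docs <- c(
    "Adjust to 10% TCA. Incubate at 30°C overnight.",
    "One. Two! Three? Four\nFive.",
    vapply(1:10, function(s) {
      normalize_text(generate_protocol(s, 4, test_catalog, test_config)$text)
    }, "")
  )
  for (doc in docs) {
    s <- split_sentences(doc)
    covered <- rep(0L, nchar(doc))
    for (i in seq_len(nrow(s))) {
      expect_identical(substr(doc, s$start[i] + 1, s$end[i]), s$text[i])
      covered[(s$start[i] + 1):s$end[i]] <- covered[(s$start[i] + 1):s$end[i]] + 1L
    }
    chars <- strsplit(doc, "")[[1]]
    nonws <- grepl("[^[:space:]]", chars)
    expect_true(all(covered[nonws] == 1L))   # every non-space char once
    expect_true(all(covered <= 1L))          # no overlap anywhere
    # spans ordered and non-overlapping
    if (nrow(s) > 1) expect_true(all(diff(s$start) > 0))
  }
})

test_that("candidate verbs come from imperative position and coordination", {
  v <- find_candidate_verbs("Incubate at 30°C overnight.")
  expect_identical(v$lemma, "incubate")
  expect_identical(substr("Incubate at 30°C overnight.", v$start + 1, v$end),
                   "Incubate")
  expect_identical(find_candidate_verbs("Freeze unused portions in aliquots.")$lemma,
                   "freeze")
  expect_identical(find_candidate_verbs("Mix and incubate.")$lemma,
                   c("mix", "incubate"))
  expect_identical(find_candidate_verbs("Mix, vortex and then incubate.")$lemma,
                   c("mix", "vortex", "incubate"))
  # infinitive position is a goal clause, not an action slot
  expect_identical(find_candidate_verbs("Centrifuge to pellet cells.")$lemma,
                   "centrifuge")
})

test_that("lemmatization strips regular inflections", {
  lex <- c("incubate", "shake", "stir", "filter", "mix", "wash")
  expect_identical(lemmatize_verb("Incubated", lex), "incubate")
  expect_identical(lemmatize_verb("incubating", lex), "incubate")
  expect_identical(lemmatize_verb("shaking", lex), "shake")
  expect_identical(lemmatize_verb("stirred", lex), "stir")
  expect_identical(lemmatize_verb("filtered", lex), "filter")
  expect_identical(lemmatize_verb("mixes", lex), "mix")
  expect_identical(lemmatize_verb("washes", lex), "wash")
  expect_identical(lemmatize_verb("mixed"), "mix")      # lexicon-free
  expect_identical(lemmatize_verb("stopped"), "stop")   # undoubling
})

test_that("quantity mentions carry unit ids and kind hints", {
  q <- find_quantities("Incubate at 30°C overnight.", test_clues)
  expect_identical(nrow(q), 1L)
  expect_identical(q$magnitude, 30)
  expect_identical(q$unit_symbol, "°C")
  expect_identical(q$unit_id, "UO:0000027")
  expect_identical(q$kind_hint, "temperature")

  q <- find_quantities("at a concentration of 100 μg/mL", test_clues)
  expect_identical(q$unit_symbol, "μg/mL")
  expect_identical(q$kind_hint, "concentration")

  q <- find_quantities("You will need 20 μL of each per 100 mL of medium.",
                       test_clues)
  expect_identical(q$magnitude, c(20, 100))
  expect_identical(q$unit_symbol, c("μL", "mL"))
  expect_identical(unique(q$kind_hint), "volume")

  q <- find_quantities("Spin at 10000 rpm for 16 hours.", test_clues)
  expect_identical(q$kind_hint, c("speed", "period"))
  expect_identical(q$unit_symbol[2], "hour")  # plural folded to the table form
})

test_that("quantity mentions never overlap and compounds beat prefixes", {
  texts <- c(
    "Reconstitute with 0.1% BSA at 100 μg/mL in 10 mL for 5 min at 37°C.",
    "Use 2 M then 10 mM then 5 μM stocks.",
    vapply(11:20, function(s) {
      generate_protocol(s, 5, test_catalog, test_config)$text
    }, "")
  )
  for (txt in texts) {
    q <- find_quantities(txt, test_clues)
    if (nrow(q) > 1) {
      expect_true(all(q$start[-1] >= q$end[-nrow(q)]))
    }
  }
  q <- find_quantities("Use 2 M then 10 mM then 5 μM stocks.", test_clues)
  expect_identical(q$unit_symbol, c("M", "mM", "μM"))
})

test_that("unknown attached units are flagged, not guessed", {
  q <- find_quantities("Heat to 30°X now.", test_clues, include_unknown = TRUE)
  expect_identical(nrow(q), 1L)
  expect_false(q$known)
  expect_true(is.na(q$unit_id))
  # plain counts are not quantity mentions
  expect_identical(
    nrow(find_quantities("Prepare 20 samples.", test_clues,
                         include_unknown = TRUE)),
    0L
  )
})
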
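tca_protocol <- function(carry_forward = FALSE) {
  translate_protocol("Adjust to 10% TCA. Incubate at 30°C overnight.",
                     test_catalog, test_config, test_clues,
                     carry_forward = carry_forward)
}

test_that("completeness reporting mirrors missing essential descriptors", {
  rep <- check_completeness(tca_protocol(), test_catalog)
  expect_identical(rep$status, "incomplete")
  expect_length(rep$steps$missing[[1]], 0)
  expect_setequal(rep$steps$missing[[2]], c("biochemical_entity", "condition"))

  # a fully specified store step is complete
  p <- translate_protocol(
    "Store yeast growth culture at 4°C for 2 h in conical tube under sterile conditions.",
    test_catalog, test_config, test_clues
  )
  rep <- check_completeness(p, test_catalog)
  expect_identical(rep$status, "complete")
  expect_length(rep$steps$missing[[1]], 0)

  # temperature is optional for filter: no missing entry without it
  p <- translate_protocol("Filter lysis buffer.", test_catalog, test_config,
                          test_clues)
  rep <- check_completeness(p, test_catalog)
  expect_false("temperature" %in% rep$steps$missing[[1]])
})

test_that("unconfirmed inferred essentials block completeness", {
  p <- translate_protocol(
    "Streak yeast growth culture on the dish. Incubate at 30°C overnight under sterile conditions.",
    test_catalog, test_config, test_clues
  )
  rep <- check_completeness(p, test_catalog)
  expect_identical(rep$status, "incomplete")
  expect_identical(rep$steps$unconfirmed[[2]], "biochemical_entity")
  # confirming the inference (value = NA) completes the protocol
  p2 <- apply_user_answers(
    p, data.frame(step_index = 2, kind = "biochemical_entity", value = NA),
    test_catalog, test_clues
  )
  rep2 <- check_completeness(p2, test_catalog)
  expect_identical(rep2$status, "complete")
  ent <- step_descriptor(p2$steps[[2]], "biochemical_entity")
  expect_identical(ent$provenance, "user")
  expect_true(ent$confirmed)
})

test_that("user answers complete a protocol monotonically", {
  p <- tca_protocol()
  n_before <- length(p$steps[[2]]$descriptors)
  answers <- data.frame(
    step_index = c(2, 2),
    kind = c("biochemical_entity", "condition"),
    value = c("bFGF/EGF stock", "under sterile conditions")
  )
  p2 <- apply_user_answers(p, answers, test_catalog, test_clues)
  expect_gte(length(p2$steps[[2]]$descriptors), n_before + 2)
  rep <- check_completeness(p2, test_catalog)
  expect_identical(rep$status, "complete")
  expect_length(rep$steps$missing[[2]], 0)
  # extracted values are untouched
  expect_identical(step_descriptor(p2$steps[[2]], "temperature")$magnitude, 30)

  # partial answers shrink the missing set by exactly the answered kinds
  p3 <- apply_user_answers(
    p, data.frame(step_index = 2, kind = "biochemical_entity",
                  value = "bFGF/EGF stock"),
    test_catalog, test_clues
  )
  expect_identical(check_completeness(p3, test_catalog)$steps$missing[[2]],
                   "condition")
  # quantity answers are parsed with unit ids
  p4 <- apply_user_answers(
    tca_protocol(),
    data.frame(step_index = 1, kind = "volume", value = "20 μL"),
    test_catalog, test_clues
  )
  vol <- step_descriptor(p4$steps[[1]], "volume")
  expect_identical(vol$magnitude, 20)
  expect_identical(vol$unit_id, "UO:0000101")
  expect_identical(vol$provenance, "user")
})

test_that("answers for disallowed kinds or empty answer sets are handled", {
  p <- tca_protocol()
  # speed is not a descriptor of incubate
  expect_error(
    apply_user_answers(
      p, data.frame(step_index = 2, kind = "speed", value = "500 rpm"),
      test_catalog, test_clues
    ),
    class = "protsem_validation_error"
  )
  expect_identical(
    apply_user_answers(p, data.frame(step_index = integer(),
                                     kind = character(),
                                     value = character()),
                      test_catalog, test_clues),
    p
  )
  expect_error(
    apply_user_answers(
      p, data.frame(step_index = 9, kind = "condition", value = "x"),
      test_catalog, test_clues
    ),
    class = "protsem_usage_error"
  )
})

test_that("manual verb mappings become curation suggestions", {
  p <- translate_protocol("Spin at 10000 rpm for 5 min.",
                          test_catalog, test_config, test_clues)
  expect_length(p$steps, 0)  # 'spin' is not in the catalog
  sug <- record_update_suggestions(
    p, data.frame(verb = "spin", action = "centrifuge"), test_catalog
  )
  expect_identical(sug$type, "new_synonym")
  expect_identical(sug$action_label, "centrifuge")

  expect_identical(
    nrow(record_update_suggestions(p, data.frame(verb = character(),
                                                 action = character()),
                                   test_catalog)),
    0L
  )
  # mapping a verb the catalog already knows is a no-op with a note
  sug2 <- record_update_suggestions(
    p, data.frame(verb = "mix", action = "centrifuge"), test_catalog
  )
  expect_identical(sug2$type, "no_op")
  expect_match(sug2$note, "already maps")
})

test_that("reports reference only catalog actions and serialize to JSON", {
  p <- tca_protocol()
  p$steps[[1]]$action_id <- "EXACT2_999999"
  expect_error(check_completeness(p, test_catalog),
               class = "protsem_validation_error")

  rep <- check_completeness(tca_protocol(), test_catalog)
  obj <- jsonlite::fromJSON(report_to_json(rep), simplifyVector = FALSE)
  expect_identical(obj$status, "incomplete")
  expect_length(obj$steps, 2)
  expect_setequal(unlist(obj$steps[[2]]$missing_essential),
                  c("biochemical_entity", "condition"))
})
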
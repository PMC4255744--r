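tca_text <- "Adjust to 10% TCA. Incubate at 30°C overnight."

test_that("action identification copies multi-action sentences", {
  s <- split_sentences("Adjust to 10% TCA. Incubate at 30°C overnight.")
  inst <- identify_actions(s, test_catalog)
  expect_length(inst, 2)
  expect_identical(vapply(inst, `[[`, "", "action_label"),
                   c("adjust", "incubate"))

  s <- split_sentences("Mix and incubate for 5 min.")
  inst <- identify_actions(s, test_catalog)
  expect_length(inst, 2)
  expect_identical(vapply(inst, `[[`, "", "action_label"),
                   c("mix", "incubate"))
  # each copy carries the full sentence
  expect_identical(inst[[1]]$sentence, inst[[2]]$sentence)

  s <- split_sentences("This is important.")
  inst <- identify_actions(s, test_catalog)
  expect_length(inst, 0)
  expect_identical(nrow(attr(inst, "unmatched")), 1L)
})

test_that("the TCA/incubate worked example translates as published", {
  p <- translate_protocol(tca_text, test_catalog, test_config, test_clues,
                          carry_forward = FALSE)
  expect_length(p$steps, 2)

  adjust <- p$steps[[1]]
  expect_identical(adjust$action_id, "EXACT2_000089")
  conc <- step_descriptor(adjust, "concentration")
  expect_identical(conc$magnitude, 10)
  expect_identical(conc$unit, "%")
  ent <- step_descriptor(adjust, "biochemical_entity")
  expect_identical(ent$value, "Trichloroacetic acid")
  expect_identical(ent$entity_source, "NCBI Pubchem")
  expect_identical(ent$entity_id, "6421")
  expect_length(adjust$missing_essential, 0)

  inc <- p$steps[[2]]
  expect_identical(inc$action_id, "EXACT2_000049")
  temp <- step_descriptor(inc, "temperature")
  expect_identical(temp$magnitude, 30)
  expect_identical(temp$unit_id, "UO:0000027")
  expect_identical(temp$provenance, "extracted")
  per <- step_descriptor(inc, "period")
  expect_identical(per$magnitude, 16)
  expect_identical(per$unit, "h")
  expect_identical(per$provenance, "default")
  expect_setequal(inc$missing_essential, c("biochemical_entity", "condition"))
})

test_that("the growth-factor reconstitution sentence yields its concentration", {
  p <- translate_protocol(
    paste(
      "Reconstitute bFGF and EGF with 0.1% BSA solution at a concentration",
      "of 100 μg/mL. You will need 20 μL of each per 100 mL of complete",
      "medium. Freeze unused portions in aliquots."
    ),
    test_catalog, test_config, test_clues
  )
  labels <- vapply(p$steps, `[[`, "", "action_label")
  expect_true("reconstitute" %in% labels)
  expect_true("freeze" %in% labels)
  rec <- p$steps[[which(labels == "reconstitute")]]
  conc <- step_descriptor(rec, "concentration")
  expect_identical(conc$magnitude, 100)
  expect_identical(conc$unit, "μg/mL")
  expect_identical(conc$provenance, "extracted")
  # the note sentence has no imperative action verb -> kept unmatched
  expect_true(any(grepl("You will need", p$unmatched$text)))
})

test_that("goal, condition and protocol-method cues are captured verbatim", {
  p <- translate_protocol(
    "Incubate yeast growth culture at 30°C overnight under sterile conditions in order to start the culture.",
    test_catalog, test_config, test_clues
  )
  step <- p$steps[[1]]
  expect_identical(step_descriptor(step, "condition")$value,
                   "under sterile conditions")
  expect_identical(step_descriptor(step, "goal")$value, "start the culture")
  expect_length(step$missing_essential, 0)

  p2 <- translate_protocol(
    "Wash agarose gel according to the manufacturer instructions.",
    test_catalog, test_config, test_clues
  )
  expect_identical(
    step_descriptor(p2$steps[[1]], "protocol_method")$value,
    "according to the manufacturer instructions"
  )
})

test_that("extracted kinds always lie within the action's descriptor specs", {
  for (s in 31:40) {
    fx <- generate_protocol(s, 4, test_catalog, test_config)
    p <- translate_protocol(fx$text, test_catalog, test_config, test_clues)
    for (step in p$steps) {
      action <- match_action_verb(step$action_label, test_catalog)
      allowed <- c(action$essential, action$optional)
      kinds <- vapply(step$descriptors, `[[`, "", "kind")
      expect_true(all(kinds %in% allowed))
      # missing and present essential kinds are disjoint and exhaustive
      present_ess <- intersect(kinds, action$essential)
      expect_length(intersect(step$missing_essential, kinds), 0)
      expect_setequal(union(step$missing_essential, present_ess),
                      action$essential)
    }
  }
})

test_that("competing quantity mentions resolve to the verb-nearest one", {
  p <- translate_protocol("Incubate at 30°C then at 65°C.",
                          test_catalog, test_config, test_clues)
  step <- p$steps[[1]]
  temps <- Filter(function(d) d$kind == "temperature", step$descriptors)
  expect_length(temps, 1)
  expect_identical(temps[[1]]$magnitude, 30)
  expect_true(any(grepl("65", step$notes)))
})

test_that("unknown units are kept as notes with empty unit ids", {
  p <- translate_protocol("Heat distilled water to 30°Z.",
                          test_catalog, test_config, test_clues)
  step <- p$steps[[1]]
  expect_identical(step$unknown_units, "°Z")
  expect_true(any(grepl("unknown unit", step$notes)))
  expect_null(step_descriptor(step, "temperature"))
})

test_that("carry-forward inherits the most recent participant, flagged", {
  p <- translate_protocol(
    "Streak yeast growth culture on the plate. Incubate at 30°C overnight.",
    test_catalog, test_config, test_clues
  )
  inc <- p$steps[[2]]
  ent <- step_descriptor(inc, "biochemical_entity")
  expect_identical(ent$value, "yeast growth culture")
  expect_identical(ent$provenance, "inferred")
  expect_false(ent$confirmed)
  expect_false("biochemical_entity" %in% inc$missing_essential)

  # nothing to inherit: stays missing
  p2 <- translate_protocol("Mix gently. Incubate at 30°C overnight.",
                           test_catalog, test_config, test_clues)
  expect_true("biochemical_entity" %in% p2$steps[[2]]$missing_essential)

  # disabled flag leaves the protocol unchanged
  p3 <- translate_protocol(
    "Streak yeast growth culture on the plate. Incubate at 30°C overnight.",
    test_catalog, test_config, test_clues, carry_forward = FALSE
  )
  expect_true("biochemical_entity" %in% p3$steps[[2]]$missing_essential)
  expect_identical(infer_carry_forward(p3, enabled = FALSE), p3)
})

test_that("translation is deterministic and handles empty input", {
  a <- protocol_to_json(translate_protocol(tca_text, test_catalog,
                                           test_config, test_clues))
  b <- protocol_to_json(translate_protocol(tca_text, test_catalog,
                                           test_config, test_clues))
  expect_identical(as.character(a), as.character(b))

  p <- translate_protocol("", test_catalog, test_config, test_clues)
  expect_length(p$steps, 0)
  expect_identical(nrow(p$unmatched), 0L)
})

test_that("protocol JSON follows the documented shape", {
  p <- translate_protocol(tca_text, test_catalog, test_config, test_clues)
  obj <- jsonlite::fromJSON(protocol_to_json(p), simplifyVector = FALSE)
  expect_named(obj, c("title", "provenance", "steps", "unmatched"),
               ignore.order = TRUE)
  expect_length(obj$steps, 2)
  s1 <- obj$steps[[1]]
  expect_identical(s1$action$id, "EXACT2_000089")
  expect_identical(s1$step_index, 1L)
  d <- s1$descriptors[[1]]
  expect_true(all(c("kind", "relation", "value", "provenance", "essential")
                  %in% names(d)))
  ent <- Filter(function(x) x$kind == "biochemical_entity", s1$descriptors)[[1]]
  expect_identical(ent$entity_id$value, "6421")
})
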
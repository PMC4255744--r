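# Descriptor values are plain lists: kind, relation, value (character),
# magnitude (numeric, quantities only), unit, unit_id, entity_source,
# entity_id, provenance (extracted | default | inferred | user), confirmed,
# essential, start, end (0-based spans in the sentence copy, NA when the
# value was not read from the text).
new_descriptor <- function(kind, value, magnitude = NA_real_,
                           unit = NA_character_, unit_id = NA_character_,
                           entity_source = NA_character_,
                           entity_id = NA_character_,
                           provenance = "extracted", confirmed = TRUE,
                           essential = FALSE,
                           start = NA_integer_, end = NA_integer_) {
  list(
    kind = kind, relation = kind_relation(kind), value = value,
    magnitude = magnitude, unit = unit, unit_id = unit_id,
    entity_source = entity_source, entity_id = entity_id,
    provenance = provenance, confirmed = confirmed, essential = essential,
    start = as.integer(unname(start)), end = as.integer(unname(end))
  )
}

new_action_instance <- function(action, sentence_index, sentence,
                                verb_start, verb_end) {
  structure(
    list(
      step_index = NA_integer_,
      action_id = action$id,
      action_label = action$label,
      sentence_index = sentence_index,
      sentence = sentence,
      verb_start = verb_start,
      verb_end = verb_end,
      descriptors = list(),
      missing_essential = character(),
      unknown_units = character(),
      notes = character()
    ),
    class = "action_instance"
  )
}

#' Identify experimental actions in sentences
#'
#' Matches candidate verbs (see [find_candidate_verbs()]) against the
#' catalog. A sentence containing several experimental actions yields that
#' many instances, each holding its own copy of the sentence; sentences
#' with no catalog match are reported as unmatched so they can be kept as
#' free-text notes.
#'
#' @param sentences A tibble from [split_sentences()].
#' @param catalog An [load_catalog()] result.
#' @return A list of `action_instance` objects (without descriptors), with
#'   an `unmatched` attribute: tibble of `sentence_index`, `text`.
#' @examples
#' s <- split_sentences("Adjust to 10% TCA. Incubate at 30°C overnight.")
#' length(identify_actions(s, load_catalog()))
#' @export
identify_actions <- function(sentences, catalog) {
  lexicon <- catalog_verb_lexicon(catalog)
  instances <- list()
  unmatched <- list()
  for (r in seq_len(nrow(sentences))) {
    text <- sentences$text[r]
    idx <- sentences$index[r]
    cands <- find_candidate_verbs(text, lexicon = lexicon)
    found <- FALSE
    seen <- integer(0)
    for (k in seq_len(nrow(cands))) {
      if (cands$start[k] %in% seen) next
      act <- match_action_verb(cands$lemma[k], catalog)
      if (is.null(act)) next
      seen <- c(seen, cands$start[k])
      found <- TRUE
      instances[[length(instances) + 1L]] <- new_action_instance(
        act, idx, text, cands$start[k], cands$end[k]
      )
    }
    if (!found) {
      unmatched[[length(unmatched) + 1L]] <- tibble::tibble(
        sentence_index = idx, text = text
      )
    }
  }
  structure(
    instances,
    unmatched = if (length(unmatched)) {
      do.call(rbind, unmatched)
    } else {
      tibble::tibble(sentence_index = integer(), text = character())
    }
  )
}

# Scan text for dictionary surfaces (names + aliases), case-insensitive,
# whole-token, longest-match-wins, non-overlapping.
scan_dictionary <- function(text, tbl) {
  hits <- list()
  for (i in seq_len(nrow(tbl))) {
    for (surface in c(tbl$name[i], tbl$aliases[[i]])) {
      pat <- sprintf("(?<![A-Za-z0-9])%s(?![A-Za-z0-9])",
                     regex_escape(surface))
      m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1L] == -1L) next
      for (j in seq_along(m)) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          start = as.integer(m[j]) - 1L,
          end = as.integer(m[j]) - 1L + attr(m, "match.length")[j],
          record = i
        )
      }
    }
  }
  if (!length(hits)) {
    return(tibble::tibble(start = integer(), end = integer(), record = integer()))
  }
  h <- do.call(rbind, hits)
  h <- h[order(h$start, -(h$end - h$start)), ]
  keep <- logical(nrow(h))
  last_end <- -1L
  for (i in seq_len(nrow(h))) {
    if (h$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- h$end[i]
    }
  }
  h[keep, ]
}

match_text_cue <- function(text, pattern) {
  m <- regexpr(pattern, text, perl = TRUE, ignore.case = TRUE)
  if (m[1L] == -1L) return(NULL)
  list(
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + attr(m, "match.length"),
    text = trimws(substr(text, as.integer(m), as.integer(m) + attr(m, "match.length") - 1L))
  )
}

#' Extract descriptor values for one action instance
#'
#' Applies the semantic clues to the instance's sentence copy: quantity
#' mentions are assigned to the descriptor kinds the action allows,
#' default tokens (overnight, room temperature) are resolved through the
#' lab defaults table, biochemical entities and equipment are linked to
#' their dictionary IDs, and condition / goal / protocol-method phrases
#' are captured verbatim after their cue words. When two mentions compete
#' for one quantity kind the one nearest the action verb wins and the
#' other is kept as a note. Essential kinds with no value are reported in
#' `missing_essential`.
#'
#' @param instance An `action_instance` from [identify_actions()].
#' @param catalog,config,clues The catalog, lab config and clue table.
#' @return The instance with `descriptors`, `missing_essential`,
#'   `unknown_units` and `notes` filled in.
#' @export
extract_descriptors <- function(instance, catalog, config = load_lab_config(),
                                clues = clue_table()) {
  if (!inherits(instance, "action_instance")) {
    ps_abort("`instance` must come from identify_actions()")
  }
  action <- catalog_action_by_id(instance$action_id, catalog)
  if (is.null(action)) {
    ps_abort(sprintf("action id %s not present in catalog", instance$action_id),
             "protsem_validation_error")
  }
  req <- descriptor_requirements(action)
  allowed <- c(req$essential, req$optional)
  text <- instance$sentence
  verb_at <- instance$verb_start
  is_essential <- function(kind) kind %in% req$essential

  candidates <- list()  # per quantity kind, competing mentions
  notes <- character()
  unknown <- character()

  entity_hits <- scan_dictionary(text, config$entities)
  equipment_hits <- scan_dictionary(text, config$equipment)

  # --- quantity mentions -------------------------------------------------
  q <- find_quantities(text, clues, include_unknown = TRUE)
  for (i in seq_len(nrow(q))) {
    if (!q$known[i]) {
      unknown <- c(unknown, q$unit_symbol[i])
      notes <- c(notes, sprintf(
        "unknown unit '%s' in '%s'; value kept without unit id",
        q$unit_symbol[i], ps_substr(text, q$start[i], q$end[i])
      ))
      next
    }
    kind <- q$kind_hint[i]
    if (!(kind %in% allowed)) {
      notes <- c(notes, sprintf(
        "quantity '%s' (%s) not applicable to action '%s'; kept as note",
        ps_substr(text, q$start[i], q$end[i]), kind, action$label
      ))
      next
    }
    d <- new_descriptor(
      kind, value = ps_substr(text, q$start[i], q$end[i]),
      magnitude = q$magnitude[i], unit = q$unit_symbol[i],
      unit_id = q$unit_id[i], essential = is_essential(kind),
      start = q$start[i], end = q$end[i]
    )
    candidates[[kind]] <- c(candidates[[kind]], list(d))
  }

  # --- default tokens ----------------------------------------------------
  for (key in names(config$defaults)) {
    cue <- match_text_cue(
      text, sprintf("(?<![A-Za-z0-9])%s(?![A-Za-z0-9])", regex_escape(key))
    )
    if (is.null(cue)) next
    dq <- config$defaults[[key]]
    if (!(dq$kind %in% allowed)) next
    d <- new_descriptor(
      dq$kind, value = sprintf("%g %s", dq$magnitude, dq$unit),
      magnitude = dq$magnitude, unit = dq$unit, unit_id = dq$unit_id,
      provenance = "default", essential = is_essential(dq$kind),
      start = cue$start, end = cue$end
    )
    candidates[[dq$kind]] <- c(candidates[[dq$kind]], list(d))
  }

  descriptors <- list()
  # resolve competing quantity mentions: extracted beats default, then
  # nearest to the action verb; losers are retained as notes. A
  # concentration written against an entity ("0.1% BSA") qualifies that
  # entity, so it yields to a free-standing concentration mention
  # ("at a concentration of 100 μg/mL") when both occur.
  for (kind in names(candidates)) {
    ds <- candidates[[kind]]
    if (length(ds) > 1L) {
      prov_rank <- vapply(ds, function(d) match(d$provenance, c("extracted", "default")), 1L)
      dist <- vapply(ds, function(d) abs(d$start - verb_at), 1)
      ent_attached <- vapply(ds, function(d) {
        kind == "concentration" && !is.na(d$end) &&
          any(entity_hits$start >= d$end & entity_hits$start <= d$end + 2L)
      }, logical(1))
      ord <- order(prov_rank, ent_attached, dist)
      ds <- ds[ord]
      for (loser in ds[-1L]) {
        notes <- c(notes, sprintf(
          "additional %s mention '%s' ignored (nearest to verb wins)",
          kind, loser$value
        ))
      }
    }
    descriptors[[length(descriptors) + 1L]] <- ds[[1L]]
  }

  # --- entities and equipment -------------------------------------------
  add_participants <- function(tbl, kind, hits) {
    if (!(kind %in% allowed)) return()
    for (i in seq_len(nrow(hits))) {
      rec <- hits$record[i]
      descriptors[[length(descriptors) + 1L]] <<- new_descriptor(
        kind, value = tbl$name[rec],
        entity_source = tbl$id_source[rec], entity_id = tbl$id_value[rec],
        essential = is_essential(kind),
        start = hits$start[i], end = hits$end[i]
      )
    }
  }
  add_participants(config$entities, "biochemical_entity", entity_hits)
  add_participants(config$equipment, "equipment", equipment_hits)

  # --- propositional cues ------------------------------------------------
  if ("condition" %in% allowed) {
    # tempered body: a condition phrase never swallows a goal clause
    body <- "(?:(?!\\bin order to\\b)[^,.;])"
    for (pat in c(
      sprintf("\\bunder\\s+%s+", body),
      sprintf("\\bin the presence of\\s+%s+", body),
      sprintf("\\bwith\\s+[a-z]+ing\\b%s*", body)
    )) {
      cue <- match_text_cue(text, pat)
      if (!is.null(cue)) {
        descriptors[[length(descriptors) + 1L]] <- new_descriptor(
          "condition", value = cue$text,
          essential = is_essential("condition"),
          start = cue$start, end = cue$end
        )
        break
      }
    }
  }
  if ("goal" %in% allowed) {
    cue <- match_text_cue(text, "\\bin order to\\s+([^.;]+)")
    if (!is.null(cue)) {
      descriptors[[length(descriptors) + 1L]] <- new_descriptor(
        "goal",
        value = trimws(sub("(?i)^in order to\\s+", "", cue$text, perl = TRUE)),
        essential = is_essential("goal"), start = cue$start, end = cue$end
      )
    } else {
      # clause-final infinitive with a catalog verb ("... to elute the DNA.")
      m <- regexpr("\\bto\\s+([a-z]+)([^.;]*)[.]?$", text, perl = TRUE,
                   ignore.case = TRUE)
      if (m[1L] != -1L) {
        phrase <- substr(text, as.integer(m), as.integer(m) + attr(m, "match.length") - 1L)
        body <- trimws(sub("^to\\s+", "", sub("[.]$", "", phrase),
                           ignore.case = TRUE))
        verb <- tolower(strsplit(body, "\\s+")[[1]][1])
        if (verb %in% catalog_verb_lexicon(catalog)) {
          descriptors[[length(descriptors) + 1L]] <- new_descriptor(
            "goal", value = body, essential = is_essential("goal"),
            start = as.integer(m) - 1L,
            end = as.integer(m) - 1L + attr(m, "match.length")
          )
        }
      }
    }
  }
  if ("protocol_method" %in% allowed) {
    cue <- match_text_cue(text, "\\baccording to\\s+[^,.;]+")
    if (!is.null(cue)) {
      descriptors[[length(descriptors) + 1L]] <- new_descriptor(
        "protocol_method", value = cue$text,
        essential = is_essential("protocol_method"),
        start = cue$start, end = cue$end
      )
    }
  }

  present <- unique(vapply(descriptors, `[[`, "", "kind"))
  instance$descriptors <- descriptors
  instance$missing_essential <- setdiff(req$essential, present)
  instance$unknown_units <- unknown
  instance$notes <- c(instance$notes, notes)
  instance
}

#' Carry a missing participant forward from the preceding step
#'
#' A protocol sentence frequently omits the participating biochemical
#' entity when it is obvious from context ("Incubate at 30°C" after a step
#' that named a yeast growth culture). For each step whose essential
#' biochemical entity is missing, the most recent preceding step's entity
#' value is copied with provenance `inferred` and left unconfirmed: the
#' user must confirm it before the protocol counts as complete. No other
#' descriptor kind is carried forward.
#'
#' @param protocol A `structured_protocol`.
#' @param enabled Set `FALSE` to return the protocol unchanged.
#' @return The protocol with inferred entities added.
#' @export
infer_carry_forward <- function(protocol, enabled = TRUE) {
  if (!enabled) return(protocol)
  last_entity <- NULL
  last_entity_step <- NA_integer_
  for (i in seq_along(protocol$steps)) {
    step <- protocol$steps[[i]]
    ents <- Filter(function(d) d$kind == "biochemical_entity", step$descriptors)
    if (length(ents)) {
      last_entity <- ents[[1L]]
      last_entity_step <- step$step_index
      next
    }
    if ("biochemical_entity" %in% step$missing_essential && !is.null(last_entity)) {
      inf <- last_entity
      inf$provenance <- "inferred"
      inf$confirmed <- FALSE
      inf$start <- NA_integer_
      inf$end <- NA_integer_
      step$descriptors <- c(step$descriptors, list(inf))
      step$missing_essential <- setdiff(step$missing_essential,
                                        "biochemical_entity")
      step$notes <- c(step$notes, sprintf(
        "biochemical entity '%s' inferred from step %d; awaiting confirmation",
        inf$value, last_entity_step
      ))
      protocol$steps[[i]] <- step
    }
  }
  protocol
}

new_structured_protocol <- function(steps, unmatched, substitutions,
                                    title = NA_character_,
                                    source = NA_character_) {
  for (i in seq_along(steps)) steps[[i]]$step_index <- i
  structure(
    list(
      title = title, source = source, steps = steps,
      unmatched = unmatched, substitutions = substitutions
    ),
    class = "structured_protocol"
  )
}

#' Translate a plain-text protocol into structured form
#'
#' Runs the full pipeline: text normalization, abbreviation expansion,
#' sentence splitting, action identification, descriptor extraction and
#' (optionally) carry-forward inference of missing participants. The
#' pipeline is deterministic: identical inputs give identical output.
#'
#' @param text The protocol text (UTF-8).
#' @param catalog,config,clues Reference model, lab config, clue table.
#' @param carry_forward Infer missing participants from preceding steps?
#' @param title,source Optional provenance metadata.
#' @return A `structured_protocol`: ordered steps (`action_instance`s with
#'   1-based `step_index`), `unmatched` sentences and the abbreviation
#'   substitution log.
#' @examples
#' p <- translate_protocol("Adjust to 10% TCA. Incubate at 30°C overnight.")
#' p$steps[[2]]$missing_essential
#' @export
translate_protocol <- function(text, catalog = load_catalog(),
                               config = load_lab_config(),
                               clues = clue_table(),
                               carry_forward = TRUE,
                               title = NA_character_,
                               source = NA_character_) {
  doc <- normalize_text(text)
  ex <- expand_abbreviations(doc, config)
  sentences <- split_sentences(ex$text)
  instances <- identify_actions(sentences, catalog)
  steps <- lapply(instances, extract_descriptors,
                  catalog = catalog, config = config, clues = clues)
  protocol <- new_structured_protocol(
    steps, attr(instances, "unmatched"), ex$substitutions,
    title = title, source = source
  )
  infer_carry_forward(protocol, enabled = carry_forward)
}

protocol_step_kinds <- function(step, provenance = NULL) {
  ds <- step$descriptors
  if (!is.null(provenance)) {
    ds <- Filter(function(d) d$provenance %in% provenance, ds)
  }
  unique(vapply(ds, `[[`, "", "kind"))
}

#' Serialize a structured protocol to JSON
#'
#' Emits the machine-amenable format documented in
#' `protocol.schema.json`: per step the action (id + label), descriptor
#' values with relation, unit and entity IDs, provenance flags, the source
#' sentence and notes; plus unmatched sentences.
#'
#' @param protocol A `structured_protocol`.
#' @param path Optional file to write to.
#' @param pretty Pretty-print?
#' @return The JSON string (invisibly when `path` is given).
#' @export
protocol_to_json <- function(protocol, path = NULL, pretty = TRUE) {
  step_obj <- function(s) {
    list(
      step_index = s$step_index,
      action = list(id = s$action_id, label = s$action_label),
      descriptors = lapply(s$descriptors, function(d) {
        list(
          kind = d$kind, relation = d$relation, value = d$value,
          magnitude = if (is.na(d$magnitude)) NULL else d$magnitude,
          unit = if (is.na(d$unit)) NULL else d$unit,
          unit_id = if (is.na(d$unit_id)) NULL else d$unit_id,
          entity_id = if (is.na(d$entity_id)) NULL else {
            list(source = d$entity_source, value = d$entity_id)
          },
          provenance = d$provenance, confirmed = d$confirmed,
          essential = d$essential
        )
      }),
      missing_essential = as.list(s$missing_essential),
      source_sentence = s$sentence,
      sentence_index = s$sentence_index,
      notes = as.list(s$notes)
    )
  }
  obj <- list(
    title = if (is.na(protocol$title)) NULL else protocol$title,
    provenance = list(
      source = if (is.na(protocol$source)) NULL else protocol$source
    ),
    steps = lapply(protocol$steps, step_obj),
    unmatched = lapply(seq_len(nrow(protocol$unmatched)), function(i) {
      list(
        sentence_index = protocol$unmatched$sentence_index[i],
        text = protocol$unmatched$text[i]
      )
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = pretty,
                           null = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

#' @export
print.structured_protocol <- function(x, ...) {
  cat(sprintf(
    "<structured_protocol> %d step(s), %d unmatched sentence(s)\n",
    length(x$steps), nrow(x$unmatched)
  ))
  for (s in x$steps) {
    miss <- if (length(s$missing_essential)) {
      paste0(" | missing: ", paste(s$missing_essential, collapse = ", "))
    } else ""
    cat(sprintf(
      "  %d. %s [%s] %d descriptor(s)%s\n",
      s$step_index, s$action_label, s$action_id, length(s$descriptors), miss
    ))
  }
  invisible(x)
}

#' @export
print.action_instance <- function(x, ...) {
  cat(sprintf("<action_instance> %s [%s] sentence %d\n",
              x$action_label, x$action_id, x$sentence_index))
  for (d in x$descriptors) {
    cat(sprintf("  %s (%s, %s): %s\n", d$kind, d$relation, d$provenance,
                d$value))
  }
  if (length(x$missing_essential)) {
    cat("  missing essential:", paste(x$missing_essential, collapse = ", "), "\n")
  }
  invisible(x)
}
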
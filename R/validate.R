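#' Check a structured protocol for completeness
#'
#' A protocol is reproducible as written only when every step records a
#' value for each essential descriptor of its action. The report lists,
#' per step, the essential kinds still missing, the inferred values that
#' await user confirmation, and any unknown unit symbols; overall status
#' is `complete` exactly when no step misses an essential value and no
#' inferred essential value is unconfirmed. Unmatched sentences persist as
#' free-text notes and do not block completeness.
#'
#' @param protocol A `structured_protocol`.
#' @param catalog The catalog the protocol was translated against.
#' @return A `validation_report`: list with `status`
#'   (`"complete"`/`"incomplete"`) and `steps` (tibble: `step_index`,
#'   `action_id`, `action_label`, list-columns `missing`, `unconfirmed`,
#'   `unknown_units`), plus the `unmatched` sentences.
#' @examples
#' p <- translate_protocol("Adjust to 10% TCA. Incubate at 30°C overnight.")
#' check_completeness(p, load_catalog())$status
#' @export
check_completeness <- function(protocol, catalog) {
  if (!inherits(protocol, "structured_protocol")) {
    ps_abort("`protocol` must be a structured_protocol")
  }
  rows <- lapply(protocol$steps, function(s) {
    action <- catalog_action_by_id(s$action_id, catalog)
    if (is.null(action)) {
      ps_abort(
        sprintf("step %d references action id %s absent from catalog",
                s$step_index, s$action_id),
        "protsem_validation_error"
      )
    }
    unconfirmed <- vapply(
      Filter(
        function(d) d$essential && d$provenance == "inferred" && !d$confirmed,
        s$descriptors
      ),
      `[[`, "", "kind"
    )
    tibble::tibble(
      step_index = s$step_index,
      action_id = s$action_id,
      action_label = s$action_label,
      missing = list(s$missing_essential),
      unconfirmed = list(unique(unconfirmed)),
      unknown_units = list(s$unknown_units)
    )
  })
  steps <- if (length(rows)) do.call(rbind, rows) else tibble::tibble(
    step_index = integer(), action_id = character(),
    action_label = character(), missing = list(), unconfirmed = list(),
    unknown_units = list()
  )
  incomplete <- any(lengths(steps$missing) > 0L) ||
    any(lengths(steps$unconfirmed) > 0L)
  structure(
    list(
      status = if (incomplete) "incomplete" else "complete",
      steps = steps,
      unmatched = protocol$unmatched
    ),
    class = "validation_report"
  )
}

#' Apply user answers and confirmations to a protocol
#'
#' Batch counterpart of the interactive "ask the user for missing
#' descriptors" step. Each answer targets a `(step_index, kind)` pair: for
#' a kind with an unconfirmed inferred value the answer confirms it (and
#' may replace the value); otherwise a new descriptor is inserted with
#' provenance `user`. Answers never remove extracted values, so applying
#' answers is a monotone completion. An answer for a kind the step's
#' action does not allow is rejected.
#'
#' @param protocol A `structured_protocol`.
#' @param answers A data frame with columns `step_index`, `kind`, `value`
#'   (`value = NA` confirms an inferred descriptor without changing it).
#' @param catalog,clues Catalog and clue table (quantity answers such as
#'   `"37 °C"` are parsed into magnitude + unit).
#' @return The updated protocol.
#' @examples
#' p <- translate_protocol("Adjust to 10% TCA. Incubate at 30°C overnight.")
#' p <- apply_user_answers(
#'   p, data.frame(step_index = 2, kind = "condition", value = "with shaking")
#' )
#' @export
apply_user_answers <- function(protocol, answers, catalog = load_catalog(),
                               clues = clue_table()) {
  if (!is.data.frame(answers)) {
    ps_abort("`answers` must be a data frame with step_index, kind, value")
  }
  if (!nrow(answers)) return(protocol)
  for (r in seq_len(nrow(answers))) {
    si <- answers$step_index[r]
    kind <- answers$kind[r]
    value <- if ("value" %in% names(answers)) answers$value[r] else NA
    pos <- which(vapply(protocol$steps, `[[`, 1L, "step_index") == si)
    if (!length(pos)) {
      ps_abort(sprintf("answer targets nonexistent step %s", si))
    }
    step <- protocol$steps[[pos]]
    action <- catalog_action_by_id(step$action_id, catalog)
    req <- descriptor_requirements(action)
    allowed <- c(req$essential, req$optional)
    if (!(kind %in% allowed)) {
      ps_abort(
        sprintf(
          "descriptor kind '%s' is not allowed for action '%s' (allowed: %s)",
          kind, action$label, paste(allowed, collapse = ", ")
        ),
        "protsem_validation_error"
      )
    }
    existing <- which(vapply(
      step$descriptors,
      function(d) d$kind == kind && d$provenance == "inferred" && !d$confirmed,
      logical(1)
    ))
    if (length(existing)) {
      d <- step$descriptors[[existing[1L]]]
      d$provenance <- "user"
      d$confirmed <- TRUE
      if (!is.na(value) && nzchar(value)) d$value <- as.character(value)
      step$descriptors[[existing[1L]]] <- d
    } else {
      if (is.na(value) || !nzchar(value)) {
        ps_abort(sprintf(
          "answer for step %s kind '%s' has no value and nothing to confirm",
          si, kind
        ))
      }
      value <- as.character(value)
      d <- if (kind_value_class(kind) == "quantity") {
        q <- parse_quantity(value, clues)
        if (!is.null(q)) {
          new_descriptor(kind, value = value, magnitude = q$magnitude,
                         unit = q$unit, unit_id = q$unit_id,
                         provenance = "user",
                         essential = kind %in% req$essential)
        } else {
          new_descriptor(kind, value = value, provenance = "user",
                         essential = kind %in% req$essential)
        }
      } else {
        new_descriptor(kind, value = value, provenance = "user",
                       essential = kind %in% req$essential)
      }
      step$descriptors <- c(step$descriptors, list(d))
    }
    step$missing_essential <- setdiff(step$missing_essential, kind)
    protocol$steps[[pos]] <- step
  }
  protocol
}

#' Turn manual verb mappings into catalog update suggestions
#'
#' When a user maps an unmatched verb to a catalog action by hand, the
#' mapping is worth preserving as a new synonym (and likewise for new clue
#' patterns). This function emits suggestion records for manual curation;
#' it never mutates the catalog.
#'
#' @param protocol The protocol the corrections refer to.
#' @param corrections A data frame with columns `verb` and `action`
#'   (action label or id); optionally rows with `pattern` and `kind` for
#'   clue suggestions.
#' @param catalog The catalog.
#' @return A tibble of suggestions: `type` (`new_synonym`, `new_clue` or
#'   `no_op`), `verb`, `action_id`, `action_label`, `note`.
#' @export
record_update_suggestions <- function(protocol, corrections,
                                      catalog = load_catalog()) {
  empty <- tibble::tibble(
    type = character(), verb = character(), action_id = character(),
    action_label = character(), note = character()
  )
  if (is.null(corrections) || !nrow(corrections)) return(empty)
  rows <- list()
  for (r in seq_len(nrow(corrections))) {
    verb <- corrections$verb[r]
    target <- corrections$action[r]
    act <- catalog_action_by_id(target, catalog) %||%
      match_action_verb(target, catalog)
    if (is.null(act)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        type = "no_op", verb = verb, action_id = NA_character_,
        action_label = NA_character_,
        note = sprintf("target action '%s' not found in catalog", target)
      )
      next
    }
    if (verb %in% catalog_verb_lexicon(catalog)) {
      owner <- match_action_verb(verb, catalog)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        type = "no_op", verb = verb, action_id = owner$id,
        action_label = owner$label,
        note = sprintf("verb '%s' already maps to %s", verb, owner$id)
      )
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        type = "new_synonym", verb = verb, action_id = act$id,
        action_label = act$label,
        note = sprintf("add '%s' as synonym of '%s'", verb, act$label)
      )
    }
  }
  do.call(rbind, rows)
}

#' Serialize a validation report
#'
#' @param report A `validation_report`.
#' @param path Optional file to write JSON to.
#' @return JSON string (invisibly when `path` given).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    status = report$status,
    steps = lapply(seq_len(nrow(report$steps)), function(i) {
      list(
        step_index = report$steps$step_index[i],
        action_id = report$steps$action_id[i],
        action_label = report$steps$action_label[i],
        missing_essential = as.list(report$steps$missing[[i]]),
        unconfirmed_inferred = as.list(report$steps$unconfirmed[[i]]),
        unknown_units = as.list(report$steps$unknown_units[[i]])
      )
    }),
    unmatched = as.list(report$unmatched$sentence_index)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(json))
  }
  json
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> status: %s\n", x$status))
  for (i in seq_len(nrow(x$steps))) {
    miss <- x$steps$missing[[i]]
    unc <- x$steps$unconfirmed[[i]]
    if (!length(miss) && !length(unc)) next
    cat(sprintf(
      "  step %d (%s):%s%s\n",
      x$steps$step_index[i], x$steps$action_label[i],
      if (length(miss)) paste0(" missing ", paste(miss, collapse = ", ")) else "",
      if (length(unc)) paste0(" unconfirmed ", paste(unc, collapse = ", ")) else ""
    ))
  }
  if (nrow(x$unmatched)) {
    cat(sprintf("  %d unmatched sentence(s) kept as notes\n", nrow(x$unmatched)))
  }
  invisible(x)
}
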
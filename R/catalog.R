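#' Load and validate an experimental-action catalog
#'
#' The catalog is the reference model for protocol translation: one entry
#' per experimental action (accession id, verb label, synonyms, definition,
#' essential and optional descriptor kinds, optional external-ontology
#' mapping, provenance) plus MIREOT records for externally imported terms.
#' The bundled catalog holds 87 actions: 33 carried over from the previous
#' catalog version (`legacy`), 51 added in the current version
#' (`added_v2`) and 3 imported from OBI (`imported_obi`).
#'
#' @param path Path to a catalog YAML file; the bundled catalog by default.
#' @return A validated `action_catalog`: list with `actions` (tibble),
#'   `imported_terms` (tibble) and `version`.
#' @seealso [match_action_verb()], [descriptor_requirements()],
#'   [catalog_stats()], [export_catalog_obo()]
#' @examples
#' cat2 <- load_catalog()
#' catalog_stats(cat2)
#' @export
load_catalog <- function(path = ps_extdata("action_catalog.yaml")) {
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      ps_abort(
        sprintf("cannot parse catalog '%s': %s", path, conditionMessage(e)),
        "protsem_format_error"
      )
    }
  )
  if (!("actions" %in% names(raw))) {
    ps_abort(sprintf("catalog '%s' has no `actions` section", path),
             "protsem_format_error")
  }
  std_optional <- setdiff(
    c("equipment", "temperature", "period", "volume", "speed",
      "concentration", "condition", "goal", "protocol_method"),
    character()
  )
  parse_action <- function(a) {
    for (f in c("id", "label", "provenance")) {
      if (is.null(a[[f]])) {
        ps_abort(sprintf("catalog action missing required field `%s`", f),
                 "protsem_format_error")
      }
    }
    essential <- as.character(unlist(a$essential %||% "biochemical_entity"))
    optional <- as.character(
      unlist(a$optional %||% setdiff(std_optional, essential))
    )
    tibble::tibble(
      id = a$id,
      label = a$label,
      definition = a$definition %||% "",
      synonyms = list(as.character(unlist(a$synonyms %||% character()))),
      essential = list(essential),
      optional = list(optional),
      external_mapping = a$external_mapping %||% NA_character_,
      provenance = a$provenance
    )
  }
  actions <- if (length(raw$actions)) {
    do.call(rbind, lapply(raw$actions, parse_action))
  } else {
    tibble::tibble(
      id = character(), label = character(), definition = character(),
      synonyms = list(), essential = list(), optional = list(),
      external_mapping = character(), provenance = character()
    )
  }
  terms <- raw$imported_terms %||% list()
  imported_terms <- tibble::tibble(
    source_ontology = vapply(terms, function(t) t$source_ontology %||% "", ""),
    term = vapply(terms, function(t) t$term %||% "", ""),
    target_superclass = vapply(terms, function(t) t$target_superclass %||% "", ""),
    label = vapply(terms, function(t) t$label %||% NA_character_, "")
  )
  catalog <- structure(
    list(
      actions = actions,
      imported_terms = imported_terms,
      version = as.character(raw$version %||% "unversioned")
    ),
    class = "action_catalog"
  )
  validate_catalog(catalog)
  catalog
}

validate_catalog <- function(catalog) {
  a <- catalog$actions
  fail <- function(msg) ps_abort(msg, "protsem_validation_error")

  bad_id <- a$id[!grepl("^EXACT2_\\d{6}$", a$id)]
  if (length(bad_id)) {
    fail(sprintf("malformed action id(s): %s", paste(bad_id, collapse = ", ")))
  }
  if (anyDuplicated(a$id)) {
    fail(sprintf("duplicate action id(s): %s",
                 paste(unique(a$id[duplicated(a$id)]), collapse = ", ")))
  }
  verbs <- c(a$label, unlist(a$synonyms))
  if (anyDuplicated(verbs)) {
    dup <- unique(verbs[duplicated(verbs)])
    owners <- a$id[vapply(
      seq_len(nrow(a)),
      function(i) any(c(a$label[i], a$synonyms[[i]]) %in% dup),
      logical(1)
    )]
    fail(sprintf(
      "verb(s) %s mapped to more than one action (%s)",
      paste0("'", dup, "'", collapse = ", "),
      paste(owners, collapse = ", ")
    ))
  }
  bad_prov <- setdiff(unique(a$provenance),
                      c("legacy", "added_v2", "imported_obi"))
  if (length(bad_prov)) {
    fail(sprintf("unknown provenance value(s): %s",
                 paste(bad_prov, collapse = ", ")))
  }
  for (i in seq_len(nrow(a))) {
    assert_known_kinds(c(a$essential[[i]], a$optional[[i]]),
                       sprintf("action %s", a$id[i]))
    both <- intersect(a$essential[[i]], a$optional[[i]])
    if (length(both)) {
      fail(sprintf(
        "action %s lists kind(s) %s as both essential and optional",
        a$id[i], paste(both, collapse = ", ")
      ))
    }
  }
  if (nrow(a) >= 100L) {
    fail(sprintf("catalog has %d actions; the action inventory must stay below 100",
                 nrow(a)))
  }
  t <- catalog$imported_terms
  incomplete <- !nzchar(t$source_ontology) | !nzchar(t$term) |
    !nzchar(t$target_superclass)
  if (any(incomplete)) {
    fail(sprintf(
      "MIREOT record(s) incomplete (need source ontology, term and target superclass URIs): %s",
      paste(t$term[incomplete], collapse = ", ")
    ))
  }
  invisible(catalog)
}

catalog_verb_lexicon <- function(catalog) {
  c(catalog$actions$label, unlist(catalog$actions$synonyms))
}

as_experimental_action <- function(catalog, i) {
  a <- catalog$actions
  structure(
    list(
      id = a$id[i], label = a$label[i], definition = a$definition[i],
      synonyms = a$synonyms[[i]], essential = a$essential[[i]],
      optional = a$optional[[i]], external_mapping = a$external_mapping[i],
      provenance = a$provenance[i]
    ),
    class = "experimental_action"
  )
}

#' Match a verb lemma against the action catalog
#'
#' Looks the lowercase lemma up among catalog labels and synonyms. Catalog
#' validation guarantees that a verb maps to at most one action, so the
#' match is unique; an absent verb is a valid "no match" outcome.
#'
#' @param verb_lemma Lowercase verb lemma (see [lemmatize_verb()]).
#' @param catalog An [load_catalog()] result.
#' @return An `experimental_action` (list with id, label, descriptors, ...)
#'   or `NULL` when no action carries the verb.
#' @examples
#' match_action_verb("incubate", load_catalog())$id
#' @export
match_action_verb <- function(verb_lemma, catalog) {
  assert_string(verb_lemma, "verb_lemma")
  a <- catalog$actions
  i <- match(verb_lemma, a$label)
  if (is.na(i)) {
    hits <- which(vapply(a$synonyms, function(s) verb_lemma %in% s, logical(1)))
    if (!length(hits)) return(NULL)
    i <- hits[1L]
  }
  as_experimental_action(catalog, i)
}

catalog_action_by_id <- function(id, catalog) {
  i <- match(id, catalog$actions$id)
  if (is.na(i)) return(NULL)
  as_experimental_action(catalog, i)
}

#' Essential and optional descriptor kinds of an action
#'
#' @param action An `experimental_action` from [match_action_verb()].
#' @return A list with character vectors `essential` and `optional`; the
#'   two sets are disjoint by catalog validation.
#' @examples
#' cat2 <- load_catalog()
#' descriptor_requirements(match_action_verb("store", cat2))$essential
#' @export
descriptor_requirements <- function(action) {
  if (!inherits(action, "experimental_action")) {
    ps_abort("`action` must be an experimental_action (see match_action_verb)")
  }
  list(essential = action$essential, optional = action$optional)
}

#' Provenance breakdown of a catalog
#'
#' @param catalog An `action_catalog`.
#' @return Named integer vector with counts for `legacy`, `added_v2`,
#'   `imported_obi` and `total`.
#' @examples
#' catalog_stats(load_catalog())
#' @export
catalog_stats <- function(catalog) {
  prov <- factor(catalog$actions$provenance,
                 levels = c("legacy", "added_v2", "imported_obi"))
  counts <- table(prov)
  out <- c(as.integer(counts), nrow(catalog$actions))
  names(out) <- c(levels(prov), "total")
  out
}

#' Export a catalog as OBO-like flat text
#'
#' Writes one `[Term]` stanza per action (id, name, def, synonym, xref,
#' provenance) for interoperability with OBO tooling. This is a flat
#' lexical export; description-logic semantics are out of scope.
#'
#' @param catalog An `action_catalog`.
#' @param path Optional output file; when `NULL` the text is returned only.
#' @return The OBO text, invisibly when `path` is given.
#' @export
export_catalog_obo <- function(catalog, path = NULL) {
  a <- catalog$actions
  stanza <- function(i) {
    lines <- c(
      "[Term]",
      paste0("id: ", sub("_", ":", a$id[i])),
      paste0("name: ", a$label[i])
    )
    if (nzchar(a$definition[i])) {
      lines <- c(lines, sprintf("def: \"%s\" []", a$definition[i]))
    }
    for (s in a$synonyms[[i]]) {
      lines <- c(lines, sprintf("synonym: \"%s\" EXACT []", s))
    }
    if (!is.na(a$external_mapping[i])) {
      lines <- c(lines, paste0("xref: ", a$external_mapping[i]))
    }
    c(lines, paste0("property_value: provenance ", a$provenance[i]), "")
  }
  txt <- paste(
    c(
      "format-version: 1.2",
      paste0("data-version: ", catalog$version),
      "",
      unlist(lapply(seq_len(nrow(a)), stanza))
    ),
    collapse = "\n"
  )
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.action_catalog <- function(x, ...) {
  s <- catalog_stats(x)
  cat(sprintf(
    "<action_catalog> version %s: %d actions (%d legacy, %d added_v2, %d imported_obi), %d imported terms\n",
    x$version, s[["total"]], s[["legacy"]], s[["added_v2"]],
    s[["imported_obi"]], nrow(x$imported_terms)
  ))
  invisible(x)
}

#' @export
print.experimental_action <- function(x, ...) {
  cat(sprintf("<experimental_action> %s: %s\n", x$id, x$label))
  if (length(x$synonyms)) {
    cat("  synonyms:", paste(x$synonyms, collapse = ", "), "\n")
  }
  cat("  essential:", paste(x$essential, collapse = ", "), "\n")
  cat("  optional:", paste(x$optional, collapse = ", "), "\n")
  invisible(x)
}
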
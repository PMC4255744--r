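#' Load a laboratory configuration
#'
#' A lab configuration carries the lab-specific dictionaries consulted
#' during translation: the equipment list, the biochemical-entity
#' dictionary with external IDs (PubChem, ChEBI, UniProt or lab-internal),
#' the abbreviation table (e.g. `DMSO` = "Dimethylsulfoxide") and the
#' default-settings table that resolves ambiguous tokens to quantities
#' (e.g. `ON` = 16 h, `RT` = 22 °C). Missing sections default to empty.
#'
#' @param path Path to a config YAML file; a bundled example by default.
#' @param clues A [clue_table()], used to parse default-setting quantities.
#' @return A validated `lab_config`: list with tibbles `equipment` and
#'   `entities` (columns `name`, `aliases`, `id_source`, `id_value`),
#'   named character vector `abbreviations`, and `defaults` (a named list
#'   of quantities: `magnitude`, `unit`, `unit_id`, `kind`).
#' @examples
#' cfg <- load_lab_config()
#' cfg$defaults$overnight
#' @export
load_lab_config <- function(path = ps_extdata("lab_config.yaml"),
                            clues = clue_table()) {
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      msg <- conditionMessage(e)
      cls <- if (grepl("[Dd]uplicate", msg)) "protsem_validation_error"
             else "protsem_format_error"
      ps_abort(sprintf("cannot parse lab config '%s': %s", path, msg), cls)
    }
  )
  raw <- raw %||% list()

  parse_records <- function(recs, section) {
    recs <- recs %||% list()
    out <- tibble::tibble(
      name = vapply(recs, function(r) r$name %||% "", ""),
      aliases = lapply(recs, function(r) as.character(unlist(r$aliases %||% character()))),
      id_source = vapply(recs, function(r) r$id_source %||% NA_character_, ""),
      id_value = vapply(recs, function(r) r$id_value %||% NA_character_, "")
    )
    if (any(!nzchar(out$name))) {
      ps_abort(sprintf("%s record without a name", section),
               "protsem_format_error")
    }
    if (anyDuplicated(tolower(out$name))) {
      ps_abort(sprintf("duplicate %s names", section),
               "protsem_validation_error")
    }
    bad <- !is.na(out$id_source) & (is.na(out$id_value) | !nzchar(out$id_value))
    if (any(bad)) {
      ps_abort(
        sprintf("%s record(s) with id_source but empty id_value: %s",
                section, paste(out$name[bad], collapse = ", ")),
        "protsem_validation_error"
      )
    }
    out
  }

  abbr_raw <- raw$abbreviations %||% list()
  abbreviations <- vapply(abbr_raw, function(x) {
    if (!is.character(x) && !is.numeric(x)) {
      ps_abort("abbreviation expansions must be strings", "protsem_format_error")
    }
    as.character(x)
  }, "")
  if (anyDuplicated(names(abbreviations))) {
    ps_abort("duplicate abbreviation keys", "protsem_validation_error")
  }

  defaults_raw <- raw$defaults %||% list()
  defaults <- lapply(names(defaults_raw), function(key) {
    q <- parse_quantity(as.character(defaults_raw[[key]]), clues)
    if (is.null(q)) {
      ps_abort(
        sprintf("default setting '%s' = '%s' is not a number with a known unit",
                key, defaults_raw[[key]]),
        "protsem_format_error"
      )
    }
    q
  })
  names(defaults) <- names(defaults_raw)

  structure(
    list(
      equipment = parse_records(raw$equipment, "equipment"),
      entities = parse_records(raw$entities, "entities"),
      abbreviations = abbreviations,
      defaults = defaults
    ),
    class = "lab_config"
  )
}

#' Parse a quantity string ("16 h", "22 °C")
#'
#' @param x A string containing exactly one number--unit pair.
#' @param clues A [clue_table()].
#' @return A quantity (list: `magnitude`, `unit`, `unit_id`, `kind`) or
#'   `NULL` when `x` does not contain exactly one known quantity.
#' @export
parse_quantity <- function(x, clues = clue_table()) {
  q <- find_quantities(normalize_text(x), clues)
  if (nrow(q) != 1L || !q$known) return(NULL)
  list(
    magnitude = q$magnitude, unit = q$unit_symbol,
    unit_id = q$unit_id, kind = q$kind_hint
  )
}

#' Expand lab abbreviations in text
#'
#' Replaces every whole-token, case-sensitive occurrence of an
#' abbreviation key by its expansion (`TCA` -> `Trichloroacetic acid`). A
#' key never fires inside a longer token (`ON` does not match inside
#' `CONICAL`). The substitution log records both the original and the
#' expanded spans, so the original text can be reconstructed exactly.
#'
#' @param text Input text.
#' @param config A [load_lab_config()] result.
#' @return A list with `text` (expanded) and `substitutions` (tibble:
#'   `abbreviation`, `expansion`, `start`, `end` in the original text,
#'   `new_start`, `new_end` in the expanded text; 0-based half-open).
#' @examples
#' expand_abbreviations("Adjust to 10% TCA.", load_lab_config())$text
#' @export
expand_abbreviations <- function(text, config) {
  assert_string(text, "text")
  abbr <- config$abbreviations
  log0 <- tibble::tibble(
    abbreviation = character(), expansion = character(),
    start = integer(), end = integer(),
    new_start = integer(), new_end = integer()
  )
  if (!length(abbr)) return(list(text = text, substitutions = log0))

  hits <- list()
  for (key in names(abbr)) {
    pat <- sprintf("(?<![A-Za-z0-9])%s(?![A-Za-z0-9])", regex_escape(key))
    m <- gregexpr(pat, text, perl = TRUE)[[1]]
    if (m[1L] == -1L) next
    for (j in seq_along(m)) {
      hits[[length(hits) + 1L]] <- list(
        start = as.integer(m[j]), len = attr(m, "match.length")[j], key = key
      )
    }
  }
  if (!length(hits)) return(list(text = text, substitutions = log0))

  ord <- order(
    vapply(hits, `[[`, 1L, "start"),
    -vapply(hits, `[[`, 1L, "len")
  )
  hits <- hits[ord]
  # drop overlapping matches (longest-leftmost wins)
  kept <- list()
  last_end <- 0L
  for (h in hits) {
    if (h$start > last_end) {
      kept[[length(kept) + 1L]] <- h
      last_end <- h$start + h$len - 1L
    }
  }

  pieces <- character()
  rows <- list()
  cursor <- 1L
  new_len <- 0L
  for (h in kept) {
    pre <- substr(text, cursor, h$start - 1L)
    exp <- abbr[[h$key]]
    pieces <- c(pieces, pre, exp)
    new_start <- new_len + nchar(pre)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      abbreviation = h$key, expansion = exp,
      start = h$start - 1L, end = h$start - 1L + h$len,
      new_start = new_start, new_end = new_start + nchar(exp)
    )
    new_len <- new_start + nchar(exp)
    cursor <- h$start + h$len
  }
  pieces <- c(pieces, substr(text, cursor, nchar(text)))
  list(text = paste(pieces, collapse = ""), substitutions = do.call(rbind, rows))
}

#' Resolve a surface form against the entity/equipment dictionaries
#'
#' Case-insensitive exact match against canonical names and aliases.
#'
#' @param surface The surface string.
#' @param config A [load_lab_config()] result.
#' @param type Which dictionary to search: biochemical entities, equipment,
#'   or both (entities first).
#' @return A list (`name`, `aliases`, `id_source`, `id_value`, `type`) or
#'   `NULL` when nothing matches.
#' @examples
#' resolve_entity("trichloroacetic ACID", load_lab_config())$id_value
#' @export
resolve_entity <- function(surface, config, type = c("any", "entity", "equipment")) {
  assert_string(surface, "surface")
  type <- match.arg(type)
  key <- tolower(trimws(surface))
  search <- function(tbl, label) {
    for (i in seq_len(nrow(tbl))) {
      if (key == tolower(tbl$name[i]) || key %in% tolower(tbl$aliases[[i]])) {
        return(list(
          name = tbl$name[i], aliases = tbl$aliases[[i]],
          id_source = tbl$id_source[i], id_value = tbl$id_value[i],
          type = label
        ))
      }
    }
    NULL
  }
  if (type %in% c("any", "entity")) {
    hit <- search(config$entities, "entity")
    if (!is.null(hit)) return(hit)
  }
  if (type %in% c("any", "equipment")) {
    hit <- search(config$equipment, "equipment")
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Resolve a default-setting token to a quantity
#'
#' Looks the token up in the defaults table, case-insensitively. An
#' abbreviation is first expanded, so `RT` and `room temperature` (and
#' likewise `ON` and `overnight`) resolve to the same default.
#'
#' @param token The token (e.g. `"overnight"`, `"RT"`).
#' @param config A [load_lab_config()] result.
#' @return A quantity (`magnitude`, `unit`, `unit_id`, `kind`) or `NULL`.
#' @examples
#' resolve_default("RT", load_lab_config())
#' @export
resolve_default <- function(token, config) {
  assert_string(token, "token")
  keys <- names(config$defaults)
  hit <- match(tolower(trimws(token)), tolower(keys))
  if (!is.na(hit)) return(config$defaults[[hit]])
  exp <- config$abbreviations[match(token, names(config$abbreviations))]
  if (!is.na(exp)) {
    hit <- match(tolower(exp), tolower(keys))
    if (!is.na(hit)) return(config$defaults[[hit]])
  }
  NULL
}

#' @export
print.lab_config <- function(x, ...) {
  cat(sprintf(
    "<lab_config> %d equipment, %d entities, %d abbreviations, %d defaults\n",
    nrow(x$equipment), nrow(x$entities), length(x$abbreviations),
    length(x$defaults)
  ))
  invisible(x)
}
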
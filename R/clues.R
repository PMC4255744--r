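#' Load the semantic-clue table
#'
#' The clue table lists the lexical triggers used to recognise descriptor
#' values in protocol text: number--unit pairs for quantity descriptors
#' (each unit mapped to a descriptor kind and, where available, a Units
#' Ontology accession) plus the cue phrases for `goal`, `condition` and
#' `protocol_method`. It is shipped as a versioned YAML file so the clue
#' inventory can be curated independently of the code.
#'
#' @param path Path to a clue YAML file; the bundled table by default.
#' @return An object of class `clue_table`: a list with elements `units`
#'   (tibble: `symbol`, `kind`, `unit_id`, `word`), `goal_cues`,
#'   `condition_cues`, `protocol_method_cues` and `version`.
#' @examples
#' clues <- clue_table()
#' clues$units[clues$units$kind == "temperature", ]
#' @export
clue_table <- function(path = ps_extdata("clues.yaml")) {
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      ps_abort(
        sprintf("cannot parse clue table '%s': %s", path, conditionMessage(e)),
        "protsem_format_error"
      )
    }
  )
  units <- tibble::tibble(
    symbol = vapply(raw$units, `[[`, "", "symbol"),
    kind = vapply(raw$units, `[[`, "", "kind"),
    unit_id = vapply(raw$units, function(u) u$unit_id %||% "", ""),
    word = vapply(raw$units, `[[`, TRUE, "word")
  )
  units$unit_id[!nzchar(units$unit_id)] <- NA_character_
  assert_known_kinds(units$kind, "clue table")
  if (anyDuplicated(units$symbol)) {
    ps_abort("duplicate unit symbols in clue table", "protsem_validation_error")
  }
  structure(
    list(
      units = units,
      goal_cues = as.character(raw$goal_cues %||% character()),
      condition_cues = as.character(raw$condition_cues %||% character()),
      protocol_method_cues = as.character(raw$protocol_method_cues %||% character()),
      version = raw$version %||% "unversioned"
    ),
    class = "clue_table"
  )
}

# Regex alternation over unit symbols, longest first so compound units
# (e.g. a mass/volume concentration) win over their suffixes. Word units
# accept an optional plural "s".
unit_alternation <- function(units) {
  units <- units[order(-nchar(units$symbol)), ]
  pats <- ifelse(
    units$word,
    paste0(regex_escape(units$symbol), "s?"),
    regex_escape(units$symbol)
  )
  paste(pats, collapse = "|")
}

lookup_unit <- function(symbol, units) {
  i <- match(symbol, units$symbol)
  if (is.na(i)) i <- match(sub("s$", "", symbol), units$symbol)
  if (is.na(i)) return(NULL)
  as.list(units[i, ])
}
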
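#' Registry of descriptor kinds
#'
#' Every descriptor of an experimental action has a *kind* (temperature,
#' period, biochemical entity, ...). Each kind carries exactly one semantic
#' relation linking it to the action and one value class:
#'
#' * `is-participant-of` + `entity_ref`: `biochemical_entity`, `equipment`;
#' * `is-quality-of` + `quantity`: `temperature`, `volume`, `speed`,
#'   `concentration`;
#' * `is-proposition`: `period` and `time_point` (quantity-valued),
#'   `condition`, `goal`, `protocol_method` (text-valued).
#'
#' @return A tibble with columns `name`, `relation` and `value_class`.
#' @examples
#' descriptor_kinds()
#' @export
descriptor_kinds <- function() {
  tibble::tibble(
    name = c(
      "biochemical_entity", "equipment",
      "temperature", "volume", "speed", "concentration",
      "period", "condition", "goal", "protocol_method", "time_point"
    ),
    relation = c(
      "is-participant-of", "is-participant-of",
      "is-quality-of", "is-quality-of", "is-quality-of", "is-quality-of",
      "is-proposition", "is-proposition", "is-proposition", "is-proposition",
      "is-proposition"
    ),
    value_class = c(
      "entity_ref", "entity_ref",
      "quantity", "quantity", "quantity", "quantity",
      "quantity", "text", "text", "text", "quantity"
    )
  )
}

kind_relation <- function(kind) {
  reg <- descriptor_kinds()
  reg$relation[match(kind, reg$name)]
}

kind_value_class <- function(kind) {
  reg <- descriptor_kinds()
  reg$value_class[match(kind, reg$name)]
}

assert_known_kinds <- function(kinds, where) {
  bad <- setdiff(kinds, descriptor_kinds()$name)
  if (length(bad)) {
    ps_abort(
      sprintf(
        "unknown descriptor kind(s) %s in %s",
        paste0("'", bad, "'", collapse = ", "), where
      ),
      "protsem_validation_error"
    )
  }
  invisible(kinds)
}
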
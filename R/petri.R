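#' Compile a structured protocol into a Petri net
#'
#' Experimental actions become transitions; sequencing places chain them
#' (`P0 -> T1 -> P1 -> T2 -> ...`); each essential descriptor kind of a
#' step becomes a condition place connected to its transition by a pair of
#' self-loop arcs, so a satisfied condition persists across firing. The
#' initial marking puts one token on the start place and one token on each
#' condition place whose descriptor value is present (extracted, default,
#' user-supplied, or inferred *and confirmed*). A step with a missing
#' essential value therefore yields an unmarked condition place that
#' blocks its transition: the protocol deadlocks at the first
#' irreproducible step.
#'
#' @param protocol A non-empty `structured_protocol`.
#' @param catalog The catalog the protocol was translated against.
#' @return A `protocol_net`: list of tibbles `places` (`id`, `label`,
#'   `role`, `step_index`, `kind`), `transitions` (`id`, `label`,
#'   `step_index`, `action_id`), `arcs` (`source`, `target`, `weight`) and
#'   the named integer vector `marking`.
#' @examples
#' p <- translate_protocol("Adjust to 10% TCA. Incubate at 30°C overnight.")
#' net <- compile_net(p, load_catalog())
#' enabled_transitions(net)
#' @export
compile_net <- function(protocol, catalog) {
  if (!inherits(protocol, "structured_protocol")) {
    ps_abort("`protocol` must be a structured_protocol")
  }
  n <- length(protocol$steps)
  if (n == 0L) {
    ps_abort("cannot compile an empty protocol into a net",
             "protsem_usage_error")
  }
  places <- list(tibble::tibble(
    id = "P0", label = "start", role = "sequencing",
    step_index = 0L, kind = NA_character_
  ))
  transitions <- list()
  arcs <- list()
  marking <- c(P0 = 1L)

  add_arc <- function(source, target) {
    arcs[[length(arcs) + 1L]] <<- tibble::tibble(
      source = source, target = target, weight = 1L
    )
  }

  for (i in seq_len(n)) {
    step <- protocol$steps[[i]]
    action <- catalog_action_by_id(step$action_id, catalog)
    if (is.null(action)) {
      ps_abort(sprintf("step %d references unknown action %s",
                       i, step$action_id),
               "protsem_validation_error")
    }
    tid <- paste0("T", i)
    pid <- paste0("P", i)
    transitions[[i]] <- tibble::tibble(
      id = tid, label = action$label, step_index = i,
      action_id = action$id
    )
    places[[length(places) + 1L]] <- tibble::tibble(
      id = pid, label = sprintf("after step %d", i), role = "sequencing",
      step_index = i, kind = NA_character_
    )
    add_arc(paste0("P", i - 1L), tid)
    add_arc(tid, pid)
    marking[pid] <- 0L

    satisfied <- protocol_step_kinds(
      step, provenance = c("extracted", "default", "user")
    )
    confirmed_inferred <- unique(vapply(
      Filter(function(d) d$provenance == "inferred" && d$confirmed,
             step$descriptors),
      `[[`, "", "kind"
    ))
    satisfied <- union(satisfied, confirmed_inferred)
    for (kind in action$essential) {
      did <- sprintf("D%d_%s", i, kind)
      val <- Filter(function(d) d$kind == kind, step$descriptors)
      lab <- if (length(val)) {
        sprintf("%s: %s", kind, val[[1L]]$value)
      } else {
        sprintf("%s: ?", kind)
      }
      places[[length(places) + 1L]] <- tibble::tibble(
        id = did, label = lab, role = "descriptor_condition",
        step_index = i, kind = kind
      )
      add_arc(did, tid)
      add_arc(tid, did)
      marking[did] <- if (kind %in% satisfied) 1L else 0L
    }
  }

  net <- structure(
    list(
      places = do.call(rbind, places),
      transitions = do.call(rbind, transitions),
      arcs = do.call(rbind, arcs),
      marking = marking
    ),
    class = "protocol_net"
  )
  validate_net(net)
  net
}

validate_net <- function(net) {
  ids <- c(net$places$id, net$transitions$id)
  if (anyDuplicated(ids)) {
    ps_abort("duplicate node ids in net", "protsem_validation_error")
  }
  is_place <- net$arcs$source %in% net$places$id
  is_trans <- net$arcs$source %in% net$transitions$id
  tgt_place <- net$arcs$target %in% net$places$id
  tgt_trans <- net$arcs$target %in% net$transitions$id
  ok <- (is_place & tgt_trans) | (is_trans & tgt_place)
  if (!all(ok)) {
    ps_abort("net is not bipartite: arcs must connect a place and a transition",
             "protsem_validation_error")
  }
  if (any(net$arcs$weight < 1L)) {
    ps_abort("arc weights must be >= 1", "protsem_validation_error")
  }
  no_input <- setdiff(net$transitions$id, net$arcs$target)
  if (length(no_input)) {
    ps_abort(sprintf("transition(s) without input arc: %s",
                     paste(no_input, collapse = ", ")),
             "protsem_validation_error")
  }
  invisible(net)
}

#' Transitions enabled under a marking
#'
#' A transition is enabled when every input place holds at least as many
#' tokens as the connecting arc's weight.
#'
#' @param net A `protocol_net`.
#' @param marking A marking (named integer over place ids); the net's
#'   initial marking by default.
#' @return Character vector of enabled transition ids, in step order.
#' @export
enabled_transitions <- function(net, marking = net$marking) {
  ord <- net$transitions[order(net$transitions$step_index), ]
  enabled <- character()
  for (i in seq_len(nrow(ord))) {
    tid <- ord$id[i]
    inputs <- net$arcs[net$arcs$target == tid, ]
    if (all(marking[inputs$source] >= inputs$weight)) {
      enabled <- c(enabled, tid)
    }
  }
  enabled
}

#' Fire a transition
#'
#' Consumes tokens from the transition's input places and produces tokens
#' in its output places according to arc weights. Self-loop condition
#' places are consumed and immediately replenished, so their token count
#' is conserved.
#'
#' @param net A `protocol_net`.
#' @param marking The current marking (defaults to the initial marking).
#' @param transition_id Id of the transition to fire.
#' @return The successor marking.
#' @export
fire <- function(net, marking = net$marking, transition_id) {
  if (!(transition_id %in% net$transitions$id)) {
    ps_abort(sprintf("unknown transition '%s'", transition_id))
  }
  if (!(transition_id %in% enabled_transitions(net, marking))) {
    ps_abort(sprintf("transition '%s' is not enabled", transition_id),
             "protsem_state_error")
  }
  inputs <- net$arcs[net$arcs$target == transition_id, ]
  outputs <- net$arcs[net$arcs$source == transition_id, ]
  for (i in seq_len(nrow(inputs))) {
    marking[inputs$source[i]] <- marking[inputs$source[i]] - inputs$weight[i]
  }
  for (i in seq_len(nrow(outputs))) {
    marking[outputs$target[i]] <- marking[outputs$target[i]] + outputs$weight[i]
  }
  marking
}

#' Simulate a compiled protocol net to completion or deadlock
#'
#' Repeatedly fires the unique enabled transition (compiled nets are
#' linear chains, so at most one transition is enabled at a time). The run
#' completes when every transition has fired; otherwise the first unfired
#' step is the deadlock: the protocol is not executable as written.
#'
#' @param net A `protocol_net`.
#' @return A list: `fired` (transition ids in firing order), `completed`
#'   (logical) and `stuck_step` (step index of the first unfired
#'   transition, or `NA` when completed).
#' @examples
#' p <- translate_protocol("Adjust to 10% TCA. Incubate at 30°C overnight.")
#' simulate_run(compile_net(p, load_catalog()))$stuck_step
#' @export
simulate_run <- function(net) {
  marking <- net$marking
  fired <- character()
  repeat {
    en <- setdiff(enabled_transitions(net, marking), fired)
    if (!length(en)) break
    t <- en[1L]
    marking <- fire(net, marking, t)
    fired <- c(fired, t)
  }
  completed <- length(fired) == nrow(net$transitions)
  stuck <- if (completed) {
    NA_integer_
  } else {
    unfired <- setdiff(net$transitions$id, fired)
    min(net$transitions$step_index[net$transitions$id %in% unfired])
  }
  list(fired = fired, completed = completed, stuck_step = stuck,
       final_marking = marking)
}

#' Export a Petri net
#'
#' Supported formats: `pnml` (ISO/IEC 15909-2 place/transition net), `dot`
#' (Graphviz; places drawn as circles, transitions as squares) and `json`
#' (lossless; see [read_net_json()]).
#'
#' @param net A `protocol_net`.
#' @param format One of `"pnml"`, `"dot"`, `"json"`.
#' @param path Optional output file.
#' @return The document as a string (invisibly when `path` is given).
#' @export
export_net <- function(net, format = c("pnml", "dot", "json"), path = NULL) {
  if (!is.character(format) || !format[1L] %in% c("pnml", "dot", "json")) {
    ps_abort(sprintf("unknown export format '%s'", format[1L]),
             "protsem_usage_error")
  }
  format <- format[1L]
  txt <- switch(format,
    pnml = net_to_pnml(net),
    dot = net_to_dot(net),
    json = net_to_json(net)
  )
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

net_to_pnml <- function(net) {
  doc <- xml2::xml_new_root(
    "pnml", xmlns = "http://www.pnml.org/version-2009/grammar/pnml"
  )
  netnode <- xml2::xml_add_child(
    doc, "net", id = "protocol",
    type = "http://www.pnml.org/version-2009/grammar/ptnet"
  )
  page <- xml2::xml_add_child(netnode, "page", id = "page0")
  for (i in seq_len(nrow(net$places))) {
    p <- xml2::xml_add_child(page, "place", id = net$places$id[i])
    nm <- xml2::xml_add_child(p, "name")
    xml2::xml_add_child(nm, "text", net$places$label[i])
    tok <- net$marking[[net$places$id[i]]]
    if (tok > 0L) {
      mk <- xml2::xml_add_child(p, "initialMarking")
      xml2::xml_add_child(mk, "text", as.character(tok))
    }
  }
  for (i in seq_len(nrow(net$transitions))) {
    t <- xml2::xml_add_child(page, "transition", id = net$transitions$id[i])
    nm <- xml2::xml_add_child(t, "name")
    xml2::xml_add_child(nm, "text", net$transitions$label[i])
  }
  for (i in seq_len(nrow(net$arcs))) {
    a <- xml2::xml_add_child(
      page, "arc",
      id = sprintf("a%d", i),
      source = net$arcs$source[i], target = net$arcs$target[i]
    )
    if (net$arcs$weight[i] != 1L) {
      ins <- xml2::xml_add_child(a, "inscription")
      xml2::xml_add_child(ins, "text", as.character(net$arcs$weight[i]))
    }
  }
  as.character(doc)
}

net_to_dot <- function(net) {
  esc <- function(x) gsub("\"", "\\\\\"", x)
  lines <- c(
    "digraph protocol_net {",
    "  rankdir=LR;",
    "  node [fontsize=10];"
  )
  for (i in seq_len(nrow(net$places))) {
    tok <- net$marking[[net$places$id[i]]]
    lab <- esc(net$places$label[i])
    if (tok > 0L) lab <- paste0(lab, "\\n", strrep("●", tok))
    lines <- c(lines, sprintf(
      "  %s [shape=circle, label=\"%s\"];", net$places$id[i], lab
    ))
  }
  for (i in seq_len(nrow(net$transitions))) {
    lines <- c(lines, sprintf(
      "  %s [shape=square, style=filled, fillcolor=lightgrey, label=\"%s\"];",
      net$transitions$id[i], esc(net$transitions$label[i])
    ))
  }
  for (i in seq_len(nrow(net$arcs))) {
    w <- net$arcs$weight[i]
    lines <- c(lines, sprintf(
      "  %s -> %s%s;", net$arcs$source[i], net$arcs$target[i],
      if (w != 1L) sprintf(" [label=\"%d\"]", w) else ""
    ))
  }
  paste(c(lines, "}"), collapse = "\n")
}

net_to_json <- function(net) {
  obj <- list(
    places = net$places,
    transitions = net$transitions,
    arcs = net$arcs,
    marking = as.list(net$marking)
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA))
}

#' Read a Petri net from its JSON export
#'
#' @param x A JSON string or a path to a JSON file written by
#'   [export_net()] with `format = "json"`.
#' @return The reconstructed `protocol_net`.
#' @export
read_net_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  marking <- vapply(obj$marking, as.integer, 1L)
  net <- structure(
    list(
      places = tibble::as_tibble(obj$places),
      transitions = tibble::as_tibble(obj$transitions),
      arcs = tibble::as_tibble(obj$arcs),
      marking = marking
    ),
    class = "protocol_net"
  )
  net$places$step_index <- as.integer(net$places$step_index)
  net$transitions$step_index <- as.integer(net$transitions$step_index)
  net$arcs$weight <- as.integer(net$arcs$weight)
  validate_net(net)
  net
}

#' @export
print.protocol_net <- function(x, ...) {
  cat(sprintf(
    "<protocol_net> %d places, %d transitions, %d arcs; %d token(s)\n",
    nrow(x$places), nrow(x$transitions), nrow(x$arcs), sum(x$marking)
  ))
  en <- enabled_transitions(x)
  cat("  enabled:", if (length(en)) paste(en, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
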
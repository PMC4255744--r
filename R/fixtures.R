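# Verbs used by the generator: transitive protocol verbs whose template
# sentences stay inside the clue-table grammar.
generator_verb_pool <- function() {
  c(
    "incubate", "mix", "wash", "heat", "cool", "shake", "vortex",
    "resuspend", "filter", "collect", "transfer", "store", "centrifuge",
    "agitate", "rinse", "dissolve", "thaw", "harvest", "dilute", "sonicate"
  )
}

generator_goals <- function() {
  c(
    "equilibrate the sample", "remove debris", "clarify the supernatant",
    "start the culture", "stop the reaction", "homogenize the suspension"
  )
}

generator_conditions <- function() {
  c("under sterile conditions", "with shaking", "with stirring",
    "in the presence of inhibitors")
}

generator_distractors <- function() {
  c(
    "Do not smoke in the laboratory.",
    "This step is critical for reproducibility.",
    "Cogitate carefully before proceeding.",
    "See the troubleshooting section for details."
  )
}

#' Generate a synthetic protocol with ground truth
#'
#' Emits imperative template sentences of the form
#' `<Verb> <entity> [at <T>°C | at RT] [for <n> min | overnight]
#' [in <equipment>] [<condition>] [in order to <goal>].`
#' drawn from the catalog verbs and the lab-config dictionaries, together
#' with the intended parse (action id per sentence, descriptor kinds with
#' exact values and units, including resolved defaults such as overnight =
#' 16 h). The grammar deliberately stays within clue-table coverage, so a
#' correct pipeline recovers the ground truth exactly; with
#' `adversarial = TRUE`, out-of-grammar distractor sentences (negations,
#' unknown verbs) are appended and must land among the unmatched
#' sentences. Generation is seeded and reproducible, and the caller's RNG
#' state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_steps Number of action sentences (>= 1).
#' @param catalog,config Catalog and lab config to draw from.
#' @param adversarial Append distractor sentences?
#' @return A list with `text` (the protocol) and `truth` (a
#'   `ground_truth`: `steps` — list of `sentence_index`, `action_id`,
#'   `action_label`, `descriptors` tibble (`kind`, `value`, `magnitude`,
#'   `unit`, `provenance`) — and `distractor_sentences`).
#' @examples
#' fx <- generate_protocol(seed = 7, n_steps = 3)
#' cat(fx$text)
#' @export
generate_protocol <- function(seed, n_steps, catalog = load_catalog(),
                              config = load_lab_config(),
                              adversarial = FALSE) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || is.na(n_steps) ||
      n_steps < 1L) {
    ps_abort("`n_steps` must be a single integer >= 1", "protsem_usage_error")
  }
  n_steps <- as.integer(n_steps)

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)

  pool <- intersect(generator_verb_pool(), catalog$actions$label)
  entities <- config$entities
  equipment <- config$equipment
  cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

  sentences <- character(n_steps)
  truth_steps <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    verb <- sample(pool, 1L)
    action <- match_action_verb(verb, catalog)
    allowed <- c(action$essential, action$optional)
    ent_i <- sample(nrow(entities), 1L)
    ent_name <- entities$name[ent_i]
    aliases <- entities$aliases[[ent_i]]
    surface <- if (length(aliases) && stats::runif(1) < 0.25) {
      sample(aliases, 1L)
    } else {
      ent_name
    }
    parts <- c(cap(verb), surface)
    rows <- list(tibble::tibble(
      kind = "biochemical_entity", value = ent_name,
      magnitude = NA_real_, unit = NA_character_, provenance = "extracted"
    ))
    add_row <- function(kind, value, magnitude = NA_real_,
                        unit = NA_character_, provenance = "extracted") {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        kind = kind, value = value, magnitude = magnitude, unit = unit,
        provenance = provenance
      )
    }

    if ("temperature" %in% allowed) {
      u <- stats::runif(1)
      if (u < 0.35) {
        temp <- sample(c(4, 15, 20, 25, 30, 37, 42, 50, 65, 95), 1L)
        parts <- c(parts, sprintf("at %d°C", temp))
        add_row("temperature", sprintf("%d°C", temp), temp, "°C")
      } else if (u < 0.55) {
        parts <- c(parts, "at RT")
        rt <- resolve_default("RT", config)
        add_row("temperature", sprintf("%g %s", rt$magnitude, rt$unit),
                rt$magnitude, rt$unit, provenance = "default")
      }
    }
    if ("period" %in% allowed) {
      u <- stats::runif(1)
      if (u < 0.3) {
        mins <- sample(c(1, 2, 5, 10, 15, 30, 45), 1L)
        parts <- c(parts, sprintf("for %d min", mins))
        add_row("period", sprintf("%d min", mins), mins, "min")
      } else if (u < 0.4) {
        hrs <- sample(c(1, 2, 4), 1L)
        parts <- c(parts, sprintf("for %d h", hrs))
        add_row("period", sprintf("%d h", hrs), hrs, "h")
      } else if (u < 0.55) {
        parts <- c(parts, "overnight")
        ov <- resolve_default("overnight", config)
        add_row("period", sprintf("%g %s", ov$magnitude, ov$unit),
                ov$magnitude, ov$unit, provenance = "default")
      }
    }
    if ("equipment" %in% allowed && stats::runif(1) < 0.3) {
      eq_i <- sample(nrow(equipment), 1L)
      eq_alias <- equipment$aliases[[eq_i]]
      eq_surface <- if (length(eq_alias) && stats::runif(1) < 0.5) {
        sample(eq_alias, 1L)
      } else {
        equipment$name[eq_i]
      }
      parts <- c(parts, paste("in", eq_surface))
      add_row("equipment", equipment$name[eq_i])
    }
    if ("condition" %in% allowed && stats::runif(1) < 0.35) {
      cond <- sample(generator_conditions(), 1L)
      parts <- c(parts, cond)
      add_row("condition", cond)
    }
    if ("goal" %in% allowed && stats::runif(1) < 0.25) {
      goal <- sample(generator_goals(), 1L)
      parts <- c(parts, paste("in order to", goal))
      add_row("goal", goal)
    }
    sentences[i] <- paste0(paste(parts, collapse = " "), ".")
    truth_steps[[i]] <- list(
      sentence_index = i - 1L,
      action_id = action$id,
      action_label = action$label,
      descriptors = do.call(rbind, rows)
    )
  }

  distractor_idx <- integer()
  if (adversarial) {
    extra <- sample(generator_distractors(), sample(1:2, 1L))
    distractor_idx <- n_steps + seq_along(extra) - 1L
    sentences <- c(sentences, extra)
  }

  list(
    text = paste(sentences, collapse = " "),
    truth = structure(
      list(steps = truth_steps, distractor_sentences = distractor_idx),
      class = "ground_truth"
    )
  )
}

descriptor_key <- function(kind, magnitude, unit, value) {
  ifelse(
    !is.na(magnitude),
    sprintf("%s|%.10g|%s", kind, magnitude, unit),
    sprintf("%s|%s", kind, value)
  )
}

#' Score pipeline recovery against generator ground truth
#'
#' An action is matched when a predicted step carries the truth's action
#' id in the truth's sentence. Recall is matched / truth actions;
#' precision is matched / predicted steps. Descriptor value accuracy
#' compares (kind, value, unit) triples over matched steps (inferred
#' values are not scored): it is the number of triples present on both
#' sides divided by the larger side, so it reaches 1.0 only when the sets
#' agree exactly.
#'
#' @param protocol The `structured_protocol` produced from the fixture
#'   text.
#' @param truth The fixture's `ground_truth`.
#' @return A list: `action_recall`, `action_precision`,
#'   `descriptor_value_accuracy`, plus the underlying counts.
#' @examples
#' fx <- generate_protocol(seed = 1, n_steps = 3)
#' p <- translate_protocol(fx$text)
#' score_recovery(p, fx$truth)$action_recall
#' @export
score_recovery <- function(protocol, truth) {
  preds <- protocol$steps
  pred_used <- logical(length(preds))
  matched <- 0L
  triples_truth <- 0L
  triples_pred <- 0L
  triples_hit <- 0L

  for (ts in truth$steps) {
    hit <- NA_integer_
    for (j in seq_along(preds)) {
      if (pred_used[j]) next
      if (preds[[j]]$sentence_index == ts$sentence_index &&
          preds[[j]]$action_id == ts$action_id) {
        hit <- j
        break
      }
    }
    if (is.na(hit)) next
    pred_used[hit] <- TRUE
    matched <- matched + 1L

    td <- ts$descriptors
    tkeys <- descriptor_key(td$kind, td$magnitude, td$unit, td$value)
    pd <- Filter(function(d) d$provenance != "inferred",
                 preds[[hit]]$descriptors)
    pkeys <- vapply(
      pd,
      function(d) descriptor_key(d$kind, d$magnitude, d$unit, d$value),
      ""
    )
    triples_truth <- triples_truth + length(tkeys)
    triples_pred <- triples_pred + length(pkeys)
    triples_hit <- triples_hit + length(intersect(tkeys, pkeys))
  }

  n_truth <- length(truth$steps)
  n_pred <- length(preds)
  list(
    action_recall = if (n_truth) matched / n_truth else 1,
    action_precision = if (n_pred) matched / n_pred else 1,
    descriptor_value_accuracy = if (max(triples_truth, triples_pred)) {
      triples_hit / max(triples_truth, triples_pred)
    } else 1,
    n_truth_actions = n_truth,
    n_predicted_actions = n_pred,
    n_matched_actions = matched
  )
}
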
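#' Normalize raw protocol text
#'
#' Unifies line endings to LF, folds unicode variants of the micro and
#' degree signs to canonical forms (`μ`, `°C`), joins a number to a
#' following degree unit (`30 °C` becomes `30°C`), and collapses runs of
#' horizontal whitespace. Content is otherwise preserved, and the function
#' is idempotent.
#'
#' @param raw A single UTF-8 string.
#' @return The normalized string.
#' @examples
#' normalize_text("Incubate at 30 °C.\r\n")
#' @export
normalize_text <- function(raw) {
  assert_string(raw, "raw")
  if (!all(validUTF8(raw))) {
    ps_abort("input is not valid UTF-8 text", "protsem_format_error")
  }
  x <- gsub("\r\n?", "\n", raw)
  x <- gsub("µ", "μ", x)          # MICRO SIGN -> GREEK SMALL MU
  x <- gsub("℃", "°C", x)         # DEGREE CELSIUS glyph
  x <- gsub("℉", "°F", x)         # DEGREE FAHRENHEIT glyph
  x <- gsub("[ \t]+", " ", x)
  x <- gsub("(?<=[0-9]) (?=°[CF])", "", x, perl = TRUE)
  x <- gsub(" ?\n ?", "\n", x)
  x
}

#' Split normalized text into sentences
#'
#' Sentence boundaries are `.`, `!`, `?` followed by whitespace (or end of
#' text) and line breaks. A period inside a decimal number (`0.1%`) or
#' after a known textual abbreviation (`e.g.`, `etc.`) is not a boundary.
#'
#' @param doc Normalized document text (see [normalize_text()]).
#' @return A tibble with one row per sentence: `index` (0-based), `text`
#'   (trimmed sentence), `start`, `end` (0-based half-open character span
#'   of the trimmed text within `doc`).
#' @examples
#' split_sentences("Adjust to 10% TCA. Incubate at 30°C overnight.")
#' @export
split_sentences <- function(doc) {
  assert_string(doc, "doc")
  empty <- tibble::tibble(
    index = integer(), text = character(),
    start = integer(), end = integer()
  )
  n <- nchar(doc)
  if (n == 0L || !grepl("[^[:space:]]", doc)) return(empty)

  non_boundary_abbrev <- c(
    "e.g", "i.e", "etc", "fig", "figs", "vs", "ca", "cf", "approx", "no", "st"
  )
  chars <- strsplit(doc, "", fixed = TRUE)[[1]]
  bounds <- integer(0)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "\n") {
      bounds <- c(bounds, i)
    } else if (ch %in% c("!", "?")) {
      if (i == n || grepl("[[:space:]]", chars[i + 1L])) bounds <- c(bounds, i)
    } else if (ch == ".") {
      if (i < n && !grepl("[[:space:]]", chars[i + 1L])) next  # decimal / internal dot
      tail <- substr(doc, max(1L, i - 12L), i - 1L)
      token <- sub(".*[[:space:](]", "", tail)
      if (tolower(token) %in% non_boundary_abbrev) next
      bounds <- c(bounds, i)
    }
  }
  cuts <- sort(unique(c(bounds, n)))
  rows <- list()
  seg_start <- 1L
  for (b in cuts) {
    seg <- substr(doc, seg_start, b)
    if (grepl("[^[:space:]]", seg)) {
      hits <- gregexpr("[^[:space:]]", seg)[[1]]
      first <- seg_start - 1L + hits[1L]
      last <- seg_start - 1L + hits[length(hits)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        text = substr(doc, first, last),
        start = first - 1L,
        end = last
      )
    }
    seg_start <- b + 1L
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  tibble::tibble(index = seq_len(nrow(out)) - 1L, out)
}

#' Lemmatize an (English) verb token
#'
#' Strips regular inflections (-s, -ed, -ing) with standard consonant
#' undoubling and silent-e restoration. When a `lexicon` of known verb
#' lemmas is supplied, candidate stems are checked against it, which makes
#' e-restoration exact for catalog verbs (`shaking` -> `shake`,
#' `filtered` -> `filter`).
#'
#' @param token A word token.
#' @param lexicon Optional character vector of known lemmas.
#' @return The lowercase lemma.
#' @examples
#' lemmatize_verb("Incubated", lexicon = "incubate")
#' @export
lemmatize_verb <- function(token, lexicon = NULL) {
  w <- tolower(token)
  in_lex <- function(x) !is.null(lexicon) && x %in% lexicon
  if (in_lex(w)) return(w)

  cands <- character(0)
  if (grepl("ies$", w) && nchar(w) > 4L) cands <- c(cands, sub("ies$", "y", w))
  if (grepl("(ss|sh|ch|x|z)es$", w)) cands <- c(cands, sub("es$", "", w))
  if (grepl("[^su]s$", w)) cands <- c(cands, sub("s$", "", w))
  for (suf in c("ing", "ed")) {
    if (grepl(paste0(suf, "$"), w) && nchar(w) > nchar(suf) + 2L) {
      stem <- sub(paste0(suf, "$"), "", w)
      cands <- c(cands, stem, paste0(stem, "e"))
      if (grepl("([bdfglmnprt])\\1$", stem)) {
        cands <- c(cands, sub("(.)\\1$", "\\1", stem))
      }
    }
  }
  hit <- cands[vapply(cands, in_lex, logical(1))]
  if (length(hit)) return(hit[[1L]])

  # lexicon-free heuristics
  if (grepl("(ing|ed)$", w) && nchar(w) > 4L) {
    stem <- sub("(ing|ed)$", "", w)
    if (grepl("([bdfgmnprt])\\1$", stem)) stem <- sub("(.)\\1$", "\\1", stem)
    return(stem)
  }
  if (grepl("ies$", w) && nchar(w) > 4L) return(sub("ies$", "y", w))
  if (grepl("[^su]s$", w)) return(sub("s$", "", w))
  w
}

#' Find candidate action verbs in a sentence
#'
#' Protocols are written in the imperative register, so no statistical POS
#' tagger is needed: the candidates are the sentence-initial token and any
#' token coordinated by `and`, `then` or a comma. Tokens in infinitive
#' position (preceded by `to`) are excluded: they belong to goal clauses.
#'
#' @param sentence A sentence string, or a row from [split_sentences()].
#' @param lexicon Optional verb lexicon passed to [lemmatize_verb()]
#'   (typically the catalog's labels and synonyms).
#' @return A tibble with columns `lemma`, `start`, `end` (0-based half-open
#'   spans within the sentence).
#' @examples
#' find_candidate_verbs("Mix and incubate for 5 min.")
#' @export
find_candidate_verbs <- function(sentence, lexicon = NULL) {
  text <- if (is.character(sentence)) sentence else sentence$text
  assert_string(text, "sentence")
  empty <- tibble::tibble(lemma = character(), start = integer(), end = integer())
  m <- gregexpr("[A-Za-z][A-Za-z'-]*", text)[[1]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tokens <- substring(text, starts, starts + lens - 1L)

  cand <- logical(length(tokens))
  cand[1L] <- TRUE
  if (length(tokens) > 1L) {
    for (k in 2L:length(tokens)) {
      prev <- tolower(tokens[k - 1L])
      gap <- substr(text, starts[k - 1L] + lens[k - 1L], starts[k] - 1L)
      if (prev %in% c("and", "then") || grepl(",", gap, fixed = TRUE)) {
        cand[k] <- TRUE
      }
      if (prev == "to") cand[k] <- FALSE
    }
  }
  cand[tolower(tokens) %in% c("and", "then")] <- FALSE
  idx <- which(cand)
  tibble::tibble(
    lemma = vapply(tokens[idx], lemmatize_verb, "", lexicon = lexicon,
                   USE.NAMES = FALSE),
    start = starts[idx] - 1L,
    end = starts[idx] - 1L + lens[idx]
  )
}

#' Find quantity mentions in a sentence
#'
#' Scans for number--unit pairs using the clue table. Each mention carries
#' the magnitude, the unit symbol, its Units Ontology accession when known,
#' and the descriptor kind the unit hints at (e.g. `°C` signals a
#' temperature). Compound units win over their components and mentions
#' never overlap. With `include_unknown = TRUE`, a number directly attached
#' to an unrecognised short unit-like token is also returned, flagged
#' `known = FALSE`.
#'
#' @param sentence A sentence string or a row from [split_sentences()].
#' @param clues A [clue_table()].
#' @param include_unknown Also report unrecognised attached units?
#' @return A tibble: `magnitude`, `unit_symbol`, `unit_id`, `kind_hint`,
#'   `start`, `end` (0-based half-open), `known`.
#' @examples
#' find_quantities("Incubate at 30°C for 5 min.")
#' @export
find_quantities <- function(sentence, clues = clue_table(),
                            include_unknown = FALSE) {
  text <- if (is.character(sentence)) sentence else sentence$text
  assert_string(text, "sentence")
  num <- "\\d+(?:\\.\\d+)?"
  pat <- sprintf(
    "(?<![\\w.])(%s) ?(%s)(?![A-Za-zμ])",
    num, unit_alternation(clues$units)
  )
  loc <- stringr::str_locate_all(text, pat)[[1]]
  grp <- stringr::str_match_all(text, pat)[[1]]
  rows <- list()
  if (nrow(loc)) {
    for (i in seq_len(nrow(loc))) {
      u <- lookup_unit(grp[i, 3L], clues$units)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        magnitude = as.numeric(grp[i, 2L]),
        unit_symbol = u$symbol,
        unit_id = u$unit_id,
        kind_hint = u$kind,
        start = loc[i, 1L] - 1L,
        end = loc[i, 2L],
        known = TRUE
      )
    }
  }
  if (include_unknown) {
    pat2 <- sprintf(
      "(?<![\\w.])(%s)([A-Za-zμ°][A-Za-zμ°/]{0,5})(?![A-Za-zμ])",
      num
    )
    loc2 <- stringr::str_locate_all(text, pat2)[[1]]
    grp2 <- stringr::str_match_all(text, pat2)[[1]]
    if (nrow(loc2)) {
      taken <- if (length(rows)) do.call(rbind, rows) else NULL
      for (i in seq_len(nrow(loc2))) {
        s0 <- loc2[i, 1L] - 1L
        e0 <- loc2[i, 2L]
        overlaps <- !is.null(taken) && any(s0 < taken$end & taken$start < e0)
        if (overlaps) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          magnitude = as.numeric(grp2[i, 2L]),
          unit_symbol = grp2[i, 3L],
          unit_id = NA_character_,
          kind_hint = NA_character_,
          start = s0,
          end = e0,
          known = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      magnitude = numeric(), unit_symbol = character(),
      unit_id = character(), kind_hint = character(),
      start = integer(), end = integer(), known = logical()
    ))
  }
  out <- do.call(rbind, rows)
  out[order(out$start), ]
}
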
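# Shared fixtures: the bundled reference model and lab configuration are
# loaded once per test run.
test_catalog <- load_catalog()
test_config <- load_lab_config()
test_clues <- clue_table()

write_tmp <- function(lines, ext = ".yaml") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, useBytes = TRUE)
  path
}

# Knock random essential descriptor values out of a translated protocol,
# keeping the bookkeeping (missing_essential) consistent. Used to exercise
# the validator/Petri-net equivalence on partially specified protocols.
delete_random_essentials <- function(protocol, prob = 0.3) {
  for (i in seq_along(protocol$steps)) {
    step <- protocol$steps[[i]]
    keep <- vapply(
      step$descriptors,
      function(d) !(d$essential && stats::runif(1) < prob),
      logical(1)
    )
    dropped <- vapply(step$descriptors[!keep], `[[`, "", "kind")
    step$descriptors <- step$descriptors[keep]
    present <- unique(vapply(step$descriptors, `[[`, "", "kind"))
    step$missing_essential <- union(
      step$missing_essential, setdiff(dropped, present)
    )
    protocol$steps[[i]] <- step
  }
  protocol
}

step_descriptor <- function(step, kind) {
  hits <- Filter(function(d) d$kind == kind, step$descriptors)
  if (length(hits)) hits[[1L]] else NULL
}
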
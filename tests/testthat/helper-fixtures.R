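# Fixtures are built in code at test time; no binary data ships with the
# package.

# A minimal CHAT transcript: one child with a %pho tier, one child
# utterance without one (must be skipped), one parent utterance, and a
# diacritic-bearing token (must be preserved by the reader).
write_chat_fixture <- function(path = tempfile(fileext = ".cha"),
                               age = "0;10.") {
  lines <- c(
    "@UTF8",
    "@Begin",
    "@Languages:\teng",
    "@Participants:\tCHI Kate Target_Child , MOT Sally Mother",
    sprintf("@ID:\teng|demo|CHI|%s|female|||Target_Child|||", age),
    "@ID:\teng|demo|MOT|28;00.|female|||Mother|||",
    "*CHI:\tbaba .",
    "%pho:\tbaba",
    "*CHI:\txxx .",
    "*MOT:\tyes baby .",
    "%pho:\tbebi",
    "*CHI:\tpata .",
    "%pho:\tpʰata",
    "@End"
  )
  writeLines(lines, path, useBytes = TRUE)
  path
}

# One-utterance corpus tibble from a plain phoneme string.
corpus_row <- function(string, child_id = "A", role = "child",
                       age = 12, durations = NULL) {
  tibble::tibble(
    child_id = child_id, speaker_role = role, age_months = age,
    phonemes = list(strsplit(string, "")[[1]]),
    durations_ms = list(durations)
  )
}

# A monthly-counts row from named category counts.
counts_row <- function(..., child_id = "A", role = "child", month = 12) {
  counts <- c(...)
  out <- tibble::tibble(child_id = child_id, speaker_role = role,
                        month = month)
  for (cat in cvc_categories()) {
    out[[cat]] <- if (cat %in% names(counts)) as.integer(counts[[cat]])
                  else 0L
  }
  out$total <- sum(unlist(counts))
  out
}

# Random monthly-counts table for property-style tests.
random_counts <- function(n = 25, max_total = 60) {
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(0:max_total, 1)
    draw <- if (k > 0) {
      tab <- table(factor(sample(cvc_categories(), k, replace = TRUE),
                          levels = cvc_categories()))
      as.integer(tab)
    } else {
      rep(0L, 9)
    }
    do.call(counts_row, c(as.list(stats::setNames(draw, cvc_categories())),
                          list(month = i)))
  })
  dplyr::bind_rows(rows)
}
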
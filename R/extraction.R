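# CVC unit extraction: slide a 3-symbol window over each utterance after
# removing boundary and diacritic marks; keep windows whose shape is
# consonant-vowel-consonant with both consonants in the admissible set.
# Syllable positions are deliberately ignored and windows may overlap
# (a shared middle consonant yields two units from C1VC2VC3).

MARK_REGEX <- "[\\p{M}\\p{Lm}\\p{Sk}\\p{P}\\p{Z}\\p{C}っッ]"

# Strip one symbol vector, returning both the cleaned symbols and the
# indices of the surviving original symbols (needed to keep optional
# duration annotations aligned).
strip_marks_idx <- function(phonemes, table = default_consonant_table()) {
  if (!length(phonemes)) {
    return(list(phonemes = character(), keep = integer()))
  }
  al <- table$aliases
  if (length(al)) {
    hit <- match(phonemes, names(al))
    phonemes[!is.na(hit)] <- unname(al[hit[!is.na(hit)]])
  }
  cleaned <- stringr::str_remove_all(phonemes, MARK_REGEX)
  keep <- which(nzchar(cleaned))
  list(phonemes = cleaned[keep], keep = keep)
}

#' Remove boundary and diacritic marks from a phoneme sequence
#'
#' Syllable/word boundaries, punctuation and diacritic marks (combining
#' characters, modifier letters such as aspiration or length marks) are
#' removed; base phonemes are preserved in order. Alias symbols defined in
#' the table (e.g. moraic-nasal notations) are folded onto their base
#' phoneme first; geminate markers are dropped.
#'
#' @param phonemes Character vector of symbols, possibly mark-bearing.
#' @param table A `consonant_table` supplying the alias map.
#' @return Character vector of bare phonemes.
#' @export
#' @examples
#' strip_marks(c("p", "a", ".", "t", "a"))
#' strip_marks(c("pʰ", "a"))
strip_marks <- function(phonemes, table = default_consonant_table()) {
  strip_marks_idx(phonemes, table)$phonemes
}

#' Extract CVC units from a corpus
#'
#' Every index triple `(i, i+1, i+2)` of the stripped phoneme sequence with
#' consonant-vowel-consonant shape yields a candidate unit; the candidate is
#' kept only if both consonants are in the admissible consonant set of
#' `table`. Units may overlap, so a strictly alternating stretch with `n`
#' admissible consonants yields `n - 1` units. Extraction runs across the
#' whole utterance: syllable and word boundaries have already been removed
#' by [strip_marks()], so cross-boundary sequences count.
#'
#' @param corpus A corpus tibble (see [read_corpus_tsv()]).
#' @param table A `consonant_table`.
#' @return A tibble with one row per CVC unit: `child_id`, `speaker_role`,
#'   `age_months`, `c1`, `v`, `c2`, `category`.
#' @export
extract_cvc_units <- function(corpus, table = default_consonant_table()) {
  empty <- tibble::tibble(
    child_id = character(), speaker_role = character(),
    age_months = numeric(), c1 = character(), v = character(),
    c2 = character(), category = character()
  )
  if (!nrow(corpus)) return(empty)
  stripped <- lapply(corpus$phonemes, function(p) {
    strip_marks_idx(p, table)$phonemes
  })
  lens <- lengths(stripped)
  if (!sum(lens)) return(empty)

  utt <- rep.int(seq_len(nrow(corpus)), lens)
  s <- unlist(stripped, use.names = FALSE)
  n <- length(s)
  i1 <- seq_len(max(0L, n - 2L))
  same_utt <- utt[i1] == utt[i1 + 2L]
  shape <- is_consonant(s[i1], table) & is_vowel(s[i1 + 1L], table) &
    is_consonant(s[i1 + 2L], table)
  hit <- i1[same_utt & shape]
  if (!length(hit)) return(empty)

  tibble::tibble(
    child_id = corpus$child_id[utt[hit]],
    speaker_role = corpus$speaker_role[utt[hit]],
    age_months = corpus$age_months[utt[hit]],
    c1 = s[hit], v = s[hit + 1L], c2 = s[hit + 2L],
    category = classify_pair(s[hit], s[hit + 2L], table)
  )
}

#' Accumulate monthly CVC category counts
#'
#' Bins units by integer month of age (`floor(age_months)`) and counts
#' tokens in each of the nine categories, per child or pooled across
#' children.
#'
#' @param units Unit tibble from [extract_cvc_units()].
#' @param pool Pool across children (`child_id` becomes `"POOLED"`)?
#' @return A tibble with columns `child_id`, `speaker_role`, `month`, the
#'   nine category counts `LL` ... `DD`, and `total` (their sum).
#' @export
count_monthly <- function(units, pool = FALSE) {
  cats <- cvc_categories()
  empty <- tibble::as_tibble(c(
    list(child_id = character(), speaker_role = character(),
         month = integer()),
    stats::setNames(rep(list(integer()), 9), cats),
    list(total = integer())
  ))
  if (!nrow(units)) return(empty)
  wide <- units |>
    dplyr::mutate(
      child_id = if (pool) "POOLED" else .data$child_id,
      month = as.integer(floor(.data$age_months))
    ) |>
    dplyr::count(.data$child_id, .data$speaker_role, .data$month,
                 .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (cat in setdiff(cats, names(wide))) wide[[cat]] <- 0L
  wide |>
    dplyr::relocate(dplyr::all_of(cats),
                    .after = "month") |>
    dplyr::mutate(total = rowSums(dplyr::pick(dplyr::all_of(cats)))) |>
    dplyr::arrange(.data$child_id, .data$speaker_role, .data$month)
}

#' Extract CVCV durations from a corpus with phoneme-duration annotations
#'
#' For every 4-gram of the stripped sequence with
#' consonant-vowel-consonant-vowel shape and both consonants admissible,
#' emits the summed duration of the four phonemes. Only CVCV (not bare
#' CVC) stretches contribute, so the duration unit is unambiguous.
#' Utterances without duration annotations yield nothing.
#'
#' @inheritParams extract_cvc_units
#' @return A tibble `child_id`, `speaker_role`, `age_months`,
#'   `duration_ms`, one row per CVCV window.
#' @export
extract_cvcv_durations <- function(corpus,
                                   table = default_consonant_table()) {
  empty <- tibble::tibble(
    child_id = character(), speaker_role = character(),
    age_months = numeric(), duration_ms = numeric()
  )
  has_dur <- vapply(corpus$durations_ms, function(d) !is.null(d), logical(1))
  corpus <- corpus[has_dur, , drop = FALSE]
  if (!nrow(corpus)) return(empty)

  stripped <- lapply(seq_len(nrow(corpus)), function(i) {
    sk <- strip_marks_idx(corpus$phonemes[[i]], table)
    list(phonemes = sk$phonemes, durations = corpus$durations_ms[[i]][sk$keep])
  })
  lens <- lengths(lapply(stripped, `[[`, "phonemes"))
  if (!sum(lens)) return(empty)
  utt <- rep.int(seq_len(nrow(corpus)), lens)
  s <- unlist(lapply(stripped, `[[`, "phonemes"), use.names = FALSE)
  d <- unlist(lapply(stripped, `[[`, "durations"), use.names = FALSE)
  n <- length(s)
  i1 <- seq_len(max(0L, n - 3L))
  same_utt <- utt[i1] == utt[i1 + 3L]
  shape <- is_consonant(s[i1], table) & is_vowel(s[i1 + 1L], table) &
    is_consonant(s[i1 + 2L], table) & is_vowel(s[i1 + 3L], table)
  hit <- i1[same_utt & shape]
  if (!length(hit)) return(empty)
  tibble::tibble(
    child_id = corpus$child_id[utt[hit]],
    speaker_role = corpus$speaker_role[utt[hit]],
    age_months = corpus$age_months[utt[hit]],
    duration_ms = d[hit] + d[hit + 1L] + d[hit + 2L] + d[hit + 3L]
  )
}
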
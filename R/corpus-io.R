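# Corpus readers: CHILDES CHAT files and the plain tabular dialect.
#
# A corpus is a tibble with one utterance per row:
#   child_id      character
#   speaker_role  "child" or "parent_to_child"
#   age_months    numeric, >= 0
#   phonemes      list-column of character vectors (one symbol per element)
#   durations_ms  list-column of numeric vectors (same length as phonemes),
#                 or NULL elements when no duration annotation exists

new_corpus <- function(child_id = character(), speaker_role = character(),
                       age_months = numeric(), phonemes = list(),
                       durations_ms = NULL) {
  if (is.null(durations_ms)) durations_ms <- rep(list(NULL), length(phonemes))
  tibble::tibble(
    child_id = child_id, speaker_role = speaker_role,
    age_months = age_months, phonemes = phonemes,
    durations_ms = durations_ms
  )
}

# Split a transcribed word into phoneme symbols, attaching combining
# diacritics and modifier letters (aspiration, length marks, ...) to the
# preceding base character so the reader stays lossless; marks are only
# removed later, by strip_marks().
tokenize_word <- function(word) {
  chars <- strsplit(word, "", fixed = FALSE)[[1]]
  if (!length(chars)) return(character())
  is_mark <- stringr::str_detect(chars, "^[\\p{M}\\p{Lm}\\p{Sk}]$")
  is_mark[1] <- FALSE
  grp <- cumsum(!is_mark)
  as.vector(tapply(chars, grp, paste0, collapse = ""))
}

tokenize_utterance <- function(text) {
  words <- stringr::str_split_1(stringr::str_trim(text), "\\s+")
  words <- words[!stringr::str_detect(words, "^[[:punct:]]+$")]
  words <- words[nzchar(words)]
  if (!length(words)) return(character())
  toks <- lapply(words, tokenize_word)
  # word boundaries kept as explicit " " tokens; extraction strips them
  out <- head(unlist(rbind(lapply(toks, identity),
                           as.list(rep(" ", length(toks))))), -1)
  out
}

# CHAT ages look like "1;07.15" (years;months.days). Fractional months use
# the mean month length so sub-month ages like 19.1 months are representable.
parse_chat_age <- function(age) {
  m <- stringr::str_match(age, "^(\\d+);(\\d+)(?:\\.(\\d*))?$")
  if (is.na(m[1, 1])) return(NA_real_)
  days <- ifelse(is.na(m[1, 4]) | m[1, 4] == "", "0", m[1, 4])
  as.numeric(m[1, 2]) * 12 + as.numeric(m[1, 3]) + as.numeric(days) / 30.44
}

chat_role_map <- function(role) {
  if (is.na(role)) return(NA_character_)
  if (role == "Target_Child") return("child")
  if (role %in% c("Mother", "Father")) return("parent_to_child")
  NA_character_
}

read_chat_file <- function(path) {
  lines <- tryCatch(readLines(path, encoding = "UTF-8", warn = FALSE),
                    error = function(e) {
                      stop("cannot read CHAT file: ", path, call. = FALSE)
                    })
  # continuation lines begin with a tab and belong to the previous tier
  joined <- character()
  for (ln in lines) {
    if (stringr::str_detect(ln, "^[\\t ]") && length(joined)) {
      joined[length(joined)] <- paste(joined[length(joined)],
                                      stringr::str_trim(ln))
    } else {
      joined <- c(joined, ln)
    }
  }

  # speaker metadata from @ID headers:
  # lang|corpus|code|age|sex|group|SES|role|education|custom
  ids <- joined[stringr::str_detect(joined, "^@ID:")]
  speakers <- list()
  for (ln in ids) {
    fields <- stringr::str_split_1(
      stringr::str_trim(stringr::str_remove(ln, "^@ID:")), "\\|")
    code <- fields[3]
    speakers[[code]] <- list(
      age_months = parse_chat_age(fields[4]),
      role = chat_role_map(if (length(fields) >= 8) fields[8] else NA)
    )
  }

  # target child's name from @Participants, falling back to the file stem
  child_id <- tools::file_path_sans_ext(basename(path))
  part <- joined[stringr::str_detect(joined, "^@Participants:")]
  if (length(part)) {
    entries <- stringr::str_split_1(
      stringr::str_remove(part[1], "^@Participants:"), ",")
    for (e in entries) {
      w <- stringr::str_split_1(stringr::str_trim(e), "\\s+")
      if (length(w) >= 3 && w[3] == "Target_Child" && nzchar(w[2])) {
        child_id <- w[2]
      }
    }
  }

  chi_age <- if (!is.null(speakers[["CHI"]])) speakers[["CHI"]]$age_months
             else NA_real_

  rows <- list()
  n_skipped_pho <- 0L
  n_skipped_age <- 0L
  cur_speaker <- NULL
  cur_pho <- NULL
  flush <- function() {
    if (is.null(cur_speaker)) return()
    sp <- speakers[[cur_speaker]]
    role <- if (is.null(sp)) NA_character_ else sp$role
    if (is.na(role)) {
      cur_speaker <<- NULL; cur_pho <<- NULL
      return()
    }
    if (is.null(cur_pho)) {
      n_skipped_pho <<- n_skipped_pho + 1L
      cur_speaker <<- NULL
      return()
    }
    # all utterances are timestamped with the target child's age
    if (is.na(chi_age)) {
      n_skipped_age <<- n_skipped_age + 1L
      cur_speaker <<- NULL; cur_pho <<- NULL
      return()
    }
    phon <- tokenize_utterance(cur_pho)
    if (length(phon)) {
      rows[[length(rows) + 1L]] <<- list(
        child_id = child_id, speaker_role = role, age_months = chi_age,
        phonemes = list(phon)
      )
    }
    cur_speaker <<- NULL; cur_pho <<- NULL
  }

  for (ln in joined) {
    if (stringr::str_detect(ln, "^\\*")) {
      flush()
      cur_speaker <- stringr::str_match(ln, "^\\*([^:]+):")[, 2]
    } else if (stringr::str_detect(ln, "^%pho:")) {
      cur_pho <- stringr::str_remove(ln, "^%pho:")
    } else if (stringr::str_detect(ln, "^[@%]")) {
      next
    }
  }
  flush()

  if (n_skipped_pho > 0) {
    message(basename(path), ": skipped ", n_skipped_pho,
            " utterance(s) without a %pho tier")
  }
  if (n_skipped_age > 0) {
    warning(basename(path), ": skipped ", n_skipped_age,
            " utterance(s) with unparsable age", call. = FALSE)
  }
  if (!length(rows)) return(new_corpus())
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  out$durations_ms <- rep(list(NULL), nrow(out))
  out
}

#' Read CHILDES CHAT transcripts
#'
#' Parses one `.cha` file or a directory of them into a corpus tibble.
#' Phonemes are taken from the phonological tier (`%pho`); utterances
#' without one are skipped (no grapheme-to-phoneme guessing), with the
#' per-file skip count reported. Speaker roles are mapped from the `@ID`
#' headers (`Target_Child` to `"child"`, `Mother`/`Father` to
#' `"parent_to_child"`; other speakers are dropped). Ages of the form
#' `years;months.days` become fractional months
#' (`years * 12 + months + days / 30.44`). The reader is lossless:
#' diacritics stay attached to their base phoneme and word boundaries are
#' kept as `" "` tokens; both are removed later by [strip_marks()].
#'
#' @param path A `.cha` file or a directory containing them.
#' @param role_filter Optional: keep only `"child"` or `"parent_to_child"`
#'   utterances.
#' @return A corpus tibble (`child_id`, `speaker_role`, `age_months`,
#'   `phonemes`, `durations_ms`).
#' @export
read_chat <- function(path, role_filter = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.cha$", full.names = TRUE,
                        recursive = TRUE)
    if (!length(files)) stop("no .cha files under ", path)
  } else {
    if (!file.exists(path)) stop("cannot read CHAT file: ", path)
    files <- path
  }
  out <- dplyr::bind_rows(lapply(files, read_chat_file))
  if (!nrow(out)) out <- new_corpus()
  if (!is.null(role_filter)) {
    out <- dplyr::filter(out, .data$speaker_role %in% role_filter)
  }
  out
}

split_phoneme_string <- function(s, delim = "") {
  strsplit(s, delim, fixed = TRUE)
}

#' Read and write the tabular corpus dialect
#'
#' A tab-separated file with header columns `child_id`, `speaker_role`,
#' `age_months`, `phonemes` and optionally `durations_ms`. The phoneme
#' string is split into symbols on `delim` (default `""`: one symbol per
#' character; set e.g. `" "` for multi-character tokenizations).
#' `durations_ms` holds space-separated per-phoneme durations; rows whose
#' duration count does not match the phoneme count are rejected with a
#' warning. `write_corpus_tsv()` inverts the reader, so a read/write
#' round trip preserves every field on well-formed input.
#'
#' @param path TSV file path.
#' @param delim Delimiter between phoneme symbols within the string.
#' @return `read_corpus_tsv()` returns a corpus tibble;
#'   `write_corpus_tsv()` returns `path` invisibly.
#' @export
read_corpus_tsv <- function(path, delim = "") {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    child_id = readr::col_character(),
    speaker_role = readr::col_character(),
    age_months = readr::col_double(),
    phonemes = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  phon <- split_phoneme_string(raw$phonemes, delim)
  if ("durations_ms" %in% names(raw)) {
    durs <- lapply(raw$durations_ms, function(d) {
      if (is.na(d) || d == "") return(NULL)
      as.numeric(stringr::str_split_1(stringr::str_trim(d), "\\s+"))
    })
    ok <- mapply(function(p, d) is.null(d) || length(d) == length(p),
                 phon, durs)
    if (any(!ok)) {
      warning(sum(!ok), " row(s) rejected: duration count does not match ",
              "phoneme count", call. = FALSE)
    }
  } else {
    durs <- rep(list(NULL), nrow(raw))
    ok <- rep(TRUE, nrow(raw))
  }
  tibble::tibble(
    child_id = raw$child_id[ok],
    speaker_role = raw$speaker_role[ok],
    age_months = raw$age_months[ok],
    phonemes = phon[ok],
    durations_ms = durs[ok]
  )
}

#' @rdname read_corpus_tsv
#' @param corpus A corpus tibble.
#' @export
write_corpus_tsv <- function(corpus, path, delim = "") {
  has_dur <- any(!vapply(corpus$durations_ms, is.null, logical(1)))
  out <- tibble::tibble(
    child_id = corpus$child_id,
    speaker_role = corpus$speaker_role,
    age_months = corpus$age_months,
    phonemes = vapply(corpus$phonemes, paste0, character(1),
                      collapse = delim)
  )
  if (has_dur) {
    out$durations_ms <- vapply(corpus$durations_ms, function(d) {
      if (is.null(d)) "" else paste(format(d, trim = TRUE, scientific = FALSE),
                                    collapse = " ")
    }, character(1))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
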
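# Phoneme inventory, place/manner classification and the nine ordered
# CVC categories.

PLACE_CODE <- c(labial = "L", coronal = "C", dorsal = "D")

#' The nine ordered CVC category labels
#'
#' A CVC unit is labelled by the places of articulation of its two
#' consonants, in order: L = labial, C = coronal, D = dorsal. The nine
#' ordered pairs are returned in their canonical order.
#'
#' @return Character vector of length nine: `LL, LC, LD, CL, CC, CD, DL,
#'   DC, DD`.
#' @export
#' @examples
#' cvc_categories()
cvc_categories <- function() {
  paste0(rep(unname(PLACE_CODE), each = 3), rep(unname(PLACE_CODE), 3))
}

#' Build a consonant table
#'
#' A consonant table defines the admissible consonant inventory (each
#' consonant mapped to a place of articulation and a manner), the vowel
#' set, a vowel frontness map (carried for completeness; the core measures
#' omit vowels), and an alias map used to fold transcription variants
#' (e.g. a moraic nasal written as a distinct symbol) onto base phonemes.
#'
#' @param consonants Data frame with columns `phoneme`, `place`
#'   (labial/coronal/dorsal) and `manner` (stop/nasal).
#' @param vowels Character vector of vowel symbols.
#' @param frontness Named character vector mapping vowels to
#'   front/center/back.
#' @param aliases Named character vector; names are symbols to be rewritten
#'   to the corresponding base phoneme before extraction.
#' @return An object of class `consonant_table`.
#' @export
consonant_table <- function(consonants, vowels, frontness = character(),
                            aliases = character()) {
  consonants <- tibble::as_tibble(consonants)
  stopifnot(all(c("phoneme", "place", "manner") %in% names(consonants)))
  if (!all(consonants$place %in% names(PLACE_CODE))) {
    stop("consonant place must be one of labial, coronal, dorsal")
  }
  if (anyDuplicated(consonants$phoneme)) {
    stop("duplicated consonant symbol in table")
  }
  overlap <- intersect(consonants$phoneme, vowels)
  if (length(overlap)) {
    stop("symbols cannot be both consonant and vowel: ",
         paste(overlap, collapse = ", "))
  }
  structure(
    list(consonants = consonants, vowels = unique(vowels),
         frontness = frontness, aliases = aliases),
    class = "consonant_table"
  )
}

#' The default eight-consonant table
#'
#' The analysis restricts attention to the stop and nasal consonants that
#' dominate early speech: labial \[p\], \[b\], \[m\]; coronal \[t\], \[d\],
#' \[n\]; dorsal \[k\], \[g\]. Fricatives, glides and affricates are
#' excluded by construction. The default vowel set is the five cardinal
#' symbols `a i u e o` plus common IPA variants; vowel identity never
#' enters the core measures, only CVC shape detection.
#'
#' @param vowels Vowel symbols; override for corpus-specific inventories.
#' @param aliases Symbol rewrites applied before extraction; the default
#'   folds moraic-nasal notations onto \[n\].
#' @return A `consonant_table`.
#' @export
#' @examples
#' tab <- default_consonant_table()
#' classify_pair("p", "t", tab)
default_consonant_table <- function(
    vowels = c("a", "i", "u", "e", "o",
               "ɑ", "æ", "ɛ", "ɪ", "ʊ",
               "ə", "ʌ", "ɔ"),
    aliases = c("ん" = "n", "ン" = "n", "ɴ" = "n")) {
  cons <- tibble::tibble(
    phoneme = c("p", "b", "m", "t", "d", "n", "k", "g"),
    place = c("labial", "labial", "labial",
              "coronal", "coronal", "coronal",
              "dorsal", "dorsal"),
    manner = c("stop", "stop", "nasal", "stop", "stop", "nasal",
               "stop", "stop")
  )
  frontness <- c(
    i = "front", e = "front", "ɪ" = "front", "ɛ" = "front",
    "æ" = "front",
    a = "center", "ə" = "center", "ʌ" = "center",
    u = "back", o = "back", "ʊ" = "back", "ɔ" = "back",
    "ɑ" = "back"
  )
  consonant_table(cons, vowels, frontness, aliases)
}

#' @export
print.consonant_table <- function(x, ...) {
  cat("<consonant_table> ", nrow(x$consonants), " consonants, ",
      length(x$vowels), " vowels\n", sep = "")
  print(x$consonants)
  invisible(x)
}

place_of <- function(phonemes, table) {
  table$consonants$place[match(phonemes, table$consonants$phoneme)]
}

is_consonant <- function(phonemes, table) {
  phonemes %in% table$consonants$phoneme
}

is_vowel <- function(phonemes, table) {
  phonemes %in% table$vowels
}

#' Classify a consonant pair into a CVC category
#'
#' Vectorized over the two consonant arguments. A pair is classified only
#' when both consonants belong to the admissible set of `table`; otherwise
#' `NA` is returned (absence is a value, not an error).
#'
#' @param c1,c2 Character vectors of phoneme symbols (first and second
#'   consonant of a CVC unit).
#' @param table A `consonant_table`.
#' @return Character vector of category labels (see [cvc_categories()]),
#'   `NA` where a consonant is outside the table.
#' @export
#' @examples
#' classify_pair(c("p", "n", "p"), c("t", "n", "s"), default_consonant_table())
classify_pair <- function(c1, c2, table = default_consonant_table()) {
  p1 <- place_of(c1, table)
  p2 <- place_of(c2, table)
  out <- paste0(PLACE_CODE[p1], PLACE_CODE[p2])
  out[is.na(p1) | is.na(p2)] <- NA_character_
  out
}

#' Read or write a consonant table as a YAML config file
#'
#' The on-disk form is a small YAML mapping: `consonants` (symbol ->
#' place/manner), `vowels`, `frontness`, `aliases`. This lets corpus-
#' specific romanization variants be mapped in without code changes.
#'
#' @param path File path.
#' @return `read_consonant_table()` returns a `consonant_table`;
#'   `write_consonant_table()` returns `path` invisibly.
#' @export
read_consonant_table <- function(path) {
  y <- yaml::read_yaml(path)
  cons <- tibble::tibble(
    phoneme = names(y$consonants),
    place = unname(vapply(y$consonants, function(e) e$place, character(1))),
    manner = unname(vapply(y$consonants, function(e) e$manner, character(1)))
  )
  consonant_table(cons, unlist(y$vowels),
                  unlist(y$frontness) %||% character(),
                  unlist(y$aliases) %||% character())
}

#' @rdname read_consonant_table
#' @param table A `consonant_table`.
#' @export
write_consonant_table <- function(table, path) {
  cons <- stats::setNames(
    lapply(seq_len(nrow(table$consonants)), function(i) {
      list(place = table$consonants$place[i],
           manner = table$consonants$manner[i])
    }),
    table$consonants$phoneme
  )
  yaml::write_yaml(
    list(consonants = cons, vowels = as.list(table$vowels),
         frontness = as.list(table$frontness),
         aliases = as.list(table$aliases)),
    path
  )
  invisible(path)
}
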
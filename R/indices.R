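# Per-month developmental measures computed from monthly CVC category
# counts. All are vectorized over the rows of a count_monthly() table and
# return NA for months where the defining denominator is zero: such months
# carry no information about preference and are omitted from index series
# rather than imputed as 0.

FRONTING_A <- c("LC", "LD", "CD")  # front-to-back orderings
FRONTING_B <- c("CL", "DL", "DC")  # back-to-front orderings

row_sum <- function(counts, cols) {
  rowSums(as.matrix(counts[, cols, drop = FALSE]))
}

ratio_or_na <- function(num, den) {
  ifelse(den > 0, num / den, NA_real_)
}

#' Repetition ratio
#'
#' Fraction of CVC tokens whose two consonants share a place of
#' articulation: `(LL + CC + DD) / total`. `NA` where `total` is zero.
#'
#' @param counts A monthly-counts tibble from [count_monthly()].
#' @return Numeric vector, one value per row of `counts`, in `[0, 1]`.
#' @export
repetition_ratio <- function(counts) {
  ratio_or_na(row_sum(counts, c("LL", "CC", "DD")), counts$total)
}

#' Fronting index
#'
#' Asymmetry between front-to-back orderings (`a = LC + LD + CD`) and
#' back-to-front orderings (`b = CL + DL + DC`): `(a - b) / (a + b)`,
#' in `[-1, 1]`; positive values mean fronting patterns are preferred over
#' backing ones. With `pair` given (`"LC"`, `"LD"` or `"CD"`), `a` and `b`
#' restrict to that pattern pair (e.g. `pair = "LC"`: `a` = LC count,
#' `b` = CL count), giving the per-pattern fronting curves. `NA` where
#' `a + b` is zero.
#'
#' @inheritParams repetition_ratio
#' @param pair Optional pattern pair restriction.
#' @return Numeric vector in `[-1, 1]`.
#' @export
fronting_index <- function(counts, pair = NULL) {
  if (is.null(pair)) {
    a <- row_sum(counts, FRONTING_A)
    b <- row_sum(counts, FRONTING_B)
  } else {
    pair <- match.arg(pair, c("LC", "LD", "CD"))
    rev_pair <- paste0(substr(pair, 2, 2), substr(pair, 1, 1))
    a <- counts[[pair]]
    b <- counts[[rev_pair]]
  }
  ratio_or_na(a - b, a + b)
}

#' Intra-organ articulation ratio
#'
#' Fraction of tokens alternating between the two tongue places (coronal
#' and dorsal): `(CD + DC) / total`. `NA` where `total` is zero.
#'
#' @inheritParams repetition_ratio
#' @return Numeric vector in `[0, 1]`.
#' @export
intra_organ_ratio <- function(counts) {
  ratio_or_na(row_sum(counts, c("CD", "DC")), counts$total)
}

#' Inter-organ articulation ratios
#'
#' Fractions of tokens alternating between lips and tongue, split by the
#' tongue place involved: labial-coronal `(LC + CL) / total` and
#' labial-dorsal `(LD + DL) / total`. `NA` components where `total` is
#' zero.
#'
#' @inheritParams repetition_ratio
#' @return A tibble with columns `inter_LC` and `inter_LD`.
#' @export
inter_organ_ratios <- function(counts) {
  tibble::tibble(
    inter_LC = ratio_or_na(row_sum(counts, c("LC", "CL")), counts$total),
    inter_LD = ratio_or_na(row_sum(counts, c("LD", "DL")), counts$total)
  )
}

#' Compute all per-month index series from monthly counts
#'
#' Produces the long table of developmental measures consumed by the
#' curve-fitting step: repetition ratio, global and per-pair fronting
#' indices, intra-organ ratio and the two inter-organ ratios. Months whose
#' measure-specific token count (`n_tokens`: `total` for ratio measures,
#' `a + b` for fronting indices) is zero or below `min_tokens` are
#' omitted, not reported as zero.
#'
#' @inheritParams repetition_ratio
#' @param min_tokens Minimum measure-relevant tokens for a month to enter
#'   the series (default 1, i.e. every month with data).
#' @return A tibble `child_id`, `speaker_role`, `measure`, `month`,
#'   `value`, `n_tokens`, sorted by month within measure.
#' @export
compute_indices <- function(counts, min_tokens = 1) {
  base <- counts[, c("child_id", "speaker_role", "month")]
  inter <- inter_organ_ratios(counts)
  pieces <- list(
    repetition = list(value = repetition_ratio(counts), n = counts$total),
    fronting = list(
      value = fronting_index(counts),
      n = row_sum(counts, FRONTING_A) + row_sum(counts, FRONTING_B)
    ),
    fronting_LC = list(value = fronting_index(counts, "LC"),
                       n = counts$LC + counts$CL),
    fronting_LD = list(value = fronting_index(counts, "LD"),
                       n = counts$LD + counts$DL),
    fronting_CD = list(value = fronting_index(counts, "CD"),
                       n = counts$CD + counts$DC),
    intra = list(value = intra_organ_ratio(counts), n = counts$total),
    inter_LC = list(value = inter$inter_LC, n = counts$total),
    inter_LD = list(value = inter$inter_LD, n = counts$total)
  )
  out <- purrr::imap(pieces, function(p, nm) {
    dplyr::mutate(base, measure = nm, value = p$value,
                  n_tokens = as.integer(p$n))
  }) |>
    purrr::list_rbind() |>
    dplyr::filter(!is.na(.data$value), .data$n_tokens >= min_tokens) |>
    dplyr::select("child_id", "speaker_role", "measure", "month",
                  "value", "n_tokens") |>
    dplyr::arrange(.data$child_id, .data$speaker_role, .data$measure,
                   .data$month)
  out
}

#' Monthly mean CVCV durations
#'
#' Bins CVCV durations by integer month of age and reports the per-month
#' arithmetic mean, sample (n-1) standard deviation (0 for single-token
#' months) and token count. Empty months are absent from the series.
#'
#' @param durations Tibble from [extract_cvcv_durations()].
#' @param pool Pool across children?
#' @return A tibble `child_id`, `speaker_role`, `measure`
#'   (`"cvcv_duration"`), `month`, `value` (mean ms), `sd_ms`, `n_tokens`.
#' @export
mean_cvcv_duration <- function(durations, pool = FALSE) {
  if (!nrow(durations)) {
    return(tibble::tibble(
      child_id = character(), speaker_role = character(),
      measure = character(), month = integer(), value = numeric(),
      sd_ms = numeric(), n_tokens = integer()
    ))
  }
  durations |>
    dplyr::mutate(
      child_id = if (pool) "POOLED" else .data$child_id,
      month = as.integer(floor(.data$age_months))
    ) |>
    dplyr::summarise(
      value = mean(.data$duration_ms),
      sd_ms = if (dplyr::n() > 1) sd(.data$duration_ms) else 0,
      n_tokens = dplyr::n(),
      .by = c("child_id", "speaker_role", "month")
    ) |>
    dplyr::mutate(measure = "cvcv_duration") |>
    dplyr::select("child_id", "speaker_role", "measure", "month",
                  "value", "sd_ms", "n_tokens") |>
    dplyr::arrange(.data$child_id, .data$speaker_role, .data$month)
}
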
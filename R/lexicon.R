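#' Normalize a transcribed reason phrase
#'
#' Case-folds, trims and collapses internal whitespace. Deterministic and
#' idempotent; applied to both lexicon patterns and survey phrases before
#' matching so that transcription artefacts in spacing or capitalisation do
#' not affect the mapping.
#'
#' @param phrase Character vector of free-text phrases.
#' @return Normalized character vector.
#' @examples
#' normalize_phrase("  Big Body ") # "big body"
#' @export
normalize_phrase <- function(phrase) {
  stringr::str_squish(stringr::str_to_lower(as.character(phrase)))
}

#' Reason lexicon: phrase patterns to trait groups
#'
#' The lexicon maps normalized keyword patterns to the seven trait groups
#' (see [trait_groups()]). It is deliberately data, not code: the grouping
#' of open interview answers is a transcription judgement, so the bundled
#' study lexicon can be replaced or extended with a two-column CSV
#' (`pattern`, `trait_group`). No pattern may map to two groups.
#'
#' @param path CSV file with columns `pattern` and `trait_group`.
#' @param groups Allowed trait-group labels.
#' @return A tibble with columns `pattern` (normalized) and `trait_group`.
#' @export
read_lexicon <- function(path, groups = trait_groups()) {
  if (!file.exists(path)) abort(paste0("lexicon file not found: ", path))
  lex <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("pattern", "trait_group") %in% names(lex))) {
    abort("lexicon needs columns: pattern, trait_group")
  }
  lex <- tibble::tibble(
    pattern = normalize_phrase(lex$pattern),
    trait_group = as.character(lex$trait_group)
  )
  bad <- setdiff(unique(lex$trait_group), groups)
  if (length(bad) > 0) {
    abort(paste0("unknown trait group(s) in lexicon: ",
                 paste(bad, collapse = ", ")))
  }
  dup <- unique(lex$pattern[duplicated(lex$pattern)])
  conflicted <- lex |>
    dplyr::filter(.data$pattern %in% dup) |>
    dplyr::distinct(.data$pattern, .data$trait_group) |>
    dplyr::count(.data$pattern) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicted) > 0) {
    abort(paste0("pattern(s) mapped to more than one group: ",
                 paste(conflicted$pattern, collapse = ", ")))
  }
  lex <- lex[!duplicated(lex$pattern), ]
  unreachable <- setdiff(groups, unique(lex$trait_group))
  if (length(unreachable) > 0) {
    warn(paste0("trait group(s) with no lexicon pattern: ",
                paste(unreachable, collapse = ", ")))
  }
  lex
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() {
  read_lexicon(ewepref_extdata("default_lexicon.csv"))
}

#' Map free-text reasons to trait groups
#'
#' Matches each normalized phrase against the lexicon patterns and fills
#' `trait_group`. A pattern matches when it occurs as a substring of the
#' normalized phrase; among matching patterns the longest wins, with ties
#' broken by lexicon order. Unmatched phrases are left unmapped and listed
#' in the attached report — an unmapped reason is a data condition to act
#' on (extend the lexicon), not an error.
#'
#' @param reasons Tibble of reason records (from [read_reason_records()]).
#' @param lexicon Lexicon tibble (default: the bundled study lexicon).
#' @return The reasons tibble with `trait_group` filled where matched;
#'   attribute `"unmapped"` holds a tibble (`ewe_id`, `order`, `phrase`) of
#'   unmatched rows. Mapped plus unmapped rows always account for every
#'   input row.
#' @examples
#' ewes <- tibble::tibble(ewe_id = "e1")
#' r <- tibble::tibble(ewe_id = "e1", order = 1:2,
#'                     phrase = c("Twinning", "fat cover"))
#' r <- validate_reason_records(r, ewes)
#' map_reasons(r)$trait_group
#' @export
map_reasons <- function(reasons, lexicon = default_lexicon()) {
  stopifnot(all(c("ewe_id", "order", "phrase") %in% names(reasons)))
  lex <- lexicon[order(-nchar(lexicon$pattern)), ] # longest first, stable
  phr <- normalize_phrase(reasons$phrase)
  grp <- rep(NA_character_, length(phr))
  for (u in unique(phr)) {
    hit <- which(stringr::str_detect(u, stringr::fixed(lex$pattern)))
    if (length(hit) > 0) grp[phr == u] <- lex$trait_group[hit[1]]
  }
  out <- reasons
  out$trait_group <- grp
  unmapped <- tibble::as_tibble(
    reasons[is.na(grp), c("ewe_id", "order", "phrase")]
  )
  if (nrow(unmapped) > 0) {
    inform(paste0(nrow(unmapped), " reason(s) left unmapped; see ",
                  "unmapped_report()"))
  }
  attr(out, "unmapped") <- unmapped
  attr(out, "quarantine") <- attr(reasons, "quarantine")
  out
}

#' Unmapped-phrase report from [map_reasons()]
#'
#' @param x Tibble returned by [map_reasons()].
#' @return Tibble of unmatched rows (`ewe_id`, `order`, `phrase`).
#' @export
unmapped_report <- function(x) {
  attr(x, "unmapped") %||%
    tibble::tibble(ewe_id = character(), order = integer(),
                   phrase = character())
}
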
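#' Rescale across-breed ranks to the 1-9 scale
#'
#' Farmers rank all ewes on a farm from 1 (most preferred) to the number of
#' ewes present. On farms with only two breed groups there are six ewes, so
#' the raw ranks run 1-6 and are stretched onto the nine-ewe scale with the
#' affine map `new = 1 + (old - 1) * 1.6`, which fixes the endpoints
#' (1 -> 1, 6 -> 9) and preserves order. Nine-ewe ranks pass through
#' unchanged. Rescaled ranks are kept as reals (the map yields 2.6, 4.2,
#' ...); summaries are reported to one decimal.
#'
#' @param rank Integer raw rank(s), `1..n_ewes_on_farm`.
#' @param n_ewes_on_farm Number of ranked ewes on the farm: 6 or 9
#'   (recycled against `rank`).
#' @return Numeric rescaled rank(s) in \[1, 9\]; `NA` maps to `NA`.
#' @examples
#' rescale_rank(4, 6) # 5.8
#' @export
rescale_rank <- function(rank, n_ewes_on_farm) {
  n <- as.numeric(n_ewes_on_farm)
  if (any(!n %in% c(6, 9))) {
    abort("n_ewes_on_farm must be 6 or 9")
  }
  rank <- as.numeric(rank)
  n <- rep_len(n, length(rank))
  ok <- is.na(rank) | (rank >= 1 & rank <= n & rank == round(rank))
  if (!all(ok)) {
    abort("rank must be an integer in 1..n_ewes_on_farm")
  }
  ifelse(n == 9, rank, 1 + (rank - 1) * 1.6)
}

#' Average rescaled rank per breed group and site
#'
#' Summarises the across-breed preference ranking: ranks from six-ewe farms
#' are rescaled to the 1-9 scale ([rescale_rank()]) and averaged per breed
#' group within site (lower mean = more preferred). The number of ranked
#' ewes on each farm is inferred from the breed groups present on that farm
#' (three groups -> nine ewes, two -> six). Missing ranks are excluded
#' pairwise and counted.
#'
#' @param ewes Validated ewe records with `across_breed_rank` on the raw
#'   scale.
#' @param per_farm If `TRUE`, average farm-level means instead of pooling
#'   ewes directly.
#' @return Tibble with `site`, `breed`, `n_ewes` (ranked), `n_missing`,
#'   `mean_rank`.
#' @export
summarize_breed_ranks <- function(ewes, per_farm = FALSE) {
  farm_n <- ewes |>
    dplyr::group_by(.data$farmer_id) |>
    dplyr::summarise(n_on_farm = dplyr::n(), .groups = "drop")
  bad <- farm_n$n_on_farm[!farm_n$n_on_farm %in% c(6, 9)]
  if (length(bad) > 0) {
    abort("farms must hold 6 or 9 ewes to interpret across-breed ranks")
  }
  dat <- ewes |>
    dplyr::left_join(farm_n, by = "farmer_id") |>
    dplyr::mutate(rank9 = rescale_rank(.data$across_breed_rank,
                                       .data$n_on_farm))
  no_rank_sites <- dat |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(any_rank = any(!is.na(.data$rank9)), .groups = "drop")
  if (any(!no_rank_sites$any_rank)) {
    warn(paste0("site(s) without any ranked ewes omitted: ",
                paste(no_rank_sites$site[!no_rank_sites$any_rank],
                      collapse = ", ")))
  }
  dat <- dat |>
    dplyr::semi_join(no_rank_sites[no_rank_sites$any_rank, "site"],
                     by = "site")
  if (per_farm) {
    dat |>
      dplyr::group_by(.data$site, .data$breed, .data$farmer_id) |>
      dplyr::summarise(
        n_ewes = sum(!is.na(.data$rank9)),
        n_missing = sum(is.na(.data$rank9)),
        farm_mean = mean(.data$rank9, na.rm = TRUE),
        .groups = "drop"
      ) |>
      dplyr::group_by(.data$site, .data$breed) |>
      dplyr::summarise(
        n_ewes = sum(.data$n_ewes),
        n_missing = sum(.data$n_missing),
        mean_rank = mean(.data$farm_mean[is.finite(.data$farm_mean)]),
        .groups = "drop"
      )
  } else {
    dat |>
      dplyr::group_by(.data$site, .data$breed) |>
      dplyr::summarise(
        n_ewes = sum(!is.na(.data$rank9)),
        n_missing = sum(is.na(.data$rank9)),
        mean_rank = mean(.data$rank9, na.rm = TRUE),
        .groups = "drop"
      )
  }
}
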
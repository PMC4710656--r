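#' Weight scheme for ordered reasons
#'
#' Weights applied to reason orders when accumulating the weighted-reasons
#' index: the most important reason counts triple, the second double, the
#' third single (`3, 2, 1` by default). Alternative schemes — equal weights
#' `c(1, 1, 1)` or steeper ones such as `c(5, 3, 1)` — are accepted for
#' sensitivity analysis.
#'
#' @param w Positive numeric vector of weights; element `j` is the weight
#'   of order-`j` reasons.
#' @return Named numeric vector (names are the orders).
#' @export
weight_scheme <- function(w = c(3, 2, 1)) {
  w <- as.numeric(w)
  if (length(w) < 1 || any(!is.finite(w)) || any(w <= 0)) {
    abort("weights must be positive finite numbers")
  }
  setNames(w, as.character(seq_along(w)))
}

#' Tally reason counts per stratum
#'
#' Counts, within each stratum (by default site x breed x quality class),
#' the number of respondents giving an order-`j` reason to each trait
#' group: the `X_ji` feeding the weighted-reasons index. All reasons must
#' already be mapped; the per-stratum counts are completed over every trait
#' group and observed order so that zero cells are explicit.
#'
#' @param reasons Mapped reason records ([map_reasons()]).
#' @param ewes Validated ewe records supplying the stratification columns.
#' @param by Character vector of ewe columns defining the strata.
#' @param groups Trait-group universe for zero-completion.
#' @return Tibble with the `by` columns, `trait_group`, `order`, `n`.
#' @export
tally_reason_counts <- function(reasons, ewes,
                                by = c("site", "breed", "quality"),
                                groups = trait_groups()) {
  if (any(is.na(reasons$trait_group))) {
    abort(paste0("unmapped reasons present; run map_reasons() and inspect ",
                 "unmapped_report() before tallying"))
  }
  stopifnot(all(by %in% names(ewes)))
  joined <- dplyr::inner_join(
    reasons[, c("ewe_id", "order", "trait_group")],
    ewes[, c("ewe_id", by)],
    by = "ewe_id"
  )
  orders <- sort(unique(joined$order))
  joined |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "trait_group", "order"))),
                 name = "n") |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(by)),
      trait_group = groups,
      order = orders,
      fill = list(n = 0L)
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(by, "trait_group", "order"))))
}

#' Order-weighted contributions and trait sums
#'
#' Multiplies each count by its order weight (`c_ji = r_j * X_ji`) and sums
#' over orders to the per-trait score `S_i`. With the default integer
#' weights the arithmetic is exact.
#'
#' @param counts Count table from [tally_reason_counts()].
#' @param weights Order weights from [weight_scheme()].
#' @return Tibble like `counts` with an added `contribution` column.
#' @export
weighted_contributions <- function(counts, weights = weight_scheme()) {
  missing_orders <- setdiff(as.character(unique(counts$order)),
                            names(weights))
  if (length(missing_orders) > 0) {
    abort(paste0("order(s) present in counts but absent from the weight ",
                 "scheme: ", paste(missing_orders, collapse = ", ")))
  }
  counts$contribution <- unname(weights[as.character(counts$order)]) *
    counts$n
  counts
}

#' Weighted-reasons index from per-trait sums
#'
#' Normalizes per-trait scores to the weighted-reasons index
#' `WR_i = S_i / sum_i(S_i)`; the values sum to one exactly. An all-zero
#' input has no defined index: an empty vector is returned with a warning.
#'
#' @param sums Named non-negative numeric vector of per-trait scores.
#' @return Named numeric vector of WR values.
#' @examples
#' compute_wr(c(BodySizeAndGrowth = 19, Condition = 5, MilkProduction = 5,
#'              ReproductionAndMotheringAbility = 2, DroughtTolerance = 0,
#'              DiseaseResistance = 0, BreedAttributes = 5))
#' @export
compute_wr <- function(sums) {
  if (any(!is.finite(sums)) || any(sums < 0)) {
    abort("per-trait sums must be finite and non-negative")
  }
  total <- sum(sums)
  if (total == 0) {
    warn("all-zero trait sums: weighted reasons undefined for this stratum")
    return(setNames(numeric(0), character(0)))
  }
  sums / total
}

#' Weighted-reasons preference table per stratum
#'
#' One-step construction of the preference table from mapped reasons:
#' tallies counts, applies order weights, and normalizes per stratum. The
#' result mirrors the published layout — one row per stratum and trait
#' group with the weighted contributions by order (`c1`, `c2`, `c3`), their
#' plain sum, and the weighted-reasons index `wr`. Strata with no reasons
#' at all are dropped with a warning.
#'
#' @inheritParams tally_reason_counts
#' @inheritParams weighted_contributions
#' @return A `pref_table` tibble with the `by` columns, `trait_group`,
#'   one `c<j>` column per order, `sum` and `wr`.
#' @export
preference_table <- function(reasons, ewes,
                             by = c("site", "breed", "quality"),
                             weights = weight_scheme(),
                             groups = trait_groups()) {
  counts <- tally_reason_counts(reasons, ewes, by = by, groups = groups)
  contrib <- weighted_contributions(counts, weights) |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "order", values_from = "contribution",
                       names_prefix = "c", values_fill = 0)
  out <- wr_from_contributions(contrib, by = by)
  attr(out, "weights") <- weights
  out
}

#' Preference table from printed contribution columns
#'
#' Builds the preference table directly from already order-weighted
#' contributions (`c_ji = r_j * X_ji`), the form in which published
#' weighted-reasons tables print their "Reasons 1-3" columns. This is the
#' ingestion path for the bundled study table (see
#' [study_contributions()]).
#'
#' @param contrib Tibble with stratification columns, `trait_group`, and
#'   contribution columns `c1`, `c2`, ... .
#' @param by Stratification columns; defaults to every column other than
#'   `trait_group` and the contribution columns.
#' @return A `pref_table` tibble (see [preference_table()]).
#' @export
wr_from_contributions <- function(contrib, by = NULL) {
  ccols <- grep("^c[0-9]+$", names(contrib), value = TRUE)
  if (length(ccols) == 0) abort("no contribution columns c1, c2, ... found")
  by <- by %||% setdiff(names(contrib), c("trait_group", ccols))
  out <- contrib |>
    dplyr::mutate(sum = rowSums(dplyr::across(dplyr::all_of(ccols)))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(total = sum(.data$sum)) |>
    dplyr::ungroup()
  empty <- out$total == 0
  if (any(empty)) {
    warn(paste0(length(unique(out[empty, by, drop = FALSE])),
                " stratum(s) with no reasons dropped"))
    out <- out[!empty, ]
  }
  out$wr <- out$sum / out$total
  out$total <- NULL
  structure(out, by = by, class = c("pref_table", class(out)))
}

#' Recover raw counts from weighted contributions
#'
#' Inverts the order weighting (`X_ji = c_ji / r_j`). Contributions must be
#' exactly divisible by their order weight; anything else indicates the
#' input was not produced by that weight scheme.
#'
#' @param contrib Tibble with contribution columns `c1`, `c2`, ... .
#' @param weights Order weights used to build the contributions.
#' @return `contrib` with the `c<j>` columns replaced by counts `x<j>`.
#' @export
contributions_to_counts <- function(contrib, weights = weight_scheme()) {
  ccols <- grep("^c[0-9]+$", names(contrib), value = TRUE)
  for (cc in ccols) {
    j <- sub("^c", "", cc)
    if (!j %in% names(weights)) {
      abort(paste0("no weight defined for order ", j))
    }
    x <- contrib[[cc]] / weights[[j]]
    if (any(abs(x - round(x)) > 1e-9)) {
      abort(paste0("column ", cc, " is not divisible by its weight ",
                   weights[[j]], "; not a contribution table for this ",
                   "weight scheme"))
    }
    contrib[[cc]] <- NULL
    contrib[[paste0("x", j)]] <- as.integer(round(x))
  }
  contrib
}

#' Published study contribution table
#'
#' The bundled order-weighted reason contributions of the study: Best and
#' Poor quality ewes by breed group and site, seven trait groups, weights
#' 3/2/1 already applied.
#'
#' @return Tibble with `quality`, `site`, `breed`, `trait_group`, `c1`,
#'   `c2`, `c3`.
#' @export
study_contributions <- function() {
  readr::read_csv(ewepref_extdata("study_contributions.csv"),
                  show_col_types = FALSE, progress = FALSE)
}

#' Clustered trait-category scheme
#'
#' Condenses the seven trait groups into four categories for an overview of
#' what characterises each breed by site: Body Size and Growth and
#' Condition stay as they are, Milk Production joins Reproduction and
#' Mothering Ability as "Reproduction and Milk", and the two adaptive
#' traits merge into "Adaptation". Breed Attributes is excluded (responses
#' are few and heterogeneous) and, by default, the clustered index is
#' renormalized over the remaining groups so it still sums to one.
#'
#' @param mapping Named character vector: trait group -> cluster.
#' @param exclude Trait groups dropped before clustering.
#' @param renormalize If `TRUE` (default) divide by the total over
#'   non-excluded groups; if `FALSE`, keep the original denominator.
#' @return A `cluster_scheme` list.
#' @export
cluster_scheme <- function(mapping = c(
                             BodySizeAndGrowth = "BodySizeAndGrowth",
                             Condition = "Condition",
                             MilkProduction = "ReproductionAndMilk",
                             ReproductionAndMotheringAbility =
                               "ReproductionAndMilk",
                             DroughtTolerance = "Adaptation",
                             DiseaseResistance = "Adaptation"
                           ),
                           exclude = "BreedAttributes",
                           renormalize = TRUE) {
  structure(list(mapping = mapping, exclude = exclude,
                 renormalize = renormalize),
            class = "cluster_scheme")
}

#' Clustered weighted-reasons table
#'
#' Accumulates the per-trait scores of a preference table into the
#' clustered categories of a [cluster_scheme()] and recomputes the index.
#'
#' @param pref A `pref_table` from [preference_table()] or
#'   [wr_from_contributions()].
#' @param scheme A [cluster_scheme()].
#' @return A `cluster_table` tibble with the stratification columns,
#'   `cluster`, `sum` and `wr`.
#' @export
cluster_wr <- function(pref, scheme = cluster_scheme()) {
  by <- attr(pref, "by") %||%
    setdiff(names(pref), c("trait_group", grep("^c[0-9]+$", names(pref),
                                               value = TRUE),
                           "sum", "wr"))
  mapped <- setdiff(unique(pref$trait_group), scheme$exclude)
  unknown <- setdiff(mapped, names(scheme$mapping))
  if (length(unknown) > 0) {
    abort(paste0("trait group(s) not covered by the cluster scheme: ",
                 paste(unknown, collapse = ", ")))
  }
  kept <- pref[!pref$trait_group %in% scheme$exclude, ]
  kept$cluster <- unname(scheme$mapping[kept$trait_group])
  totals <- pref |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(total_all = sum(.data$sum), .groups = "drop")
  out <- kept |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "cluster")))) |>
    dplyr::summarise(sum = sum(.data$sum), .groups = "drop") |>
    tidyr::complete(tidyr::nesting(!!!rlang::syms(by)),
                    cluster = unique(unname(scheme$mapping)),
                    fill = list(sum = 0)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(total_kept = sum(.data$sum)) |>
    dplyr::ungroup() |>
    dplyr::left_join(totals, by = by)
  denom <- if (scheme$renormalize) out$total_kept else out$total_all
  out$wr <- ifelse(denom > 0, out$sum / denom, NA_real_)
  out$total_kept <- NULL
  out$total_all <- NULL
  structure(out, by = by, class = c("cluster_table", class(out)))
}

#' Render a preference or cluster table for publication
#'
#' Formats the weighted-reasons index to two decimals with half-up
#' rounding (the convention of the published tables) and optionally writes
#' the result to CSV. The underlying values are untouched; only the `wr`
#' column is formatted.
#'
#' @param tbl A `pref_table` or `cluster_table`.
#' @param path Optional CSV output path.
#' @return Tibble with `wr` replaced by its formatted text.
#' @export
render_preference_report <- function(tbl, path = NULL) {
  out <- tibble::as_tibble(tbl)
  out$wr <- format_2dp(out$wr)
  if (!is.null(path)) readr::write_csv(out, path, progress = FALSE)
  out
}
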
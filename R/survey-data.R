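#' Read and validate ewe survey records
#'
#' Reads the ewe-level table of a participatory flock survey: one row per
#' surveyed ewe with identity, grouping factors (farmer, site, breed group,
#' within-flock quality class), body measurements, estimated daily milk
#' yield, the price the farmer would pay for the ewe, approximate age from
#' dentition, and the raw across-breed rank. Rows violating record
#' invariants are quarantined, not dropped silently: the returned tibble
#' carries a row-level validation report retrievable with
#' [quarantine_report()], and every input row is accounted for either as a
#' record or as a reported rejection.
#'
#' Record invariants: body measurements positive and finite; body condition
#' score on the half-point grid in \[1, 5\]; milk yield non-negative (zero is
#' a valid value meaning no extra milk after the lambs have suckled); price
#' a positive whole number of KES; age, when present, in \[1, 9\]; each
#' farmer belongs to exactly one site; within one farm and breed group each
#' quality class appears at most once.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, header row,
#'   decimal point).
#' @param col_map Optional named character vector mapping the standard
#'   column names (names) to the column names used in the file (values),
#'   e.g. `c(body_weight = "bw_kg")`.
#' @param sites,breeds,qualities Allowed factor labels; defaults are the
#'   study configuration from [study_metadata()].
#' @return A tibble of validated ewe records with attribute `"quarantine"`
#'   (a tibble with columns `row`, `ewe_id`, `reason`).
#' @seealso [read_reason_records()], [write_ewe_records()]
#' @export
read_ewe_records <- function(path, col_map = NULL,
                             sites = study_metadata()$sites,
                             breeds = study_metadata()$breeds,
                             qualities = study_metadata()$qualities) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw <- apply_col_map(raw, col_map)
  if (nrow(raw) == 0) {
    warn("empty ewe file: no records read")
  }
  validate_ewe_records(raw, sites = sites, breeds = breeds,
                       qualities = qualities)
}

ewe_mandatory_cols <- function() {
  c("ewe_id", "farmer_id", "site", "breed", "quality",
    "body_weight", "body_length", "heart_girth", "bcs", "milk_yield",
    "price")
}

ewe_optional_cols <- function() {
  c("age", "coat_colour", "across_breed_rank")
}

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  stopifnot(is.character(col_map), !is.null(names(col_map)))
  for (std in names(col_map)) {
    src <- col_map[[std]]
    if (!src %in% names(df)) {
      abort(paste0("mapped column not in file: ", src))
    }
    names(df)[names(df) == src] <- std
  }
  df
}

#' Validate a data frame of ewe records
#'
#' Applies the record invariants documented in [read_ewe_records()] to an
#' in-memory data frame. Invalid rows are quarantined with a reason and the
#' remaining rows are returned as validated records.
#'
#' @param df A data frame with the standard ewe columns.
#' @inheritParams read_ewe_records
#' @return A tibble of valid records with a `"quarantine"` attribute.
#' @export
validate_ewe_records <- function(df,
                                 sites = study_metadata()$sites,
                                 breeds = study_metadata()$breeds,
                                 qualities = study_metadata()$qualities) {
  missing_cols <- setdiff(ewe_mandatory_cols(), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  for (opt in ewe_optional_cols()) {
    if (!opt %in% names(df)) df[[opt]] <- NA
  }
  df$ewe_id <- as.character(df$ewe_id)
  df$farmer_id <- as.character(df$farmer_id)
  df$coat_colour <- as.character(df$coat_colour)
  for (num in c("body_weight", "body_length", "heart_girth", "bcs",
                "milk_yield", "price", "age", "across_breed_rank")) {
    df[[num]] <- suppressWarnings(as.numeric(df[[num]]))
  }

  n <- nrow(df)
  reason <- character(n)
  flag <- function(bad, why) {
    bad <- which(bad & reason == "")
    reason[bad] <<- why
  }

  on_grid <- function(x, step) abs(x / step - round(x / step)) < 1e-8
  flag(is.na(df$ewe_id) | df$ewe_id == "", "missing ewe_id")
  flag(duplicated(df$ewe_id), "duplicate ewe_id")
  flag(is.na(df$farmer_id) | df$farmer_id == "", "missing farmer_id")
  flag(!(df$site %in% sites), "unknown site")
  flag(!(df$breed %in% breeds), "unknown breed group")
  flag(!(df$quality %in% qualities), "unknown quality class")
  for (m in c("body_weight", "body_length", "heart_girth")) {
    flag(!is.finite(df[[m]]) | df[[m]] <= 0,
         paste0(m, " not a positive finite number"))
  }
  flag(!is.finite(df$bcs) | df$bcs < 1 | df$bcs > 5 | !on_grid(df$bcs, 0.5),
       "bcs not on the half-point grid in [1, 5]")
  flag(!is.finite(df$milk_yield) | df$milk_yield < 0,
       "milk_yield negative or missing")
  flag(!is.finite(df$price) | df$price <= 0 | !on_grid(df$price, 1),
       "price not a positive whole number")
  flag(!is.na(df$age) & (df$age < 1 | df$age > 9),
       "age outside [1, 9]")
  flag(!is.na(df$across_breed_rank) &
         (!on_grid(df$across_breed_rank, 1) |
            df$across_breed_rank < 1 | df$across_breed_rank > 9),
       "across_breed_rank not an integer in 1..9")

  # dataset-level invariants, applied to rows still standing
  ok_rows <- reason == ""
  site_per_farmer <- tapply(df$site[ok_rows], df$farmer_id[ok_rows],
                            function(s) length(unique(s)))
  multi <- names(site_per_farmer)[site_per_farmer > 1]
  flag(df$farmer_id %in% multi, "farmer_id appears in more than one site")
  key <- paste(df$farmer_id, df$breed, df$quality, sep = "\r")
  flag(reason == "" & duplicated(key),
       "duplicate quality class within farm and breed group")

  keep <- reason == ""
  quarantine <- tibble::tibble(
    row = which(!keep),
    ewe_id = df$ewe_id[!keep],
    reason = reason[!keep]
  )
  out <- df[keep, c(ewe_mandatory_cols(), ewe_optional_cols())]
  if (nrow(quarantine) > 0) {
    warn(paste0(nrow(quarantine), " ewe record(s) quarantined; see ",
                "quarantine_report()"))
  }
  attr(out, "quarantine") <- quarantine
  out
}

#' Row-level validation report of a loaded table
#'
#' @param x A tibble returned by [read_ewe_records()],
#'   [read_reason_records()], [validate_ewe_records()] or [map_reasons()].
#' @return The quarantine tibble (`row`, `ewe_id`, `reason`); empty when
#'   every row validated.
#' @export
quarantine_report <- function(x) {
  attr(x, "quarantine") %||%
    tibble::tibble(row = integer(), ewe_id = character(),
                   reason = character())
}

#' Read ordered reason records for surveyed ewes
#'
#' Reads the reason table: up to three free-text reasons per ewe, each with
#' an importance order (1 = most important). Orders beyond 3 are rejected
#' with a reason, matching the analysis convention that only the top three
#' ordered reasons enter the weighted-reasons index. Dangling ewe
#' references and duplicated orders within a ewe are quarantined likewise.
#'
#' @param path Path to a CSV file with columns `ewe_id`, `order`, `phrase`.
#' @param ewes Tibble of validated ewe records the reasons must refer to.
#' @param col_map Optional standard-to-file column name map as in
#'   [read_ewe_records()].
#' @return A tibble of reason records (`ewe_id`, `order`, `phrase`,
#'   `trait_group` initialised to `NA` until [map_reasons()] is applied),
#'   with a `"quarantine"` attribute.
#' @export
read_reason_records <- function(path, ewes, col_map = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  raw <- apply_col_map(raw, col_map)
  validate_reason_records(raw, ewes)
}

#' @rdname read_reason_records
#' @param df In-memory data frame of raw reason rows.
#' @export
validate_reason_records <- function(df, ewes) {
  needed <- c("ewe_id", "order", "phrase")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  df$ewe_id <- as.character(df$ewe_id)
  df$order <- suppressWarnings(as.numeric(df$order))
  df$phrase <- as.character(df$phrase)

  n <- nrow(df)
  reason <- character(n)
  flag <- function(bad, why) {
    bad <- which(bad & reason == "")
    reason[bad] <<- why
  }
  flag(!df$ewe_id %in% ewes$ewe_id, "ewe_id does not resolve")
  flag(is.na(df$order) | df$order != round(df$order) | df$order < 1,
       "order not a positive integer")
  flag(df$order > 3, "order beyond 3")
  flag(is.na(df$phrase) | stringr::str_trim(df$phrase) == "",
       "empty phrase")
  key <- paste(df$ewe_id, df$order, sep = "\r")
  flag(reason == "" & duplicated(key), "duplicate order within ewe")

  keep <- reason == ""
  quarantine <- tibble::tibble(
    row = which(!keep),
    ewe_id = df$ewe_id[!keep],
    reason = reason[!keep]
  )
  out <- df[keep, needed]
  out$order <- as.integer(out$order)
  if (!"trait_group" %in% names(out)) out$trait_group <- NA_character_
  if (nrow(quarantine) > 0) {
    warn(paste0(nrow(quarantine), " reason record(s) quarantined; see ",
                "quarantine_report()"))
  }
  attr(out, "quarantine") <- quarantine
  out
}

#' Write survey tables back to CSV
#'
#' Round-trip companions of [read_ewe_records()] and
#' [read_reason_records()]: reading a written file reproduces the records
#' field for field.
#'
#' @param records Tibble of validated records.
#' @param path Output CSV path.
#' @return The input, invisibly.
#' @export
write_ewe_records <- function(records, path) {
  readr::write_csv(records[, c(ewe_mandatory_cols(), ewe_optional_cols())],
                   path, progress = FALSE)
  invisible(records)
}

#' @rdname write_ewe_records
#' @export
write_reason_records <- function(records, path) {
  cols <- intersect(c("ewe_id", "order", "phrase", "trait_group"),
                    names(records))
  readr::write_csv(records[, cols], path, progress = FALSE)
  invisible(records)
}
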
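#' Round half away from zero
#'
#' Decimal rounding in which a digit of exactly five rounds away from zero
#' (so 0.125 becomes 0.13 at two decimals), unlike [base::round()], which
#' rounds half to even. All published tables in this package's reports are
#' rendered with this rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(1 / 8)   # 0.13
#' round_half_up(6 / 48)  # 0.13
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # the 1e-9 guard absorbs binary representation error just below a half
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

format_2dp <- function(x) {
  formatC(round_half_up(x, 2), format = "f", digits = 2)
}

#' Trait groups, clusters and study constants
#'
#' The seven trait groups into which farmers' free-text reasons are mapped,
#' the four clustered categories used for the condensed summary, and survey
#' metadata (sites, breed groups, quality classes, currency conversion).
#'
#' @return `trait_groups()` and `cluster_names()` return character vectors;
#'   `study_metadata()` returns a named list.
#' @export
trait_groups <- function() {
  c(
    "BodySizeAndGrowth", "Condition", "MilkProduction",
    "ReproductionAndMotheringAbility", "DroughtTolerance",
    "DiseaseResistance", "BreedAttributes"
  )
}

#' @rdname trait_groups
#' @export
cluster_names <- function() {
  c("BodySizeAndGrowth", "Condition", "ReproductionAndMilk", "Adaptation")
}

#' @rdname trait_groups
#' @export
study_metadata <- function() {
  list(
    sites = c("Amboseli", "Isinya"),
    breeds = c("RedMaasai", "Dorper", "Cross"),
    qualities = c("Best", "Average", "Poor"),
    kes_per_usd = 84
  )
}

ewepref_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ewepref")
  if (path == "") abort(paste0("bundled file not found: ", file))
  path
}
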
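#' Synthetic flock-survey design
#'
#' Configuration for the synthetic survey generator, defaulting to the
#' study layout: 19 farmers (10 Amboseli, 9 Isinya); 11 farms with all
#' three breed groups and 9 ewes, 6 farms with Red Maasai and Crosses
#' only, 2 with Dorper and Crosses only (6 ewes each) — 147 ewes in all;
#' one Best, Average and Poor quality ewe per breed group per farm. Trait
#' means and SDs per breed and quality class follow the published
#' descriptive statistics, with breed-specific Isinya-minus-Amboseli
#' shifts taken from the breed-by-site least-squares means. Reason-profile
#' probabilities are proportional to the published weighted contribution
#' table; the Average class (not analysed in the source tables) uses the
#' mean of the Best and Poor profiles.
#'
#' @param n_rep Replicate the farm layout this many times (fresh farmer
#'   ids) to scale the dataset for large-sample checks.
#' @param farmer_sd_frac Fraction of a trait's typical stratum SD assigned
#'   to the between-farmer effect (default 0.4); the residual SD is scaled
#'   so the total stratum SD is preserved.
#' @param reason_mode How ordered reasons are drawn per ewe:
#'   `"pooled"` (default) draws the three ordered reasons independently
#'   from the stratum's pooled contribution profile, so the expected
#'   weighted shares equal the design WR exactly; `"by_order"` draws each
#'   order from its own count profile; `"sequential"` samples without
#'   replacement from the pooled profile (order-biased, for comparison).
#' @param rank_noise_sd SD of the latent preference noise in the
#'   across-breed ranking.
#' @param quality_pref_weight How strongly the quality class drives the
#'   across-breed ranking latent score.
#' @param breed_pref Tibble `site`, `breed`, `shift`: latent preference
#'   shift per breed and site (lower = preferred); the default prefers
#'   Dorper in Isinya and is near-neutral in Amboseli.
#' @return A `flock_design` list.
#' @export
flock_design <- function(n_rep = 1,
                         farmer_sd_frac = 0.4,
                         reason_mode = c("pooled", "by_order",
                                         "sequential"),
                         rank_noise_sd = 0.8,
                         quality_pref_weight = 0.8,
                         breed_pref = NULL) {
  reason_mode <- match.arg(reason_mode)
  if (n_rep < 1) abort("n_rep must be at least 1")
  all3 <- c("RedMaasai", "Dorper", "Cross")
  farm_types <- c(rep("all3", 6), rep("rm_cross", 3), "dorper_cross",
                  rep("all3", 5), rep("rm_cross", 3), "dorper_cross")
  farms <- tibble::tibble(
    site = c(rep("Amboseli", 10), rep("Isinya", 9)),
    type = farm_types
  )
  farms <- farms[rep(seq_len(nrow(farms)), n_rep), ]
  farms$farmer_id <- sprintf("F%03d", seq_len(nrow(farms)))
  farms$breeds <- lapply(farms$type, function(t) {
    switch(t, all3 = all3, rm_cross = c("RedMaasai", "Cross"),
           dorper_cross = c("Dorper", "Cross"))
  })
  farms$type <- NULL

  trait_params <- default_trait_params()
  site_deltas <- default_site_deltas()
  if (is.null(breed_pref)) {
    breed_pref <- tibble::tribble(
      ~site, ~breed, ~shift,
      "Amboseli", "RedMaasai", 0.0,
      "Amboseli", "Dorper", 0.0,
      "Amboseli", "Cross", 0.3,
      "Isinya", "RedMaasai", 0.6,
      "Isinya", "Dorper", -0.6,
      "Isinya", "Cross", 0.0
    )
  }
  structure(list(
    farms = farms,
    trait_params = trait_params,
    site_deltas = site_deltas,
    farmer_sd_frac = farmer_sd_frac,
    reason_profiles = build_reason_profiles(),
    reason_mode = reason_mode,
    breed_pref = breed_pref,
    rank_noise_sd = rank_noise_sd,
    quality_pref_weight = quality_pref_weight,
    age_weights = c(0.12, 0.22, 0.22, 0.16, 0.11, 0.07, 0.05, 0.03, 0.02),
    weights = weight_scheme()
  ), class = "flock_design")
}

default_trait_params <- function() {
  tp <- tibble::tribble(
    ~trait, ~breed, ~quality, ~mean, ~sd,
    "body_weight", "RedMaasai", "Best", 41.6, 5.3,
    "body_weight", "RedMaasai", "Average", 38.5, 4.3,
    "body_weight", "RedMaasai", "Poor", 32.4, 4.5,
    "body_weight", "Dorper", "Best", 46.7, 9.2,
    "body_weight", "Dorper", "Average", 44.8, 7.3,
    "body_weight", "Dorper", "Poor", 37.0, 3.9,
    "body_weight", "Cross", "Best", 43.3, 7.8,
    "body_weight", "Cross", "Average", 39.2, 5.5,
    "body_weight", "Cross", "Poor", 34.1, 3.9,
    "body_length", "RedMaasai", "Best", 62.9, 7.3,
    "body_length", "RedMaasai", "Average", 61.4, 6.4,
    "body_length", "RedMaasai", "Poor", 57.6, 4.6,
    "body_length", "Dorper", "Best", 64.0, 8.0,
    "body_length", "Dorper", "Average", 64.8, 6.4,
    "body_length", "Dorper", "Poor", 58.8, 4.1,
    "body_length", "Cross", "Best", 62.1, 6.8,
    "body_length", "Cross", "Average", 62.1, 5.8,
    "body_length", "Cross", "Poor", 58.5, 8.6,
    "heart_girth", "RedMaasai", "Best", 79.2, 7.3,
    "heart_girth", "RedMaasai", "Average", 76.9, 7.2,
    "heart_girth", "RedMaasai", "Poor", 72.9, 4.7,
    "heart_girth", "Dorper", "Best", 82.2, 6.4,
    "heart_girth", "Dorper", "Average", 81.7, 4.8,
    "heart_girth", "Dorper", "Poor", 76.2, 3.7,
    "heart_girth", "Cross", "Best", 80.8, 6.0,
    "heart_girth", "Cross", "Average", 76.8, 6.6,
    "heart_girth", "Cross", "Poor", 74.3, 4.1,
    "bcs", "RedMaasai", "Best", 3.03, 0.6,
    "bcs", "RedMaasai", "Average", 2.47, 0.7,
    "bcs", "RedMaasai", "Poor", 1.82, 0.5,
    "bcs", "Dorper", "Best", 2.85, 0.7,
    "bcs", "Dorper", "Average", 3.04, 0.8,
    "bcs", "Dorper", "Poor", 2.08, 0.8,
    "bcs", "Cross", "Best", 2.82, 0.5,
    "bcs", "Cross", "Average", 2.63, 0.7,
    "bcs", "Cross", "Poor", 2.00, 0.6,
    "milk_yield", "RedMaasai", "Best", 0.43, 0.25,
    "milk_yield", "RedMaasai", "Average", 0.29, 0.17,
    "milk_yield", "RedMaasai", "Poor", 0.16, 0.15,
    "milk_yield", "Dorper", "Best", 0.72, 0.37,
    "milk_yield", "Dorper", "Average", 0.45, 0.26,
    "milk_yield", "Dorper", "Poor", 0.21, 0.14,
    "milk_yield", "Cross", "Best", 0.53, 0.21,
    "milk_yield", "Cross", "Average", 0.35, 0.17,
    "milk_yield", "Cross", "Poor", 0.30, 0.19,
    "price", "RedMaasai", "Best", 5147, 1344,
    "price", "RedMaasai", "Average", 4341, 1229,
    "price", "RedMaasai", "Poor", 2988, 718,
    "price", "Dorper", "Best", 8462, 4235,
    "price", "Dorper", "Average", 7000, 4439,
    "price", "Dorper", "Poor", 4462, 1785,
    "price", "Cross", "Best", 5858, 2353,
    "price", "Cross", "Average", 4532, 1668,
    "price", "Cross", "Poor", 3405, 1166
  )
  tp
}

default_site_deltas <- function() {
  tibble::tribble(
    ~trait, ~breed, ~delta, # Isinya minus Amboseli
    "body_weight", "RedMaasai", 1.6,
    "body_weight", "Dorper", 5.9,
    "body_weight", "Cross", 6.7,
    "body_length", "RedMaasai", 3.9,
    "body_length", "Dorper", 3.0,
    "body_length", "Cross", 6.7,
    "heart_girth", "RedMaasai", -1.5,
    "heart_girth", "Dorper", 0.3,
    "heart_girth", "Cross", 3.6,
    "bcs", "RedMaasai", -0.6,
    "bcs", "Dorper", -0.9,
    "bcs", "Cross", -0.2,
    "milk_yield", "RedMaasai", -0.2,
    "milk_yield", "Dorper", -0.2,
    "milk_yield", "Cross", 0.0,
    "price", "RedMaasai", 820,
    "price", "Dorper", 4370,
    "price", "Cross", 2450
  )
}

build_reason_profiles <- function(contrib = study_contributions(),
                                  weights = weight_scheme()) {
  groups <- trait_groups()
  key <- function(site, breed, quality) paste(site, breed, quality,
                                              sep = "|")
  profiles <- list()
  strata <- dplyr::distinct(contrib[, c("site", "breed", "quality")])
  for (r in seq_len(nrow(strata))) {
    s <- strata[r, ]
    sub <- dplyr::inner_join(contrib, s, by = c("site", "breed", "quality"))
    sub <- sub[match(groups, sub$trait_group), ]
    sums <- rowSums(sub[, c("c1", "c2", "c3")])
    pooled <- setNames(sums / sum(sums), groups)
    by_order <- lapply(1:3, function(j) {
      x <- sub[[paste0("c", j)]] / weights[[as.character(j)]]
      if (sum(x) == 0) pooled else setNames(x / sum(x), groups)
    })
    profiles[[key(s$site, s$breed, s$quality)]] <-
      list(pooled = pooled, by_order = by_order)
  }
  # Average quality class: mean of Best and Poor profiles
  for (s in unique(strata$site)) {
    for (b in unique(strata$breed)) {
      best <- profiles[[key(s, b, "Best")]]
      poor <- profiles[[key(s, b, "Poor")]]
      avg_pooled <- (best$pooled + poor$pooled) / 2
      profiles[[key(s, b, "Average")]] <- list(
        pooled = avg_pooled / sum(avg_pooled),
        by_order = lapply(1:3, function(j) {
          p <- (best$by_order[[j]] + poor$by_order[[j]]) / 2
          p / sum(p)
        })
      )
    }
  }
  profiles
}

phrase_bank <- function() {
  list(
    positive = list(
      BodySizeAndGrowth = c("big body", "fast growth", "heavy"),
      Condition = c("good condition", "fat cover"),
      MilkProduction = c("much milk", "good milk"),
      ReproductionAndMotheringAbility = c("twinning", "good mother",
                                          "lamb survival"),
      DroughtTolerance = c("survives drought", "needs little water"),
      DiseaseResistance = c("never sick", "resistant to disease"),
      BreedAttributes = c("good colour", "strong legs", "long fat tail")
    ),
    negative = list(
      BodySizeAndGrowth = c("small body", "slow growth"),
      Condition = c("thin", "poor condition"),
      MilkProduction = c("little milk", "low milk"),
      ReproductionAndMotheringAbility = c("poor mother", "loses lambs"),
      DroughtTolerance = c("suffers in drought"),
      DiseaseResistance = c("often sick", "gets worms"),
      BreedAttributes = c("bad colour", "weak legs")
    )
  )
}

#' Generate a synthetic flock survey
#'
#' Draws a complete synthetic dataset from a [flock_design()]: ewe records
#' with traits from per-stratum normal distributions (plus a shared
#' farmer effect), BCS snapped to the half-point grid and clipped to
#' \[1, 5\], milk truncated at zero, price a positive whole number; ages
#' 1-9 from the design's age distribution; across-breed ranks from a
#' latent preference score combining breed-by-site preference, quality
#' class, and noise; and three ordered reasons per ewe from the stratum's
#' reason profile. Every latent draw is recorded in the generation ledger
#' so recovery tests can compare against the truth. The output is fully
#' reproducible given `seed`.
#'
#' @param design A [flock_design()].
#' @param seed Integer seed; if `NULL`, the current RNG state is used.
#' @return A `flock_survey` list: `ewes`, `reasons` (mapped trait groups
#'   included), `ledger`, `design`, `seed`.
#' @export
generate_flocks <- function(design = flock_design(), seed = NULL) {
  if (!inherits(design, "flock_design")) abort("design must be a flock_design")
  if (nrow(design$farms) == 0) abort("infeasible design: no farms")
  if (!is.null(seed)) withr::local_seed(seed)

  qualities <- c("Best", "Average", "Poor")
  ewes <- purrr::pmap(design$farms[, c("farmer_id", "site", "breeds")],
                      function(farmer_id, site, breeds) {
                        tidyr::expand_grid(farmer_id = farmer_id,
                                           site = site, breed = breeds,
                                           quality = qualities)
                      }) |>
    dplyr::bind_rows()
  n <- nrow(ewes)
  ewes$ewe_id <- sprintf("E%04d", seq_len(n))

  traits <- unique(design$trait_params$trait)
  trait_scale <- design$trait_params |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(scale = mean(.data$sd), .groups = "drop")
  f_sd <- design$farmer_sd_frac
  farmer_effects <- tidyr::expand_grid(
    farmer_id = design$farms$farmer_id, trait = traits
  ) |>
    dplyr::left_join(trait_scale, by = "trait") |>
    dplyr::mutate(effect = rnorm(dplyr::n(), 0, f_sd * .data$scale))

  dat <- tidyr::expand_grid(ewes, trait = traits) |>
    dplyr::left_join(design$trait_params,
                     by = c("breed", "quality", "trait")) |>
    dplyr::left_join(design$site_deltas, by = c("trait", "breed")) |>
    dplyr::left_join(farmer_effects[, c("farmer_id", "trait", "effect")],
                     by = c("farmer_id", "trait")) |>
    dplyr::mutate(
      stratum_mean = .data$mean +
        ifelse(.data$site == "Isinya", 0.5, -0.5) * .data$delta,
      value = .data$stratum_mean + .data$effect +
        rnorm(dplyr::n(), 0, sqrt(1 - f_sd^2) * .data$sd)
    )
  latent_means <- dat[, c("ewe_id", "trait", "stratum_mean", "effect")]
  wide <- dat |>
    dplyr::select("ewe_id", "trait", "value") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  ewes <- dplyr::left_join(ewes, wide, by = "ewe_id") |>
    dplyr::mutate(
      body_weight = pmax(round(.data$body_weight, 1), 5),
      body_length = pmax(round(.data$body_length, 1), 20),
      heart_girth = pmax(round(.data$heart_girth, 1), 30),
      bcs = pmin(pmax(round(.data$bcs * 2) / 2, 1), 5),
      milk_yield = pmax(round(.data$milk_yield, 2), 0),
      price = pmax(round(.data$price), 500),
      age = sample(1:9, dplyr::n(), replace = TRUE,
                   prob = design$age_weights)
    )
  ewes$coat_colour <- vapply(ewes$breed, function(b) {
    switch(b,
      RedMaasai = sample(c("red", "brown", "red-brown"), 1),
      Dorper = sample(c("white", "white-blackhead"), 1),
      sample(c("mixed", "white-red", "spotted"), 1)
    )
  }, character(1))

  # across-breed ranking: latent preference, lower = preferred
  ewes <- ewes |>
    dplyr::left_join(design$breed_pref, by = c("site", "breed")) |>
    dplyr::mutate(
      qscore = c(Best = 1, Average = 0, Poor = -1)[.data$quality],
      latent_pref = .data$shift -
        design$quality_pref_weight * .data$qscore +
        rnorm(dplyr::n(), 0, design$rank_noise_sd)
    ) |>
    dplyr::group_by(.data$farmer_id) |>
    dplyr::mutate(across_breed_rank = rank(.data$latent_pref,
                                           ties.method = "first")) |>
    dplyr::ungroup()
  latent_pref <- ewes[, c("ewe_id", "latent_pref")]
  ewes <- ewes |>
    dplyr::select(dplyr::all_of(c(ewe_mandatory_cols(),
                                  ewe_optional_cols())))

  reasons <- generate_reasons(ewes, design)

  ledger <- list(
    farmer_effects = farmer_effects[, c("farmer_id", "trait", "effect")],
    latent_means = latent_means,
    latent_pref = latent_pref,
    reason_draws = reasons[, c("ewe_id", "order", "trait_group")],
    seed = seed
  )
  structure(list(ewes = ewes, reasons = reasons, ledger = ledger,
                 design = design, seed = seed),
            class = "flock_survey")
}

#' Generate ordered reasons for ewes from a design's reason profiles
#'
#' Draws up to three ordered reasons per ewe from the reason profile of
#' its site-breed-quality stratum (see [flock_design()] for the available
#' drawing modes) and phrases each drawn trait group with a vocabulary the
#' bundled lexicon maps back to it — positive wording for Best and
#' Average ewes, negative for Poor ones. Categories with zero profile
#' probability are never emitted; a stratum with an all-zero profile
#' yields no reasons, with a warning.
#'
#' @param ewes Tibble with `ewe_id`, `site`, `breed`, `quality`.
#' @param design A [flock_design()].
#' @param mode Override of the design's `reason_mode`.
#' @return Tibble of reason records (`ewe_id`, `order`, `phrase`,
#'   `trait_group`).
#' @export
generate_reasons <- function(ewes, design, mode = design$reason_mode) {
  groups <- trait_groups()
  bank <- phrase_bank()
  key <- paste(ewes$site, ewes$breed, ewes$quality, sep = "|")
  res <- list()
  for (k in unique(key)) {
    prof <- design$reason_profiles[[k]]
    if (is.null(prof)) {
      abort(paste0("no reason profile for stratum ", k))
    }
    idx <- which(key == k)
    m <- length(idx)
    if (sum(prof$pooled) == 0) {
      warn(paste0("degenerate (all-zero) reason profile for ", k,
                  ": no reasons emitted"))
      next
    }
    draws <- switch(mode,
      pooled = matrix(sample(groups, 3 * m, replace = TRUE,
                             prob = prof$pooled), nrow = m),
      by_order = vapply(1:3, function(j) {
        sample(groups, m, replace = TRUE, prob = prof$by_order[[j]])
      }, character(m)),
      sequential = t(vapply(seq_len(m), function(i) {
        sample(groups, 3, replace = FALSE, prob = prof$pooled)
      }, character(3)))
    )
    draws <- matrix(draws, nrow = m)
    res[[k]] <- tibble::tibble(
      ewe_id = rep(ewes$ewe_id[idx], each = 3),
      order = rep(1:3, m),
      trait_group = as.character(t(draws)),
      quality = rep(ewes$quality[idx], each = 3)
    )
  }
  if (length(res) == 0) {
    return(tibble::tibble(ewe_id = character(), order = integer(),
                          phrase = character(),
                          trait_group = character()))
  }
  reasons <- dplyr::bind_rows(res)
  sentiment <- ifelse(reasons$quality == "Poor", "negative", "positive")
  reasons$phrase <- vapply(seq_len(nrow(reasons)), function(i) {
    options <- bank[[sentiment[i]]][[reasons$trait_group[i]]]
    options[sample.int(length(options), 1)]
  }, character(1))
  reasons$quality <- NULL
  reasons <- reasons[order(match(reasons$ewe_id, ewes$ewe_id),
                           reasons$order), ]
  reasons[, c("ewe_id", "order", "phrase", "trait_group")]
}

#' @export
print.flock_survey <- function(x, ...) {
  cat("Synthetic flock survey:", nrow(x$ewes), "ewes on",
      nrow(x$design$farms), "farms;", nrow(x$reasons), "reasons\n")
  invisible(x)
}

#' @export
print.flock_design <- function(x, ...) {
  cat("Flock design:", nrow(x$farms), "farms,",
      sum(3 * lengths(x$farms$breeds)), "ewes; reason mode:",
      x$reason_mode, "\n")
  invisible(x)
}
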
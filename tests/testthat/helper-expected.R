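# Published weighted-reasons values, frozen from the printed tables.
# Trait-group order per stratum: BodySizeAndGrowth, Condition,
# MilkProduction, ReproductionAndMotheringAbility, DroughtTolerance,
# DiseaseResistance, BreedAttributes. Stratum order matches the bundled
# contribution fixture.

study_wr_printed <- function() {
  strata <- expand.grid(
    trait_group = trait_groups(),
    stratum = 1:12, stringsAsFactors = FALSE
  )
  meta <- data.frame(
    stratum = 1:12,
    quality = rep(c("Best", "Poor"), each = 6),
    site = rep(c("Amboseli", "Isinya"), 6),
    breed = rep(rep(c("RedMaasai", "Dorper", "Cross"), each = 2), 2)
  )
  wr <- c(
    0.27, 0.15, 0.17, 0.27, 0.13, 0.00, 0.02, # Best Amboseli RedMaasai
    0.35, 0.00, 0.17, 0.09, 0.17, 0.18, 0.05, # Best Isinya RedMaasai
    0.53, 0.14, 0.14, 0.06, 0.00, 0.00, 0.14, # Best Amboseli Dorper
    0.71, 0.00, 0.14, 0.12, 0.00, 0.00, 0.02, # Best Isinya Dorper
    0.30, 0.12, 0.20, 0.17, 0.10, 0.00, 0.12, # Best Amboseli Cross
    0.58, 0.00, 0.21, 0.13, 0.06, 0.02, 0.00, # Best Isinya Cross
    0.15, 0.33, 0.23, 0.18, 0.00, 0.08, 0.05, # Poor Amboseli RedMaasai
    0.36, 0.07, 0.36, 0.00, 0.04, 0.13, 0.04, # Poor Isinya RedMaasai
    0.09, 0.06, 0.25, 0.31, 0.00, 0.28, 0.00, # Poor Amboseli Dorper
    0.07, 0.00, 0.52, 0.19, 0.04, 0.19, 0.00, # Poor Isinya Dorper
    0.12, 0.17, 0.27, 0.17, 0.10, 0.17, 0.00, # Poor Amboseli Cross
    0.18, 0.00, 0.47, 0.11, 0.05, 0.18, 0.00  # Poor Isinya Cross
  )
  out <- merge(strata, meta, by = "stratum")
  out <- out[order(out$stratum, match(out$trait_group, trait_groups())), ]
  out$wr_printed <- wr
  tibble::as_tibble(out[, c("quality", "site", "breed", "trait_group",
                            "wr_printed")])
}

# Clustered four-category values for the pure breeds (the published
# condensed table covers Red Maasai and Dorper only).
study_cluster_printed <- function() {
  meta <- expand.grid(
    cluster = cluster_names(),
    site = c("Amboseli", "Isinya"),
    breed = c("RedMaasai", "Dorper"),
    quality = c("Best", "Poor"),
    stringsAsFactors = FALSE
  )
  vals <- list(
    Best_RedMaasai_Amboseli = c(0.28, 0.15, 0.45, 0.13),
    Best_RedMaasai_Isinya = c(0.37, 0.00, 0.27, 0.37),
    Best_Dorper_Amboseli = c(0.61, 0.16, 0.23, 0.00),
    Best_Dorper_Isinya = c(0.73, 0.00, 0.27, 0.00),
    Poor_RedMaasai_Amboseli = c(0.16, 0.34, 0.42, 0.08),
    Poor_RedMaasai_Isinya = c(0.37, 0.07, 0.37, 0.19),
    Poor_Dorper_Amboseli = c(0.09, 0.06, 0.56, 0.28),
    Poor_Dorper_Isinya = c(0.07, 0.00, 0.70, 0.22)
  )
  meta$wr_printed <- unlist(lapply(seq_len(nrow(meta)), function(i) {
    key <- paste(meta$quality[i], meta$breed[i], meta$site[i], sep = "_")
    vals[[key]][match(meta$cluster[i], cluster_names())]
  }))
  tibble::as_tibble(meta)
}

make_toy_ewes <- function(n_farmers = 4, seed = 101) {
  withr::local_seed(seed)
  sites <- rep(c("Amboseli", "Isinya"), length.out = n_farmers)
  rows <- list()
  id <- 0
  for (f in seq_len(n_farmers)) {
    for (b in c("RedMaasai", "Dorper", "Cross")) {
      for (q in c("Best", "Average", "Poor")) {
        id <- id + 1
        rows[[id]] <- tibble::tibble(
          ewe_id = sprintf("E%03d", id),
          farmer_id = sprintf("F%02d", f),
          site = sites[f], breed = b, quality = q,
          body_weight = round(stats::rnorm(1, 40, 5), 1),
          body_length = round(stats::rnorm(1, 60, 5), 1),
          heart_girth = round(stats::rnorm(1, 78, 5), 1),
          bcs = sample(seq(1, 5, 0.5), 1),
          milk_yield = round(stats::runif(1, 0, 1), 2),
          price = round(stats::rnorm(1, 5000, 800)),
          age = sample(1:9, 1),
          coat_colour = "red",
          across_breed_rank = NA_real_
        )
      }
    }
  }
  ewes <- dplyr::bind_rows(rows)
  ewes <- ewes |>
    dplyr::group_by(farmer_id) |>
    dplyr::mutate(across_breed_rank = sample(dplyr::n())) |>
    dplyr::ungroup()
  ewes
}
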
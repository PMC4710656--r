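test_that("the default design emits the study layout", {
  sim <- generate_flocks(flock_design(), seed = 1)
  expect_equal(nrow(sim$ewes), 147)
  expect_equal(sum(sim$ewes$breed == "RedMaasai"), 51)
  expect_equal(sum(sim$ewes$breed == "Dorper"), 39)
  expect_equal(sum(sim$ewes$breed == "Cross"), 57)
  farmers <- dplyr::distinct(sim$ewes[, c("farmer_id", "site")])
  expect_equal(sum(farmers$site == "Amboseli"), 10)
  expect_equal(sum(farmers$site == "Isinya"), 9)
  # generated records satisfy every survey invariant
  v <- validate_ewe_records(sim$ewes)
  expect_equal(nrow(quarantine_report(v)), 0)
  expect_error(generate_flocks(structure(list(farms = tibble::tibble()),
                                         class = "flock_design")),
               "no farms")
})

test_that("generation is byte-identical under a fixed seed", {
  d <- flock_design()
  s1 <- generate_flocks(d, seed = 5)
  s2 <- generate_flocks(d, seed = 5)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ewe_records(s1$ewes, p1)
  write_ewe_records(s2$ewes, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(s1$reasons, s2$reasons)
  s3 <- generate_flocks(d, seed = 6)
  expect_false(identical(s1$ewes$body_weight, s3$ewes$body_weight))
})

test_that("the ledger is a faithful oracle for the reason tally", {
  sim <- generate_flocks(flock_design(), seed = 9)
  counts <- tally_reason_counts(sim$reasons, sim$ewes)
  ledger <- dplyr::inner_join(
    sim$ledger$reason_draws,
    sim$ewes[, c("ewe_id", "site", "breed", "quality")],
    by = "ewe_id"
  ) |>
    dplyr::count(.data$site, .data$breed, .data$quality,
                 .data$trait_group, .data$order, name = "n_ledger")
  joined <- dplyr::left_join(
    counts, ledger,
    by = c("site", "breed", "quality", "trait_group", "order")
  )
  joined$n_ledger[is.na(joined$n_ledger)] <- 0
  expect_equal(joined$n, joined$n_ledger)
  # ledger is complete: every emitted record is traceable
  expect_setequal(sim$ledger$reason_draws$ewe_id, sim$ewes$ewe_id)
  expect_setequal(sim$ledger$latent_pref$ewe_id, sim$ewes$ewe_id)
})

test_that("reason draws honour the stratum profile support", {
  d <- flock_design()
  # concentrated profile: every reason lands on the single category
  d$reason_profiles[["Amboseli|Dorper|Best"]] <- list(
    pooled = setNames(c(1, rep(0, 6)), trait_groups()),
    by_order = rep(list(setNames(c(1, rep(0, 6)), trait_groups())), 3)
  )
  sim <- generate_flocks(d, seed = 3)
  conc <- dplyr::inner_join(
    sim$reasons,
    sim$ewes[sim$ewes$site == "Amboseli" & sim$ewes$breed == "Dorper" &
               sim$ewes$quality == "Best", "ewe_id"],
    by = "ewe_id"
  )
  expect_true(all(conc$trait_group == "BodySizeAndGrowth"))
  # zero-probability categories are never emitted anywhere
  zero_cats <- lapply(names(d$reason_profiles), function(k) {
    names(which(d$reason_profiles[[k]]$pooled == 0))
  })
  names(zero_cats) <- names(d$reason_profiles)
  key <- with(dplyr::inner_join(sim$reasons,
                                sim$ewes[, c("ewe_id", "site", "breed",
                                             "quality")],
                                by = "ewe_id"),
              paste(site, breed, quality, sep = "|"))
  joined <- dplyr::inner_join(
    sim$reasons, sim$ewes[, c("ewe_id", "site", "breed", "quality")],
    by = "ewe_id"
  )
  for (i in seq_len(nrow(joined))) {
    k <- paste(joined$site[i], joined$breed[i], joined$quality[i],
               sep = "|")
    expect_false(joined$trait_group[i] %in% zero_cats[[k]])
  }
})

test_that("an all-zero profile emits no reasons, with a warning", {
  d <- flock_design()
  zero <- setNames(rep(0, 7), trait_groups())
  d$reason_profiles[["Amboseli|Dorper|Best"]] <-
    list(pooled = zero, by_order = rep(list(zero), 3))
  expect_warning(sim <- generate_flocks(d, seed = 3), "degenerate")
  stratum_ewes <- sim$ewes$ewe_id[sim$ewes$site == "Amboseli" &
                                    sim$ewes$breed == "Dorper" &
                                    sim$ewes$quality == "Best"]
  expect_false(any(sim$reasons$ewe_id %in% stratum_ewes))
})

test_that("large samples concentrate on the design trait means", {
  # ~40 replicates of the layout = 5,880 ewes; empirical stratum means of
  # an unclipped trait must sit within 3 SE of the design means
  sim <- generate_flocks(flock_design(n_rep = 40), seed = 77)
  d <- flock_design()
  got <- sim$ewes |>
    dplyr::group_by(.data$site, .data$breed, .data$quality) |>
    dplyr::summarise(m = mean(.data$body_weight), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::left_join(
      d$trait_params[d$trait_params$trait == "body_weight", ],
      by = c("breed", "quality")
    ) |>
    dplyr::left_join(
      d$site_deltas[d$site_deltas$trait == "body_weight",
                    c("breed", "delta")],
      by = "breed"
    ) |>
    dplyr::mutate(
      want = .data$mean + ifelse(.data$site == "Isinya", 0.5, -0.5) *
        .data$delta,
      se = .data$sd / sqrt(.data$n)
    )
  expect_true(all(abs(got$m - got$want) < 3 * got$se + 0.06))
})

test_that("emitted phrases map back to the drawn trait groups", {
  sim <- generate_flocks(flock_design(), seed = 15)
  mapped <- map_reasons(sim$reasons[, c("ewe_id", "order", "phrase")])
  expect_equal(mapped$trait_group, sim$reasons$trait_group)
  expect_equal(nrow(unmapped_report(mapped)), 0)
})
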
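test_that("counts tally per stratum and sum to the number of reasons", {
  ewes <- make_toy_ewes(n_farmers = 2)
  reasons <- validate_reason_records(tibble::tibble(
    ewe_id = rep("E001", 3), order = 1:3, phrase = "big body"
  ), ewes)
  reasons <- map_reasons(reasons)
  counts <- tally_reason_counts(reasons, ewes)
  in_stratum <- counts[counts$trait_group == "BodySizeAndGrowth" &
                         counts$site == "Amboseli", ]
  expect_equal(sum(in_stratum$n), 3)
  expect_equal(sum(counts$n), nrow(reasons))
  # zero cells are explicit
  expect_true(all(trait_groups() %in% counts$trait_group))
  # unmapped reasons block the tally with a pointer to the report
  reasons$trait_group[1] <- NA
  expect_error(tally_reason_counts(reasons, ewes), "unmapped")
})

test_that("weighted contributions match an explicit loop on random counts", {
  withr::local_seed(5)
  for (rep in 1:20) {
    counts <- tidyr::expand_grid(
      stratum = "s1", trait_group = trait_groups(), order = 1:3
    )
    counts$n <- sample(0:9, nrow(counts), replace = TRUE)
    w <- weight_scheme()
    got <- weighted_contributions(counts, w)
    # brute-force loop oracle
    for (i in seq_len(nrow(counts))) {
      expect_identical(got$contribution[i],
                       w[[as.character(counts$order[i])]] * counts$n[i])
    }
    sums <- tapply(got$contribution, got$trait_group, sum)
    by_hand <- sapply(split(counts, counts$trait_group), function(d) {
      tot <- 0
      for (i in seq_len(nrow(d))) tot <- tot + d$n[i] * w[[d$order[i]]]
      tot
    })
    expect_equal(as.numeric(sums[names(by_hand)]), as.numeric(by_hand))
  }
  expect_error(weighted_contributions(
    tibble::tibble(trait_group = "Condition", order = 4, n = 1),
    weight_scheme()
  ), "absent from the weight scheme")
})

test_that("published contribution rows reproduce the printed arithmetic", {
  # Amboseli Dorper Best, body size: counts (2,2,3) -> contributions
  # (6,4,3), sum 13; sums {19,5,5,2,0,0,5} -> WR 19/36
  w <- weight_scheme()
  x <- c(2, 2, 3)
  expect_equal(unname(w[as.character(1:3)] * x), c(6, 4, 3))
  sums <- c(19, 5, 5, 2, 0, 0, 5)
  names(sums) <- trait_groups()
  wr <- compute_wr(sums)
  expect_equal(unname(wr["BodySizeAndGrowth"]), 19 / 36)
  expect_equal(round_half_up(wr[["BodySizeAndGrowth"]]), 0.53)
})

test_that("the WR index normalizes, is scale invariant, and flags zeros", {
  withr::local_seed(9)
  for (rep in 1:50) {
    sums <- stats::rpois(7, 4)
    names(sums) <- trait_groups()
    if (sum(sums) == 0) next
    wr <- compute_wr(sums)
    expect_equal(sum(wr), 1, tolerance = 1e-12)
    expect_true(all(wr >= 0 & wr <= 1))
    expect_equal(compute_wr(sums * 17), wr)
  }
  expect_equal(compute_wr(c(a = 5, b = 0)), c(a = 1, b = 0))
  expect_warning(out <- compute_wr(c(a = 0, b = 0)), "all-zero")
  expect_length(out, 0)
})

test_that("alternative weight schemes give valid normalized tables", {
  sim <- generate_flocks(flock_design(), seed = 21)
  for (w in list(c(1, 1, 1), c(5, 3, 1))) {
    pt <- preference_table(sim$reasons, sim$ewes,
                           weights = weight_scheme(w))
    tot <- tapply(pt$wr, paste(pt$site, pt$breed, pt$quality), sum)
    expect_true(all(abs(tot - 1) < 1e-12))
  }
})

test_that("clustering accumulates, excludes, and renormalizes", {
  p <- wr_from_contributions(study_contributions())
  cl <- cluster_wr(p)
  rm_best_a <- cl[cl$site == "Amboseli" & cl$breed == "RedMaasai" &
                    cl$quality == "Best", ]
  expect_equal(rm_best_a$wr[rm_best_a$cluster == "ReproductionAndMilk"],
               21 / 47)
  # all weight in one cluster -> 1.00
  one <- tibble::tibble(
    site = "Amboseli", breed = "Dorper", quality = "Best",
    trait_group = trait_groups(),
    c1 = c(3, 0, 0, 0, 0, 0, 0), c2 = 0, c3 = 0
  )
  clw <- cluster_wr(wr_from_contributions(one))
  expect_equal(clw$wr[clw$cluster == "BodySizeAndGrowth"], 1)
  # without renormalization the excluded group's mass stays in the total
  cl_raw <- cluster_wr(p, cluster_scheme(renormalize = FALSE))
  raw_rm <- cl_raw[cl_raw$site == "Amboseli" & cl_raw$breed == "RedMaasai" &
                     cl_raw$quality == "Best", ]
  expect_equal(raw_rm$wr[raw_rm$cluster == "ReproductionAndMilk"], 21 / 48)
})

test_that("report rendering rounds half up to two decimals", {
  expect_equal(round_half_up(6 / 48), 0.13)
  expect_equal(round_half_up(1 / 8), 0.13)  # half-up, not banker's
  expect_equal(round_half_up(0), 0)
  p <- wr_from_contributions(study_contributions())
  rep_tbl <- render_preference_report(p)
  drought <- rep_tbl[rep_tbl$site == "Amboseli" &
                       rep_tbl$breed == "RedMaasai" &
                       rep_tbl$quality == "Best" &
                       rep_tbl$trait_group == "DroughtTolerance", ]
  expect_equal(drought$wr, "0.13")
  expect_equal(render_preference_report(
    wr_from_contributions(tibble::tibble(
      site = "x", breed = "y", quality = "z",
      trait_group = c("a", "b"), c1 = c(0, 5), c2 = 0, c3 = 0
    ))
  )$wr, c("0.00", "1.00"))
})

test_that("raw-count recovery requires exact divisibility", {
  contrib <- study_contributions()
  counts <- contributions_to_counts(contrib)
  expect_true(all(counts$x1 == contrib$c1 / 3))
  expect_true(all(counts$x2 == contrib$c2 / 2))
  bad <- contrib
  bad$c1[1] <- 7
  expect_error(contributions_to_counts(bad), "not divisible")
})
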
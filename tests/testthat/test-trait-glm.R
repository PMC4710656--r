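test_that("design encoding has the arithmetic column count and nests farmers", {
  # 2 sites x 2 farmers/site x 2 breeds x 3 quality classes, 1 obs/cell
  grid <- tidyr::expand_grid(
    site = c("Amboseli", "Isinya"), fws = c("a", "b"),
    breed = c("RedMaasai", "Dorper"),
    quality = c("Best", "Average", "Poor")
  )
  grid$farmer_id <- paste0(grid$site, grid$fws)
  grid$y <- stats::rnorm(nrow(grid))
  des <- build_design(grid, "y")
  # 1 + (2-1) + 2*(2-1) + (2-1) + (3-1) + (2-1)*(2-1)
  expect_equal(ncol(des$X), 8)
  # farmer columns are sum-to-zero within their own site only
  fcols <- des$X[, des$terms$farmer, drop = FALSE]
  for (s in c("Amboseli", "Isinya")) {
    expect_true(all(colSums(fcols[grid$site == s, , drop = FALSE]) %in%
                      c(0)))
  }
  # deterministic encoding: identical input gives an identical matrix
  expect_identical(des$X, build_design(grid, "y")$X)
})

test_that("degenerate designs collapse gracefully", {
  skel <- model_skeleton()
  one_site <- skel[skel$site == "Amboseli", ]
  one_site$y <- stats::rnorm(nrow(one_site), 40, 4)
  expect_warning(fit <- fit_trait_model(one_site, "y"),
                 "single-level factor dropped: site")
  expect_false("site" %in% names(fit$design$terms))
  expect_false("breed_site" %in% names(fit$design$terms))

  # intercept-only model recovers the sample mean
  flat <- tibble::tibble(
    ewe_id = paste0("e", 1:10), farmer_id = "F1", site = "Amboseli",
    breed = "RedMaasai", quality = "Best",
    y = stats::rnorm(10, 40, 4)
  )
  fit0 <- suppressWarnings(fit_trait_model(flat, "y"))
  expect_equal(unname(fit0$coefficients), mean(flat$y))

  # one-factor model reproduces group means
  onef <- tibble::tibble(
    ewe_id = paste0("e", 1:30), farmer_id = "F1", site = "Amboseli",
    breed = rep(c("RedMaasai", "Dorper", "Cross"), each = 10),
    quality = "Best", y = stats::rnorm(30, 40, 4)
  )
  fit1 <- suppressWarnings(fit_trait_model(onef, "y"))
  lsm <- ls_means(fit1, "breed")
  raw <- tapply(onef$y, onef$breed, mean)
  expect_equal(lsm$estimate, as.numeric(raw[lsm$breed]))
})

test_that("coefficients, F tests and LS-means match the brute-force oracle", {
  withr::local_seed(17)
  for (rep in 1:10) {
    df <- random_instance()
    fit <- fit_trait_model(df, "y")
    om <- oracle_model(df)
    of <- oracle_fit(om, df$y)
    expect_equal(unname(fit$coefficients), unname(of$beta),
                 tolerance = 1e-8)
    expect_equal(fit$rss, of$rss, tolerance = 1e-8)
    a <- anova_table(fit)
    oa <- oracle_type2(om, df$y)
    expect_equal(a$statistic[match(oa$term, a$term)], oa$statistic,
                 tolerance = 1e-8)
    lsm <- ls_means(fit, "breed_site")
    ol <- oracle_lsmeans_breed_site(om, df$y)
    key <- paste(lsm$site, lsm$breed)
    okey <- paste(ol$site, ol$breed)
    expect_equal(lsm$estimate, ol$estimate[match(key, okey)],
                 tolerance = 1e-8)
    expect_equal(lsm$se, ol$se[match(key, okey)], tolerance = 1e-8)
  }
})

test_that("type II matches car::Anova where a plain formula expresses the model", {
  skip_if_not_installed("car")
  withr::local_seed(23)
  # one farmer per site, so the model is site + breed + quality + site:breed
  df <- tidyr::expand_grid(
    site = c("Amboseli", "Isinya"),
    breed = c("RedMaasai", "Dorper", "Cross"),
    quality = c("Best", "Average", "Poor"),
    repn = 1:3
  )
  df$farmer_id <- ifelse(df$site == "Amboseli", "F1", "F2")
  df <- df[-c(1, 5, 20), ] # unbalance it so type I and II differ
  df$y <- stats::rnorm(nrow(df), 40, 4)
  fit <- fit_trait_model(df, "y")
  mine <- anova_table(fit, type = "II")
  lmfit <- stats::lm(y ~ site + breed + quality + site:breed, data = df)
  theirs <- car::Anova(lmfit, type = "II")
  map <- c(site = "site", breed = "breed", quality = "quality",
           breed_site = "site:breed")
  for (tm in names(map)) {
    expect_equal(mine$statistic[mine$term == tm],
                 theirs[map[[tm]], "F value"], tolerance = 1e-8)
  }
})

test_that("LS-means agree with emmeans on an unbalanced no-nesting design", {
  skip_if_not_installed("emmeans")
  withr::local_seed(29)
  df <- tidyr::expand_grid(
    site = c("Amboseli", "Isinya"),
    breed = c("RedMaasai", "Dorper", "Cross"),
    quality = c("Best", "Average", "Poor"),
    repn = 1:2
  )
  df$farmer_id <- ifelse(df$site == "Amboseli", "F1", "F2")
  df <- df[-c(2, 3, 11), ]
  df$y <- stats::rnorm(nrow(df), 40, 4)
  fit <- fit_trait_model(df, "y")
  lsm <- ls_means(fit, "breed_site")
  lmfit <- stats::lm(y ~ site + breed + quality + site:breed, data = df)
  em <- as.data.frame(emmeans::emmeans(lmfit, ~ breed * site))
  key <- paste(lsm$site, lsm$breed)
  ekey <- paste(em$site, em$breed)
  expect_equal(lsm$estimate, em$emmean[match(key, ekey)],
               tolerance = 1e-8)
  expect_equal(lsm$se, em$SE[match(key, ekey)], tolerance = 1e-8)
})

test_that("balanced designs: LS-means equal cell means; type I equals II", {
  withr::local_seed(31)
  grid <- tidyr::expand_grid(
    site = c("Amboseli", "Isinya"), fws = c("a", "b"),
    breed = c("RedMaasai", "Dorper"),
    quality = c("Best", "Average", "Poor"), repn = 1:2
  )
  grid$farmer_id <- paste0(grid$site, grid$fws)
  grid$y <- stats::rnorm(nrow(grid), 40, 4)
  fit <- fit_trait_model(grid, "y")
  lsm <- ls_means(fit, "breed_site")
  raw <- aggregate(y ~ site + breed, grid, mean)
  key <- paste(lsm$site, lsm$breed)
  rkey <- paste(raw$site, raw$breed)
  expect_equal(lsm$estimate, raw$y[match(key, rkey)], tolerance = 1e-10)
  a1 <- anova_table(fit, type = "I")
  a2 <- anova_table(fit, type = "II")
  expect_equal(a1$sum_sq, a2$sum_sq[match(a1$term, a2$term)],
               tolerance = 1e-8)
})

test_that("duplicating a record moves the LS-mean off the raw mean", {
  withr::local_seed(37)
  toy <- tidyr::expand_grid(
    site = c("Amboseli", "Isinya"),
    breed = c("RedMaasai", "Dorper"),
    quality = c("Best", "Average", "Poor")
  )
  toy$farmer_id <- ifelse(toy$site == "Amboseli", "F1", "F2")
  toy$y <- stats::rnorm(nrow(toy), 40, 5)
  toy <- rbind(toy, toy[1, ]) # 13 records, unbalanced in one cell
  fit <- fit_trait_model(toy, "y")
  lsm <- ls_means(fit, "breed_site")
  cell <- lsm[lsm$site == toy$site[1] & lsm$breed == toy$breed[1], ]
  raw_mean <- mean(toy$y[toy$site == toy$site[1] &
                           toy$breed == toy$breed[1]])
  expect_gt(abs(cell$estimate - raw_mean), 1e-6)
  ol <- oracle_lsmeans_breed_site(oracle_model(toy), toy$y)
  expect_equal(cell$estimate,
               ol$estimate[ol$site == toy$site[1] &
                             ol$breed == toy$breed[1]],
               tolerance = 1e-10)
})

test_that("shifting the response shifts LS-means and leaves F untouched", {
  skel <- model_skeleton()
  eff <- default_effects(unique(skel$farmer_id))
  withr::local_seed(41)
  skel$y <- sim_response(skel, eff)
  skel2 <- skel
  skel2$y <- skel$y + 100
  f1 <- fit_trait_model(skel, "y")
  f2 <- fit_trait_model(skel2, "y")
  expect_equal(ls_means(f2, "breed_site")$estimate,
               ls_means(f1, "breed_site")$estimate + 100,
               tolerance = 1e-8)
  expect_equal(anova_table(f2)$statistic, anova_table(f1)$statistic,
               tolerance = 1e-8)
})

test_that("a real breed-by-site interaction is detected with high power", {
  skel <- model_skeleton()
  eff <- default_effects(unique(skel$farmer_id))
  # an 8 kg breed-by-site gap at the survey's n has ~95% nominal power
  # for the 2-df interaction test; demand at least 80% empirically
  eff$breed_site <- c("Dorper.Isinya" = 8, "Cross.Isinya" = 2)
  withr::local_seed(43)
  hits <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    skel$y <- sim_response(skel, eff)
    a <- anova_table(fit_trait_model(skel, "y"))
    hits <- hits + (a$p_value[a$term == "breed_site"] < 0.05)
  }
  expect_gt(hits / n_rep, 0.8)
})

test_that("term screening keeps real effects and passes null ones", {
  skel <- model_skeleton()
  eff <- default_effects(unique(skel$farmer_id))
  # no candidates: base spec unchanged
  empty <- screen_terms(skel, "y", candidates = character())
  expect_equal(empty$extra_terms, character())

  withr::local_seed(47)
  # strong quality-by-site effect is retained
  hits_qs <- 0
  hits_age_null <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    y0 <- sim_response(skel, eff)
    qs <- ifelse(skel$site == "Isinya" & skel$quality == "Poor", -6, 0)
    skel$y <- y0 + qs
    scr <- screen_terms(skel, "y", candidates = "quality_site")
    hits_qs <- hits_qs + ("quality_site" %in% scr$retained)
    skel$y <- y0 # age never entered the truth
    scr2 <- screen_terms(skel, "y", candidates = "age")
    hits_age_null <- hits_age_null + ("age" %in% scr2$retained)
  }
  expect_gt(hits_qs / n_rep, 0.9)
  expect_lt(hits_age_null / n_rep, 0.25) # null retention is rare
})

test_that("tidy and glance expose the fit in broom shape", {
  skel <- model_skeleton()
  eff <- default_effects(unique(skel$farmer_id))
  withr::local_seed(53)
  skel$y <- sim_response(skel, eff)
  fit <- fit_trait_model(skel, "y")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "p_value") %in%
                    names(td)))
  expect_equal(nrow(td), ncol(fit$design$X))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(skel))
  expect_true(gl$r_squared > 0 && gl$r_squared < 1)
  expect_true(is.finite(gl$skewness) && is.finite(gl$shapiro_p))
})
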
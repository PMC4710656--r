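# Simulation scaffolding for the trait model: a fixed study-like factor
# layout plus a response drawn from the exact model equation with known
# effects.

model_skeleton <- function() {
  sim <- generate_flocks(flock_design(), seed = 2024)
  sim$ewes[, c("ewe_id", "farmer_id", "site", "breed", "quality", "age")]
}

default_effects <- function(farmer_ids, farmer_sd = 2, seed = 99) {
  withr::local_seed(seed)
  list(
    mu = 40,
    site = c(Amboseli = 0, Isinya = 2),
    farmer = stats::setNames(stats::rnorm(length(farmer_ids), 0, farmer_sd),
                             farmer_ids),
    breed = c(RedMaasai = 0, Dorper = 4, Cross = 2),
    quality = c(Best = 0, Average = -3, Poor = -8),
    breed_site = c("Dorper.Isinya" = 3, "Cross.Isinya" = 1.5),
    sigma = 4.5
  )
}

sim_response <- function(skel, eff) {
  bs <- paste(skel$breed, skel$site, sep = ".")
  bs_eff <- ifelse(bs %in% names(eff$breed_site), eff$breed_site[bs], 0)
  eff$mu + eff$site[skel$site] + eff$farmer[skel$farmer_id] +
    eff$breed[skel$breed] + eff$quality[skel$quality] + bs_eff +
    stats::rnorm(nrow(skel), 0, eff$sigma)
}

# true LS-mean difference Dorper minus Red Maasai within Isinya: breed
# effect difference plus interaction difference (farmer and quality
# averages cancel within the site)
true_isinya_gap <- function(eff) {
  unname(eff$breed["Dorper"] - eff$breed["RedMaasai"] +
           eff$breed_site["Dorper.Isinya"])
}

lsmean_diff_ci <- function(fit, level = 0.95) {
  lsm <- ls_means(fit, "breed_site")
  V <- attr(lsm, "vcov")
  i <- which(lsm$site == "Isinya" & lsm$breed == "Dorper")
  j <- which(lsm$site == "Isinya" & lsm$breed == "RedMaasai")
  d <- lsm$estimate[i] - lsm$estimate[j]
  se <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
  tq <- stats::qt(1 - (1 - level) / 2, lsm$df[1])
  c(lower = d - tq * se, upper = d + tq * se, estimate = d)
}
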
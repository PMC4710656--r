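# Independent brute-force least-squares oracle: explicit dummy-building
# loops and normal equations (solve(crossprod)), no code shared with the
# package's qr-based fitting path.

oracle_levels <- function(x, std) {
  u <- unique(as.character(x))
  if (all(u %in% std)) std[std %in% u] else sort(u)
}

oracle_model <- function(df, include_interaction = TRUE,
                         extra = character()) {
  sites <- oracle_levels(df$site, c("Amboseli", "Isinya"))
  breeds <- oracle_levels(df$breed, c("RedMaasai", "Dorper", "Cross"))
  quals <- oracle_levels(df$quality, c("Best", "Average", "Poor"))
  n <- nrow(df)
  cols <- list(int = rep(1, n))
  terms <- list(intercept = "int")
  if (length(sites) > 1) {
    for (s in sites[-1]) {
      nm <- paste0("S.", s)
      cols[[nm]] <- as.numeric(df$site == s)
      terms$site <- c(terms$site, nm)
    }
  }
  fnames <- character()
  for (s in sites) {
    fs <- sort(unique(as.character(df$farmer_id[df$site == s])))
    if (length(fs) < 2) next
    for (k in seq_len(length(fs) - 1)) {
      nm <- paste0("Fm.", s, ".", k)
      v <- numeric(n)
      v[df$site == s & df$farmer_id == fs[k]] <- 1
      v[df$site == s & df$farmer_id == fs[length(fs)]] <- -1
      cols[[nm]] <- v
      fnames <- c(fnames, nm)
    }
  }
  if (length(fnames) > 0) terms$farmer <- fnames
  if (length(breeds) > 1) {
    for (b in breeds[-1]) {
      nm <- paste0("B.", b)
      cols[[nm]] <- as.numeric(df$breed == b)
      terms$breed <- c(terms$breed, nm)
    }
  }
  if (length(quals) > 1) {
    for (q in quals[-1]) {
      nm <- paste0("Q.", q)
      cols[[nm]] <- as.numeric(df$quality == q)
      terms$quality <- c(terms$quality, nm)
    }
  }
  if (include_interaction && length(sites) > 1 && length(breeds) > 1) {
    for (b in breeds[-1]) {
      for (s in sites[-1]) {
        nm <- paste0("BS.", b, ".", s)
        cols[[nm]] <- as.numeric(df$breed == b) * as.numeric(df$site == s)
        terms$breed_site <- c(terms$breed_site, nm)
      }
    }
  }
  if ("age" %in% extra) {
    cols[["age"]] <- as.numeric(df$age) - mean(as.numeric(df$age))
    terms$age <- "age"
  }
  X <- do.call(cbind, cols)
  list(X = X, terms = terms, sites = sites, breeds = breeds,
       quals = quals,
       farmers = lapply(stats::setNames(sites, sites), function(s) {
         sort(unique(as.character(df$farmer_id[df$site == s])))
       }))
}

oracle_rss <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  sum((y - X %*% b)^2)
}

oracle_fit <- function(om, y) {
  X <- om$X
  XtXi <- solve(crossprod(X))
  beta <- drop(XtXi %*% crossprod(X, y))
  rss <- sum((y - X %*% beta)^2)
  dfres <- nrow(X) - ncol(X)
  list(beta = beta, rss = rss, sigma2 = rss / dfres, df = dfres,
       XtXi = XtXi)
}

oracle_factor_sets <- list(
  site = "site", farmer = "farmer", breed = "breed", quality = "quality",
  breed_site = c("breed", "site"), age = "age"
)

oracle_type2 <- function(om, y) {
  of <- oracle_fit(om, y)
  tnames <- setdiff(names(om$terms), "intercept")
  out <- lapply(tnames, function(tm) {
    fs <- oracle_factor_sets[[tm]]
    others <- setdiff(tnames, tm)
    contains <- vapply(others, function(o) {
      all(fs %in% oracle_factor_sets[[o]])
    }, logical(1))
    base_terms <- c("intercept", others[!contains])
    base_cols <- unlist(om$terms[base_terms])
    full_cols <- c(base_cols, om$terms[[tm]])
    ss <- oracle_rss(om$X[, base_cols, drop = FALSE], y) -
      oracle_rss(om$X[, full_cols, drop = FALSE], y)
    q <- length(om$terms[[tm]])
    f <- (ss / q) / of$sigma2
    data.frame(term = tm, df = q, sum_sq = ss, statistic = f,
               p_value = stats::pf(f, q, of$df, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

# encode one grid row with the oracle's column layout
oracle_grid_row <- function(om, site, farmer, breed, quality) {
  df1 <- data.frame(site = site, farmer_id = farmer, breed = breed,
                    quality = quality)
  v <- stats::setNames(numeric(ncol(om$X)), colnames(om$X))
  v["int"] <- 1
  for (nm in colnames(om$X)) {
    if (startsWith(nm, "S.")) v[nm] <- as.numeric(site == sub("^S\\.", "", nm))
    if (startsWith(nm, "B.")) v[nm] <- as.numeric(breed == sub("^B\\.", "", nm))
    if (startsWith(nm, "Q.")) v[nm] <- as.numeric(quality == sub("^Q\\.", "", nm))
    if (startsWith(nm, "BS.")) {
      parts <- strsplit(sub("^BS\\.", "", nm), "\\.")[[1]]
      v[nm] <- as.numeric(breed == parts[1] && site == parts[2])
    }
    if (startsWith(nm, "Fm.")) {
      parts <- strsplit(sub("^Fm\\.", "", nm), "\\.")[[1]]
      s <- parts[1]
      k <- as.integer(parts[2])
      fs <- om$farmers[[s]]
      if (site == s && farmer == fs[k]) v[nm] <- 1
      if (site == s && farmer == fs[length(fs)]) v[nm] <- -1
    }
  }
  v
}

# LS-means for the breed-within-site margin: equal weight per quality
# class and per farmer within the margin's site
oracle_lsmeans_breed_site <- function(om, y) {
  of <- oracle_fit(om, y)
  out <- list()
  for (s in om$sites) {
    for (b in om$breeds) {
      fs <- om$farmers[[s]]
      acc <- 0
      cnt <- 0
      for (f in fs) {
        for (q in om$quals) {
          acc <- acc + oracle_grid_row(om, s, f, b, q)
          cnt <- cnt + 1
        }
      }
      cvec <- acc / cnt
      est <- sum(cvec * of$beta)
      se <- sqrt(drop(t(cvec) %*% of$XtXi %*% cvec) * of$sigma2)
      out[[paste(s, b)]] <- data.frame(site = s, breed = b,
                                       estimate = est, se = se)
    }
  }
  do.call(rbind, out)
}

# random small survey-like instance with a full-rank design
random_instance <- function(n_max = 60) {
  repeat {
    n_farmers <- sample(2:3, 2, replace = TRUE)
    farms <- data.frame(
      site = rep(c("Amboseli", "Isinya"), n_farmers),
      farmer_id = paste0("F", seq_len(sum(n_farmers)))
    )
    n <- sample(30:n_max, 1)
    idx <- sample(nrow(farms), n, replace = TRUE)
    df <- data.frame(
      site = farms$site[idx],
      farmer_id = farms$farmer_id[idx],
      breed = sample(c("RedMaasai", "Dorper", "Cross"), n, replace = TRUE),
      quality = sample(c("Best", "Average", "Poor"), n, replace = TRUE),
      age = sample(1:9, n, replace = TRUE),
      y = stats::rnorm(n, 40, 5)
    )
    om <- oracle_model(df)
    if (qr(om$X)$rank == ncol(om$X) && nrow(om$X) > ncol(om$X) + 2) {
      return(df)
    }
  }
}
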
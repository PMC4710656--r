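#' Build the fixed-effects design for a trait model
#'
#' Constructs the full-rank-reduced design matrix of the survey trait
#' model: overall mean, site, farmer nested within site, breed group,
#' quality class, and the breed-by-site interaction. Site, breed and
#' quality are treatment-coded against their first level; the nested farmer
#' effect is sum-to-zero coded *within each site*, which keeps the site
#' contrast estimable while identifying farmer deviations inside their own
#' site (a plain farmer factor would alias site). Factors with a single
#' observed level are dropped with a warning. Optional screened terms —
#' `"age"` (centred numeric covariate), `"quality_breed"` and
#' `"quality_site"` interactions — can be appended.
#'
#' @param data Ewe records (needs `site`, `farmer_id`, `breed`, `quality`,
#'   the response column, and `age` if requested).
#' @param response Name of the response trait column.
#' @param include_interaction Include breed-by-site (default `TRUE`).
#' @param extra_terms Character subset of
#'   `c("age", "quality_breed", "quality_site")`.
#' @return A list with the design matrix `X`, response `y`, a `terms` map
#'   (term -> column indices), the encoder, and the rows of `data` used.
#' @export
build_design <- function(data, response, include_interaction = TRUE,
                         extra_terms = character()) {
  needed <- c("site", "farmer_id", "breed", "quality", response)
  if ("age" %in% extra_terms) needed <- c(needed, "age")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  keep <- stats::complete.cases(data[, needed])
  if (sum(keep) < length(needed)) abort("too few complete records to fit")
  data <- data[keep, ]
  enc <- make_encoder(data, include_interaction, extra_terms)
  Xt <- encode_rows(data, enc)
  list(X = Xt$X, y = as.numeric(data[[response]]), terms = Xt$terms,
       encoder = enc, data = tibble::as_tibble(data))
}

make_encoder <- function(data, include_interaction = TRUE,
                         extra_terms = character()) {
  std_order <- function(x, std) {
    u <- unique(as.character(x))
    if (all(u %in% std)) std[std %in% u] else sort(u)
  }
  md <- study_metadata()
  sites <- std_order(data$site, md$sites)
  breeds <- std_order(data$breed, md$breeds)
  quals <- std_order(data$quality, md$qualities)
  farmers <- lapply(setNames(sites, sites), function(s) {
    sort(unique(as.character(data$farmer_id[data$site == s])))
  })
  for (nm in c(site = "site", breed = "breed", quality = "quality")) {
    n_lev <- c(site = length(sites), breed = length(breeds),
               quality = length(quals))[[nm]]
    if (n_lev < 2) warn(paste0("single-level factor dropped: ", nm))
  }
  bad_extra <- setdiff(extra_terms,
                       c("age", "quality_breed", "quality_site"))
  if (length(bad_extra) > 0) {
    abort(paste0("unknown extra term(s): ",
                 paste(bad_extra, collapse = ", ")))
  }
  list(
    sites = sites, breeds = breeds, quals = quals, farmers = farmers,
    use_site = length(sites) > 1,
    use_breed = length(breeds) > 1,
    use_quality = length(quals) > 1,
    use_farmer = any(lengths(farmers) > 1),
    use_interaction = include_interaction &&
      length(sites) > 1 && length(breeds) > 1,
    extra = extra_terms,
    age_center = if ("age" %in% extra_terms) mean(data$age) else NA_real_
  )
}

encode_rows <- function(data, enc) {
  n <- nrow(data)
  site <- as.character(data$site)
  breed <- as.character(data$breed)
  qual <- as.character(data$quality)
  farmer <- as.character(data$farmer_id)

  cols <- list(`(Intercept)` = rep(1, n))
  terms <- list(intercept = 1L)
  add_term <- function(name, mat) {
    start <- length(cols) + 1L
    for (cn in colnames(mat)) cols[[cn]] <<- mat[, cn]
    terms[[name]] <<- seq.int(start, length.out = ncol(mat))
  }
  dummies <- function(x, levels, prefix) {
    m <- vapply(levels[-1], function(l) as.numeric(x == l), numeric(n))
    m <- matrix(m, nrow = n,
                dimnames = list(NULL, paste0(prefix, levels[-1])))
    m
  }

  if (enc$use_site) add_term("site", dummies(site, enc$sites, "site:"))
  if (enc$use_farmer) {
    fcols <- list()
    for (s in enc$sites) {
      fs <- enc$farmers[[s]]
      m <- length(fs)
      if (m < 2) next
      for (k in seq_len(m - 1)) {
        # sum-to-zero contrast within site s: farmer k vs last farmer
        v <- as.numeric(site == s & farmer == fs[k]) -
          as.numeric(site == s & farmer == fs[m])
        fcols[[paste0("farmer:", s, ":", fs[k])]] <- v
      }
    }
    add_term("farmer", do.call(cbind, fcols))
  }
  if (enc$use_breed) add_term("breed", dummies(breed, enc$breeds, "breed:"))
  if (enc$use_quality) {
    add_term("quality", dummies(qual, enc$quals, "quality:"))
  }
  if (enc$use_interaction) {
    m <- list()
    for (b in enc$breeds[-1]) {
      for (s in enc$sites[-1]) {
        m[[paste0("breed_site:", b, ":", s)]] <-
          as.numeric(breed == b) * as.numeric(site == s)
      }
    }
    add_term("breed_site", do.call(cbind, m))
  }
  if ("age" %in% enc$extra) {
    add_term("age", matrix(as.numeric(data$age) - enc$age_center,
                           ncol = 1, dimnames = list(NULL, "age")))
  }
  if ("quality_breed" %in% enc$extra && enc$use_quality && enc$use_breed) {
    m <- list()
    for (q in enc$quals[-1]) {
      for (b in enc$breeds[-1]) {
        m[[paste0("quality_breed:", q, ":", b)]] <-
          as.numeric(qual == q) * as.numeric(breed == b)
      }
    }
    add_term("quality_breed", do.call(cbind, m))
  }
  if ("quality_site" %in% enc$extra && enc$use_quality && enc$use_site) {
    m <- list()
    for (q in enc$quals[-1]) {
      for (s in enc$sites[-1]) {
        m[[paste0("quality_site:", q, ":", s)]] <-
          as.numeric(qual == q) * as.numeric(site == s)
      }
    }
    add_term("quality_site", do.call(cbind, m))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, terms = terms)
}

#' Fit the survey trait model by least squares
#'
#' Fits the fixed linear model
#' `trait = mean + site + farmer(site) + breed + quality + breed:site + e`
#' to one trait at a time by ordinary least squares on the reduced design
#' of [build_design()]. Farmer-within-site is a fixed nested effect. The
#' returned object carries the coefficient vector, residual variance, a
#' numeric residual-diagnostics summary (skewness, excess kurtosis,
#' Shapiro-Wilk), and everything needed for [anova_table()],
#' [ls_means()] and [letter_groups()].
#'
#' @inheritParams build_design
#' @param ss_type Sum-of-squares type for [anova_table()]: `"II"`
#'   (default) or `"I"`.
#' @param alpha Significance level carried to downstream letter displays.
#' @return An object of class `trait_fit`.
#' @export
fit_trait_model <- function(data, response, include_interaction = TRUE,
                            extra_terms = character(),
                            ss_type = c("II", "I"), alpha = 0.05) {
  ss_type <- match.arg(ss_type)
  des <- build_design(data, response, include_interaction, extra_terms)
  fit <- fit_design(des$X, des$y)
  res <- fit$residuals
  n <- length(res)
  m2 <- mean(res^2)
  diagnostics <- tibble::tibble(
    skewness = mean(res^3) / m2^1.5,
    kurtosis_excess = mean(res^4) / m2^2 - 3,
    shapiro_w = if (n >= 3 && n <= 5000) shapiro.test(res)$statistic[[1]]
                else NA_real_,
    shapiro_p = if (n >= 3 && n <= 5000) shapiro.test(res)$p.value
                else NA_real_
  )
  structure(
    list(response = response, design = des, coefficients = fit$coefficients,
         vcov = fit$vcov, sigma2 = fit$sigma2, df_residual = fit$df_residual,
         fitted = fit$fitted, residuals = res, rss = fit$rss,
         diagnostics = diagnostics, ss_type = ss_type, alpha = alpha),
    class = "trait_fit"
  )
}

# least-squares core on an explicit design matrix; errors on aliasing
fit_design <- function(X, y) {
  fit <- lm(y ~ X - 1)
  beta <- coef(fit)
  names(beta) <- colnames(X)
  if (any(is.na(beta))) {
    abort(paste0("design is rank deficient; aliased column(s): ",
                 paste(colnames(X)[is.na(beta)], collapse = ", ")))
  }
  df_res <- fit$df.residual
  if (df_res <= 0) abort("no residual degrees of freedom")
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df_res
  V <- vcov(fit)
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coefficients = beta, vcov = V, sigma2 = sigma2,
       df_residual = df_res, fitted = fit$fitted.values,
       residuals = fit$residuals, rss = rss)
}

rss_for_terms <- function(des, term_names) {
  idx <- sort(unique(unlist(des$terms[term_names])))
  X <- des$X[, idx, drop = FALSE]
  qrX <- qr(X)
  sum(qr.resid(qrX, des$y)^2)
}

term_factor_sets <- list(
  site = "site", farmer = "farmer", breed = "breed", quality = "quality",
  breed_site = c("breed", "site"), age = "age",
  quality_breed = c("quality", "breed"),
  quality_site = c("quality", "site")
)

signif_code <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Term-wise F tests for a fitted trait model
#'
#' Marginal (type II) F tests by default: each term is tested by comparing
#' the model containing every term that does not contain it, with and
#' without the term itself (so `site` is never tested in the presence of
#' `breed:site`, respecting marginality; the nested farmer deviations,
#' being within-site contrasts, stay in both models). The denominator is
#' always the full-model residual mean square. `type = "I"` gives
#' sequential tests in model order; the two agree on balanced orthogonal
#' designs. Significance codes follow the `***`/`**`/`*`/`ns` convention.
#'
#' @param fit A `trait_fit`.
#' @param type `"II"` (default, marginal) or `"I"` (sequential).
#' @return Tibble with `term`, `df`, `sum_sq`, `mean_sq`, `statistic`
#'   (F), `p_value` and `signif`.
#' @export
anova_table <- function(fit, type = fit$ss_type) {
  type <- match.arg(type, c("II", "I"))
  des <- fit$design
  all_terms <- setdiff(names(des$terms), "intercept")
  mse <- fit$sigma2
  df_res <- fit$df_residual
  rows <- purrr::map(all_terms, function(tm) {
    df_t <- length(des$terms[[tm]])
    if (type == "II") {
      fs <- term_factor_sets[[tm]]
      contains_tm <- vapply(all_terms, function(o) {
        all(fs %in% term_factor_sets[[o]]) && !identical(o, tm)
      }, logical(1))
      base <- c("intercept", all_terms[!contains_tm & all_terms != tm])
      ss <- rss_for_terms(des, base) - rss_for_terms(des, c(base, tm))
    } else {
      pos <- match(tm, all_terms)
      before <- c("intercept", all_terms[seq_len(pos - 1)])
      ss <- rss_for_terms(des, before) - rss_for_terms(des, c(before, tm))
    }
    f <- (ss / df_t) / mse
    tibble::tibble(term = tm, df = df_t, sum_sq = ss, mean_sq = ss / df_t,
                   statistic = f, p_value = pf(f, df_t, df_res,
                                               lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  out$signif <- signif_code(out$p_value)
  out <- dplyr::bind_rows(out, tibble::tibble(
    term = "residual", df = df_res, sum_sq = fit$rss, mean_sq = mse,
    statistic = NA_real_, p_value = NA_real_, signif = NA_character_
  ))
  out
}

#' Preliminary screening of candidate model terms
#'
#' Reproduces the preliminary-analysis step of the survey model: candidate
#' terms (ewe age from dentition, and the quality-class interactions with
#' breed and with site) are each added to the base model in turn and kept
#' only if significant at `alpha`. Candidates that cannot be estimated on
#' the given data are reported and treated as not retained.
#'
#' @inheritParams fit_trait_model
#' @param candidates Character vector out of
#'   `c("age", "quality_breed", "quality_site")`.
#' @param alpha Retention threshold (default 0.05).
#' @return A list with `retained` (character vector), `report` (tibble
#'   with `candidate`, `df`, `statistic`, `p_value`, `retained`) and
#'   `extra_terms` to pass on to [fit_trait_model()].
#' @export
screen_terms <- function(data, response,
                         candidates = c("age", "quality_breed",
                                        "quality_site"),
                         alpha = 0.05, include_interaction = TRUE) {
  if (length(candidates) == 0) {
    return(list(retained = character(),
                report = tibble::tibble(candidate = character(),
                                        df = integer(),
                                        statistic = numeric(),
                                        p_value = numeric(),
                                        retained = logical()),
                extra_terms = character()))
  }
  base <- fit_trait_model(data, response,
                          include_interaction = include_interaction)
  report <- purrr::map(candidates, function(cand) {
    aug <- tryCatch(
      fit_trait_model(data, response,
                      include_interaction = include_interaction,
                      extra_terms = cand),
      error = function(e) NULL
    )
    if (is.null(aug) || !cand %in% names(aug$design$terms)) {
      return(tibble::tibble(candidate = cand, df = NA_integer_,
                            statistic = NA_real_, p_value = NA_real_,
                            retained = FALSE))
    }
    q <- length(aug$design$terms[[cand]])
    f <- ((base$rss - aug$rss) / q) / aug$sigma2
    p <- pf(f, q, aug$df_residual, lower.tail = FALSE)
    tibble::tibble(candidate = cand, df = q, statistic = f, p_value = p,
                   retained = p < alpha)
  }) |> dplyr::bind_rows()
  list(retained = report$candidate[report$retained],
       report = report,
       extra_terms = report$candidate[report$retained])
}

#' @export
print.trait_fit <- function(x, ...) {
  cat("Survey trait model:", x$response, "\n")
  cat("  terms:", paste(setdiff(names(x$design$terms), "intercept"),
                        collapse = " + "), "\n")
  cat("  n =", length(x$design$y),
      " residual df =", x$df_residual,
      " sigma =", signif(sqrt(x$sigma2), 4), "\n")
  invisible(x)
}

#' @rdname fit_trait_model
#' @param x A `trait_fit` object.
#' @param ... Unused.
#' @export
tidy.trait_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  est <- x$coefficients
  stat <- est / se
  tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    statistic = unname(stat),
    p_value = 2 * pt(-abs(stat), x$df_residual)
  )
}

#' @rdname fit_trait_model
#' @export
glance.trait_fit <- function(x, ...) {
  y <- x$design$y
  tss <- sum((y - mean(y))^2)
  tibble::tibble(
    r_squared = 1 - x$rss / tss,
    sigma = sqrt(x$sigma2),
    df_residual = x$df_residual,
    nobs = length(y),
    skewness = x$diagnostics$skewness,
    kurtosis_excess = x$diagnostics$kurtosis_excess,
    shapiro_p = x$diagnostics$shapiro_p
  )
}
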
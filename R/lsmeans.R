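#' Least-squares means for model factors
#'
#' Model-based marginal means: the prediction for each cell of the full
#' factor grid is averaged over the levels of every factor not in the
#' requested margin, with equal weight per level. The averaging is
#' hierarchical for the nested farmer effect — farmers get equal weight
#' *within their site* and sites get equal weight — so unequal farmer
#' counts per site do not tilt the margin. If the model carries an age
#' covariate, means are evaluated at its sample mean. Standard errors come
#' from the variance of the corresponding coefficient contrast; with a
#' full-rank reduced design every requested margin is estimable.
#'
#' @param fit A `trait_fit` from [fit_trait_model()].
#' @param margin One of `"breed_site"` (breed within site), `"quality"`,
#'   `"breed"`, `"site"`.
#' @return A `lsmeans_tbl` tibble with the margin columns, `estimate`,
#'   `se` and `df`; the full covariance of the estimates is attached for
#'   [letter_groups()].
#' @export
ls_means <- function(fit, margin = c("breed_site", "quality", "breed",
                                     "site")) {
  margin <- match.arg(margin)
  enc <- fit$design$encoder
  grid <- ref_grid_cells(enc)
  rows <- encode_rows(grid, enc)$X
  # hierarchical equal weights: site -> farmer(site); breed; quality
  w <- (1 / length(enc$sites)) *
    (1 / vapply(grid$site, function(s) length(enc$farmers[[s]]),
                numeric(1))) *
    (1 / length(enc$breeds)) * (1 / length(enc$quals))
  margin_cols <- switch(margin,
    breed_site = c("site", "breed"),
    quality = "quality",
    breed = "breed",
    site = "site"
  )
  key <- do.call(paste, c(grid[margin_cols], sep = "\r"))
  levels_tbl <- dplyr::distinct(grid[margin_cols])
  lkey <- do.call(paste, c(levels_tbl[margin_cols], sep = "\r"))
  C <- t(vapply(lkey, function(k) {
    in_cell <- key == k
    colSums(rows[in_cell, , drop = FALSE] * w[in_cell]) / sum(w[in_cell])
  }, numeric(ncol(rows))))
  est <- unname(drop(C %*% fit$coefficients))
  V <- unname(C %*% fit$vcov %*% t(C))
  out <- levels_tbl
  out$estimate <- est
  out$se <- sqrt(diag(V))
  out$df <- fit$df_residual
  structure(tibble::as_tibble(out),
            vcov = V, margin = margin_cols, alpha = fit$alpha,
            response = fit$response,
            class = c("lsmeans_tbl", class(tibble::as_tibble(out))))
}

ref_grid_cells <- function(enc) {
  farms <- dplyr::bind_rows(lapply(enc$sites, function(s) {
    tibble::tibble(site = s, farmer_id = enc$farmers[[s]])
  }))
  grid <- tidyr::expand_grid(farms, breed = enc$breeds,
                             quality = enc$quals)
  if ("age" %in% enc$extra) grid$age <- enc$age_center
  grid
}

#' Compact letter display for least-squares means
#'
#' Pairwise comparisons of the LS-means (t tests on the estimate
#' differences, unadjusted at `alpha` by default; a Tukey-style adjustment
#' is available) summarised as letters by the insert-and-absorb algorithm:
#' levels sharing a letter are not significantly different. Letters are
#' assigned scanning the means in descending order, so `"a"` marks the
#' group containing the largest mean.
#'
#' @param lsm A `lsmeans_tbl` from [ls_means()].
#' @param alpha Significance level (default: the fit's, usually 0.05).
#' @param adjust `"none"` (default) or `"tukey"`.
#' @return `lsm` with added `letters` column; the pairwise p-value matrix
#'   is attached as attribute `"pairwise_p"`.
#' @export
letter_groups <- function(lsm, alpha = attr(lsm, "alpha") %||% 0.05,
                          adjust = c("none", "tukey")) {
  adjust <- match.arg(adjust)
  V <- attr(lsm, "vcov")
  est <- lsm$estimate
  df <- lsm$df[1]
  k <- length(est)
  p <- matrix(1, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      se_ij <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
      tstat <- (est[i] - est[j]) / se_ij
      p[i, j] <- p[j, i] <- if (adjust == "tukey") {
        ptukey(sqrt(2) * abs(tstat), k, df, lower.tail = FALSE)
      } else {
        2 * pt(-abs(tstat), df)
      }
    }
  }
  ord <- order(-est)
  sig_sorted <- (p < alpha)[ord, ord, drop = FALSE]
  letters_sorted <- cld_insert_absorb(sig_sorted)
  out <- lsm
  out$letters <- letters_sorted[order(ord)]
  attr(out, "pairwise_p") <- p
  attr(out, "vcov") <- V
  out
}

# insert-and-absorb compact letter display on a logical "significantly
# different" matrix whose rows are already sorted by descending mean
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  sets <- list(seq_len(k))
  drop_absorbed <- function(sets) {
    keep <- rep(TRUE, length(sets))
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (a != b && keep[a] && all(sets[[a]] %in% sets[[b]]) &&
            (length(sets[[a]]) < length(sets[[b]]) ||
             (length(sets[[a]]) == length(sets[[b]]) && a > b))) {
          keep[a] <- FALSE
        }
      }
    }
    sets[keep]
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        if (!sig[i, j]) next
        new_sets <- list()
        for (s in sets) {
          if (i %in% s && j %in% s) {
            new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        sets <- drop_absorbed(new_sets)
      }
    }
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  out <- character(k)
  for (s in seq_along(sets)) {
    members <- sets[[s]]
    out[members] <- paste0(out[members], letters[s])
  }
  out
}

#' @export
print.lsmeans_tbl <- function(x, ...) {
  cat("Least-squares means", if (!is.null(attr(x, "response"))) {
    paste0("for ", attr(x, "response"))
  }, "\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
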
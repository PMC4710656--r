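#' Pipeline run configuration
#'
#' Assembles (or reads from YAML) the configuration driving
#' [run_pipeline()]: where the survey tables come from, which lexicon,
#' weight and cluster schemes to use, the significance level and
#' sum-of-squares type of the trait models, the output directory and the
#' seed.
#'
#' @param input `"study"` (analyse the bundled published contribution
#'   table), `"simulate"` (generate a synthetic survey), or a list
#'   `list(ewes = path, reasons = path)` of CSV files.
#' @param lexicon Path to a lexicon CSV, or `NULL` for the bundled one.
#' @param weights Numeric order weights (default `c(3, 2, 1)`).
#' @param alpha Significance level in (0, 1).
#' @param ss_type `"II"` or `"I"`.
#' @param seed Integer seed for simulation.
#' @param responses Trait columns to model when record-level data exist.
#' @return A `run_config` list.
#' @export
run_config <- function(input = "study", lexicon = NULL,
                       weights = c(3, 2, 1), alpha = 0.05,
                       ss_type = "II", seed = 1,
                       responses = c("body_weight", "body_length",
                                     "heart_girth", "bcs", "milk_yield",
                                     "price")) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    abort("alpha must be a single number in (0, 1)")
  }
  if (is.list(input)) {
    for (p in unlist(input)) {
      if (!file.exists(p)) abort(paste0("input file not found: ", p))
    }
  } else if (!input %in% c("study", "simulate")) {
    abort('input must be "study", "simulate", or a list of file paths')
  }
  if (!is.null(lexicon) && !file.exists(lexicon)) {
    abort(paste0("lexicon file not found: ", lexicon))
  }
  structure(list(input = input, lexicon = lexicon,
                 weights = weight_scheme(weights), alpha = alpha,
                 ss_type = match.arg(ss_type, c("II", "I")),
                 seed = as.integer(seed), responses = responses),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any of the `run_config()` fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' Run the full preference-analysis pipeline
#'
#' Executes every stage applicable to the configured input and writes the
#' results under `out_dir`: the weighted-reasons preference table and its
#' four-category clustered summary (always); and, when record-level survey
#' data are available (files or simulation), the across-breed rank summary
#' plus, per trait, the ANOVA table, the LS-means with letter groups, and
#' the term-screening report. A JSON manifest lists every emitted file
#' with its MD5 checksum, so identical configurations are verifiably
#' reproducible. On a stage failure the partial outputs are kept and the
#' manifest records the failure point.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `status` (0 ok, 2 validation failure,
#'   3 estimation failure) and the `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  status <- 0L
  failed_at <- NULL
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p, progress = FALSE)
    files <<- c(files, p)
  }
  lexicon <- if (is.null(config$lexicon)) default_lexicon() else {
    read_lexicon(config$lexicon)
  }

  run_stage <- function(stage, code, code_on_error = 3L) {
    tryCatch(code, error = function(e) {
      status <<- code_on_error
      failed_at <<- stage
      warn(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
      NULL
    })
  }

  ewes <- NULL
  reasons <- NULL
  if (identical(config$input, "study")) {
    pref <- run_stage("prefs", {
      wr_from_contributions(study_contributions())
    })
  } else {
    if (identical(config$input, "simulate")) {
      sim <- run_stage("simulate", {
        generate_flocks(flock_design(), seed = config$seed)
      })
      if (!is.null(sim)) {
        ewes <- sim$ewes
        reasons <- map_reasons(sim$reasons[, c("ewe_id", "order", "phrase")],
                               lexicon)
        emit(sim$ewes, "ewes.csv")
        emit(sim$reasons, "reasons.csv")
      }
    } else {
      loaded <- run_stage("load", {
        e <- read_ewe_records(config$input$ewes)
        r <- read_reason_records(config$input$reasons, e)
        list(e = e, r = r)
      }, code_on_error = 2L)
      if (!is.null(loaded)) {
        ewes <- loaded$e
        reasons <- map_reasons(loaded$r, lexicon)
      }
    }
    pref <- if (!is.null(ewes)) run_stage("prefs", {
      preference_table(reasons, ewes, weights = config$weights)
    })
  }

  if (!is.null(pref)) {
    emit(render_preference_report(pref), "preference_table.csv")
    emit(render_preference_report(cluster_wr(pref)), "clustered_table.csv")
  }
  if (!is.null(ewes)) {
    rk <- run_stage("ranks", summarize_breed_ranks(ewes))
    if (!is.null(rk)) emit(rk, "breed_ranks.csv")
    for (resp in intersect(config$responses, names(ewes))) {
      res <- run_stage(paste0("glm:", resp), {
        scr <- screen_terms(ewes, resp, alpha = config$alpha)
        fit <- fit_trait_model(ewes, resp, extra_terms = scr$extra_terms,
                               ss_type = config$ss_type,
                               alpha = config$alpha)
        lsm <- letter_groups(ls_means(fit, "breed_site"),
                             alpha = config$alpha)
        list(scr = scr, fit = fit, lsm = lsm)
      })
      if (!is.null(res)) {
        emit(res$scr$report, paste0("screening_", resp, ".csv"))
        emit(anova_table(res$fit), paste0("anova_", resp, ".csv"))
        emit(tibble::as_tibble(res$lsm), paste0("lsmeans_", resp, ".csv"))
      }
    }
  }

  manifest <- list(
    config = list(input = if (is.list(config$input)) "files" else
                    config$input,
                  weights = unname(config$weights), alpha = config$alpha,
                  ss_type = config$ss_type, seed = config$seed),
    status = status,
    failed_at = failed_at,
    files = lapply(files, function(p) {
      list(name = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(status = status, manifest = manifest, out_dir = out_dir))
}
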
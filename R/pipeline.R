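#' Assemble a pipeline run configuration
#'
#' @param corpus Path to a review CSV/JSON-lines file, a `useis_corpus`, or
#'   `NULL` to simulate the default synthetic scenario.
#' @param hierarchy Path to a hierarchy JSON/YAML file, a `useis_hierarchy`,
#'   or `NULL` to use the default scenario's hierarchy.
#' @param market Market to evaluate (`"US"` or `"CN"`).
#' @param out_dir Output directory for the report bundle; `NULL` writes
#'   nothing.
#' @param seed Integer seed funneling all randomness (simulation only; the
#'   analysis itself is deterministic).
#' @param n_reviews Corpus size when simulating.
#' @param filters A [filter_config()].
#' @param bot_predicate Optional bot flagger passed to [apply_filters()];
#'   `"synthetic"` selects [flag_bot_authors()].
#' @param scale_table Optional path to a scale-table CSV (see
#'   [read_scale_table()]) overriding the per-set equal-width mapping.
#' @param ttf Optional list describing the availability stage: either
#'   `list(catalog = <csv>, matrices = <named csv paths>)` or
#'   `list(simulate = list(n_apps =, target_rate =, ...))`.
#' @param verbose Emit stage messages to stderr.
#' @return A list of class `useis_run_config`.
#' @export
run_config <- function(corpus = NULL, hierarchy = NULL, market = "US",
                       out_dir = NULL, seed = 1, n_reviews = 50000,
                       filters = filter_config(), bot_predicate = NULL,
                       scale_table = NULL, ttf = NULL, verbose = TRUE) {
  if (!is.numeric(seed) || length(seed) != 1 || seed != as.integer(seed)) {
    abort("seed must be a single integer", class = "useis_validation_error")
  }
  structure(
    list(corpus = corpus, hierarchy = hierarchy, market = market,
         out_dir = out_dir, seed = as.integer(seed), n_reviews = n_reviews,
         filters = filters, bot_predicate = bot_predicate,
         scale_table = scale_table, ttf = ttf, verbose = verbose),
    class = "useis_run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; `filters` maps
#' onto [filter_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `useis_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  fc <- if (is.null(y$filters)) filter_config() else do.call(filter_config, y$filters)
  run_config(
    corpus = y$corpus, hierarchy = y$hierarchy,
    market = y$market %||% "US", out_dir = y$out_dir,
    seed = y$seed %||% 1, n_reviews = y$n_reviews %||% 50000,
    filters = fc, bot_predicate = y$bot_predicate,
    scale_table = y$scale_table, ttf = y$ttf,
    verbose = y$verbose %||% TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(name, verbose, expr) {
  if (verbose) message("[useis] stage: ", name)
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline failed at stage '", name, "': ", conditionMessage(e)),
          class = "useis_pipeline_error", parent = e)
  })
}

#' Run the full evaluation pipeline
#'
#' Executes, in order: corpus acquisition (file or simulation), rule-based
#' filtering, per-topic proportion and positive-share summaries, the
#' proportion-driven hierarchy weighting with all consistency tests,
#' satisfaction scoring, and improvement ranking, plus an optional
#' task-technology-fit availability stage. Any failed consistency test
#' aborts the run before scoring. Identical configuration and seed yield a
#' byte-identical report bundle.
#'
#' @param config A `useis_run_config` (or path to a YAML one).
#' @return A list of class `useis_report_bundle` with elements
#'   `filter_report`, `proportions`, `ahp`, `scored`, `priorities`, and
#'   (optionally) `ttf`; written to `out_dir` as `report.json`,
#'   `tables/*.csv`, and `manifest.json` when configured.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "useis_run_config"))
  verbose <- isTRUE(config$verbose)

  scenario <- if (is.null(config$corpus)) {
    default_scenario(n_reviews = config$n_reviews, seed = config$seed)
  }
  corpus <- run_stage("corpus", verbose, {
    if (!is.null(scenario)) {
      simulate_reviews(scenario$spec)
    } else if (is.character(config$corpus)) {
      read_reviews(config$corpus)
    } else {
      review_corpus(config$corpus)
    }
  })

  hierarchy <- run_stage("hierarchy", verbose, {
    if (is.null(config$hierarchy)) {
      if (is.null(scenario)) {
        abort("a hierarchy must be supplied when the corpus is not simulated")
      }
      scenario$hierarchy
    } else {
      as_hierarchy_frame(config$hierarchy)
    }
  })

  bot_pred <- config$bot_predicate
  if (identical(bot_pred, "synthetic")) bot_pred <- flag_bot_authors
  if (is.null(bot_pred) && !is.null(scenario)) bot_pred <- flag_bot_authors

  filtered <- run_stage("preprocess", verbose, {
    apply_filters(corpus, config = config$filters, bot_predicate = bot_pred)
  })

  props <- run_stage("proportions", verbose, {
    topic_proportions(filtered$corpus, config$market)
  })
  shares <- run_stage("positive-shares", verbose, {
    positive_shares(filtered$corpus, config$market)
  })

  scale <- if (is.null(config$scale_table)) NULL else
    read_scale_table(config$scale_table)
  ahp <- run_stage("ahp", verbose, {
    fit <- ahp_weights(hierarchy, props, scale = scale)
    bad <- fit$consistency$set[!fit$consistency$pass]
    if (length(bad) > 0 || !fit$combined$pass) {
      abort(paste0(
        "consistency test failed for: ",
        paste(c(bad, if (!fit$combined$pass) "combined"), collapse = ", ")
      ), class = "useis_consistency_error")
    }
    fit
  })

  scored <- run_stage("score", verbose, {
    score_hierarchy(hierarchy, ahp$weights, shares)
  })
  priorities <- improvement_priorities(scored)

  ttf <- NULL
  if (!is.null(config$ttf)) {
    ttf <- run_stage("ttf", verbose, {
      if (!is.null(config$ttf$simulate)) {
        args <- config$ttf$simulate
        args$seed <- args$seed %||% config$seed
        apps <- simulate_fit_matrices(do.call(cohort_spec, args))
        cohort_summary(apps, attr(apps, "catalog"))
      } else {
        catalog <- read_demand_catalog(config$ttf$catalog)
        apps <- purrr::imap(
          config$ttf$matrices,
          function(p, id) read_fit_matrix(p, id, catalog)
        )
        cohort_summary(unname(apps), catalog)
      }
    })
  }

  bundle <- structure(
    list(
      market = config$market,
      seed = config$seed,
      filter_report = filtered$report,
      proportions = props,
      positive_shares = shares,
      ahp = ahp,
      scored = scored,
      priorities = priorities,
      ttf = ttf
    ),
    class = "useis_report_bundle"
  )
  if (!is.null(config$out_dir)) {
    run_stage("write", verbose, write_report_bundle(bundle, config$out_dir))
  }
  bundle
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (the full machine-readable bundle), `tables/*.csv`
#' (proportions, weights, consistency, scored hierarchy, priorities, and
#' availability tables), and `manifest.json` recording the seed, package
#' version, and MD5 checksum of every written artifact.
#'
#' @param bundle A `useis_report_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "useis_report_bundle"))
  tables_dir <- file.path(out_dir, "tables")
  dir.create(tables_dir, showWarnings = FALSE, recursive = TRUE)

  report <- list(
    market = bundle$market,
    seed = bundle$seed,
    filter_report = unclass(bundle$filter_report),
    proportions = bundle$proportions,
    positive_shares = bundle$positive_shares,
    weights = list(
      criteria = bundle$ahp$weights$criteria,
      indicators = bundle$ahp$weights$indicators
    ),
    consistency = bundle$ahp$consistency,
    combined_consistency = bundle$ahp$combined,
    satisfaction = list(
      criteria = bundle$scored$criteria,
      indicators = bundle$scored$indicators,
      overall = bundle$scored$overall
    ),
    priorities = bundle$priorities
  )
  if (!is.null(bundle$ttf)) {
    report$ttf <- list(
      n_apps = bundle$ttf$n_apps,
      mean_utilization_pct = bundle$ttf$mean_utilization_pct,
      mean_demand_satisfaction_pct = bundle$ttf$mean_demand_satisfaction_pct,
      bin_counts = bundle$ttf$bin_counts,
      dimension_coverage = bundle$ttf$dimension_coverage,
      unmet_demands = bundle$ttf$unmet_demands,
      unmet_dimensions = bundle$ttf$unmet_dimensions
    )
  }
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  write.csv(bundle$proportions, file.path(tables_dir, "proportions.csv"),
            row.names = FALSE)
  write.csv(bundle$ahp$weights$indicators,
            file.path(tables_dir, "weights.csv"), row.names = FALSE)
  write.csv(bundle$ahp$consistency,
            file.path(tables_dir, "consistency.csv"), row.names = FALSE)
  write.csv(bundle$priorities, file.path(tables_dir, "priorities.csv"),
            row.names = FALSE)
  write_scored_hierarchy(bundle$scored,
                         csv_path = file.path(tables_dir, "satisfaction.csv"))
  if (!is.null(bundle$ttf)) {
    write_cohort_summary(bundle$ttf, file.path(out_dir, "ttf.json"),
                         csv_dir = tables_dir)
  }

  files <- sort(c(
    report_path,
    list.files(tables_dir, full.names = TRUE),
    if (!is.null(bundle$ttf)) file.path(out_dir, "ttf.json")
  ))
  manifest <- list(
    seed = bundle$seed,
    market = bundle$market,
    package = "useis",
    version = as.character(utils::packageVersion("useis")),
    files = lapply(files, function(f) {
      list(path = sub(paste0("^", out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
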
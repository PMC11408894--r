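# Task-technology fit: how well an app's functions cover the business
# demands of hypertension self-management. Each app contributes a binary
# function x demand incidence matrix over a shared demand catalog.

#' Define a demand catalog
#'
#' The catalog lists the business demands an app cohort is evaluated
#' against, each demand assigned to exactly one demand dimension (e.g.
#' health indicator recording, intelligent diagnosis).
#'
#' @param demands A data frame with columns `id`, `label`, `dimension`.
#' @param dimensions Optional character vector fixing dimension order.
#' @return A list of class `useis_demand_catalog`.
#' @export
demand_catalog <- function(demands, dimensions = NULL) {
  demands <- tibble::as_tibble(demands)
  if (!all(c("id", "dimension") %in% names(demands))) {
    abort("demand catalog needs columns 'id' and 'dimension'",
          class = "useis_validation_error")
  }
  if (nrow(demands) == 0) {
    abort("demand catalog is empty", class = "useis_empty_input_error")
  }
  if (anyDuplicated(demands$id)) {
    abort("demand ids must be unique", class = "useis_validation_error")
  }
  if (!"label" %in% names(demands)) demands$label <- demands$id
  if (is.null(dimensions)) dimensions <- unique(demands$dimension)
  if (length(setdiff(demands$dimension, dimensions)) > 0) {
    abort("demand dimensions not declared in 'dimensions'",
          class = "useis_validation_error")
  }
  structure(
    list(dimensions = dimensions,
         demands = demands[, c("id", "label", "dimension")]),
    class = "useis_demand_catalog"
  )
}

#' Read a demand catalog from CSV
#'
#' @param path CSV with columns `id`, `label`, `dimension`.
#' @return A `useis_demand_catalog`.
#' @export
read_demand_catalog <- function(path) {
  demand_catalog(read.csv(path, fileEncoding = "UTF-8"))
}

#' Construct one app's function-demand incidence matrix
#'
#' @param app_id App identifier.
#' @param incidence Binary matrix, functions as rows and demand ids as
#'   columns; column names must match the catalog's demand ids exactly.
#' @param catalog A `useis_demand_catalog`.
#' @return A list of class `useis_fit_matrix`.
#' @export
fit_matrix <- function(app_id, incidence, catalog) {
  stopifnot(inherits(catalog, "useis_demand_catalog"))
  incidence <- as.matrix(incidence)
  if (!all(incidence %in% c(0, 1))) {
    abort("incidence entries must be 0 or 1", class = "useis_validation_error")
  }
  if (is.null(colnames(incidence)) ||
      !identical(sort(colnames(incidence)), sort(catalog$demands$id))) {
    abort("incidence columns must match the catalog demand ids",
          class = "useis_validation_error")
  }
  incidence <- incidence[, catalog$demands$id, drop = FALSE]
  if (is.null(rownames(incidence)) && nrow(incidence) > 0) {
    rownames(incidence) <- paste0("f", seq_len(nrow(incidence)))
  }
  structure(
    list(app_id = app_id, incidence = incidence, catalog = catalog),
    class = "useis_fit_matrix"
  )
}

#' Read an incidence matrix from CSV
#'
#' Expects functions as rows (first column `function`), demand ids as the
#' remaining columns, and 0/1 cells.
#'
#' @param path CSV file path.
#' @param app_id App identifier.
#' @param catalog A `useis_demand_catalog`.
#' @return A `useis_fit_matrix`.
#' @export
read_fit_matrix <- function(path, app_id, catalog) {
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  fit_matrix(app_id, m, catalog)
}

#' Functional utilization rate
#'
#' The share of an app's functions that meet at least one catalog demand. A
#' function serving several demands still counts once: the rate asks whether
#' each function is useful, not how useful.
#'
#' @param fit A `useis_fit_matrix`.
#' @return A rate in `[0, 1]`.
#' @export
utilization_rate <- function(fit) {
  stopifnot(inherits(fit, "useis_fit_matrix"))
  n_fun <- nrow(fit$incidence)
  if (n_fun == 0) {
    abort("utilization rate undefined for an app with zero functions",
          class = "useis_validation_error")
  }
  sum(rowSums(fit$incidence) > 0) / n_fun
}

#' Demand satisfaction rate
#'
#' The share of catalog demands met by at least one of the app's functions.
#' A demand covered by several functions counts once.
#'
#' @param fit A `useis_fit_matrix`.
#' @return A rate in `[0, 1]`.
#' @export
demand_satisfaction_rate <- function(fit) {
  stopifnot(inherits(fit, "useis_fit_matrix"))
  n_dem <- ncol(fit$incidence)
  if (n_dem == 0) {
    abort("demand satisfaction rate undefined for an empty catalog",
          class = "useis_empty_input_error")
  }
  sum(colSums(fit$incidence) > 0) / n_dem
}

#' Per-app fit metrics
#'
#' @param fit A `useis_fit_matrix`.
#' @return A list with `utilization_rate`, `demand_satisfaction_rate`,
#'   `met_demands`, and `unmet_demands` (disjoint id sets covering the
#'   catalog).
#' @export
fit_metrics <- function(fit) {
  met <- colnames(fit$incidence)[colSums(fit$incidence) > 0]
  list(
    app_id = fit$app_id,
    utilization_rate = utilization_rate(fit),
    demand_satisfaction_rate = demand_satisfaction_rate(fit),
    met_demands = met,
    unmet_demands = setdiff(fit$catalog$demands$id, met)
  )
}

# Percent bins used throughout availability reporting: the first bin is
# closed on both ends, the rest are lower-open / upper-closed, so "between
# 41% and 60%" reads as (40, 60] and exactly 80% does not count as
# "exceeding 80%".
RATE_BINS <- c("[0,20]", "(20,40]", "(40,60]", "(60,80]", "(80,100]")

rate_bin <- function(rate) {
  cut(rate * 100, breaks = c(0, 20, 40, 60, 80, 100),
      include.lowest = TRUE, right = TRUE, labels = RATE_BINS)
}

#' Round a proportion to a percentage
#'
#' Half-even rounding to 2 decimal places, the convention used in all
#' percent reporting here.
#'
#' @param x Proportion(s) in `[0, 1]`.
#' @return Percent value(s).
#' @export
as_percent <- function(x) round(100 * x, 2)

#' Cohort availability summary
#'
#' Aggregates per-app fit metrics over an app cohort sharing one demand
#' catalog: mean utilization and demand-satisfaction rates, counts of apps
#' per demand-satisfaction bin, per-dimension coverage (share of apps
#' meeting at least one demand in the dimension), and the demands and
#' dimensions met by no app in the cohort.
#'
#' @param apps A list of `useis_fit_matrix` objects on the same catalog.
#' @param catalog The shared `useis_demand_catalog`.
#' @return A list of class `useis_cohort_summary`.
#' @export
cohort_summary <- function(apps, catalog) {
  stopifnot(inherits(catalog, "useis_demand_catalog"))
  if (length(apps) == 0) {
    abort("cohort is empty", class = "useis_empty_input_error")
  }
  same <- vapply(
    apps,
    function(a) identical(a$catalog$demands$id, catalog$demands$id),
    logical(1)
  )
  if (!all(same)) {
    abort("all apps must share the cohort demand catalog",
          class = "useis_validation_error")
  }
  metrics <- lapply(apps, fit_metrics)
  util <- vapply(metrics, `[[`, numeric(1), "utilization_rate")
  dsr <- vapply(metrics, `[[`, numeric(1), "demand_satisfaction_rate")
  bins <- table(rate_bin(dsr))

  met_by <- vapply(
    catalog$demands$id,
    function(d) sum(vapply(metrics, function(m) d %in% m$met_demands, logical(1))),
    numeric(1)
  )
  dim_cov <- vapply(catalog$dimensions, function(dim) {
    dids <- catalog$demands$id[catalog$demands$dimension == dim]
    mean(vapply(
      metrics,
      function(m) any(dids %in% m$met_demands),
      logical(1)
    ))
  }, numeric(1))

  unmet <- catalog$demands$id[met_by == 0]
  unmet_dims <- catalog$dimensions[vapply(catalog$dimensions, function(dim) {
    dids <- catalog$demands$id[catalog$demands$dimension == dim]
    all(dids %in% unmet)
  }, logical(1))]

  structure(
    list(
      n_apps = length(apps),
      mean_utilization = mean(util),
      mean_demand_satisfaction = mean(dsr),
      mean_utilization_pct = as_percent(mean(util)),
      mean_demand_satisfaction_pct = as_percent(mean(dsr)),
      bin_counts = tibble::tibble(
        bin = RATE_BINS, n = as.integer(bins[RATE_BINS])
      ),
      dimension_coverage = tibble::tibble(
        dimension = catalog$dimensions,
        coverage = unname(dim_cov),
        coverage_pct = as_percent(unname(dim_cov))
      ),
      unmet_demands = unmet,
      unmet_dimensions = unmet_dims
    ),
    class = "useis_cohort_summary"
  )
}

#' @export
print.useis_cohort_summary <- function(x, ...) {
  cat("<cohort availability summary>", x$n_apps, "apps\n")
  cat(sprintf("  mean utilization: %.2f%%  mean demand satisfaction: %.2f%%\n",
              x$mean_utilization_pct, x$mean_demand_satisfaction_pct))
  cat("  demand-satisfaction bins:",
      paste(sprintf("%s:%d", x$bin_counts$bin, x$bin_counts$n), collapse = " "),
      "\n")
  if (length(x$unmet_dimensions) > 0) {
    cat("  unmet dimensions:", paste(x$unmet_dimensions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a cohort summary as JSON (and optional CSV tables)
#'
#' @param summary A `useis_cohort_summary`.
#' @param path Output JSON path.
#' @param csv_dir Optional directory for `bins.csv` and
#'   `dimension_coverage.csv` companions.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summary, path, csv_dir = NULL) {
  jsonlite::write_json(
    list(
      n_apps = summary$n_apps,
      mean_utilization_pct = summary$mean_utilization_pct,
      mean_demand_satisfaction_pct = summary$mean_demand_satisfaction_pct,
      bin_counts = summary$bin_counts,
      dimension_coverage = summary$dimension_coverage,
      unmet_demands = summary$unmet_demands,
      unmet_dimensions = summary$unmet_dimensions
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  if (!is.null(csv_dir)) {
    dir.create(csv_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(summary$bin_counts, file.path(csv_dir, "bins.csv"),
              row.names = FALSE)
    write.csv(summary$dimension_coverage,
              file.path(csv_dir, "dimension_coverage.csv"), row.names = FALSE)
  }
  invisible(path)
}
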
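#' Score a hierarchy: criterion and overall satisfaction
#'
#' Combines importance weights with per-indicator initial satisfaction
#' values (positive-review shares) by linear weighted sum. Criterion
#' satisfaction is the local-weight average of its indicators' satisfaction;
#' overall satisfaction is the global-weight average over all indicators,
#' which by bilinearity equals the criterion-weight average of criterion
#' satisfactions - both routes are computed and asserted to agree.
#'
#' @param hierarchy A `useis_hierarchy`.
#' @param weights A `useis_weights` (from [weight_set()] or
#'   [ahp_weights()]`$weights`), or a `useis_ahp` object.
#' @param satisfaction Named numeric vector (or tibble with columns `topic` /
#'   `indicator` and `positive_share` / `satisfaction`) giving each
#'   indicator's initial satisfaction in `[0, 1]`.
#' @return A list of class `useis_scored` with tibbles `indicators`
#'   (`indicator`, `criterion`, `local_weight`, `global_weight`,
#'   `satisfaction`), `criteria` (`criterion`, `weight`, `satisfaction`),
#'   plus `overall` and `overall_by_criterion`.
#' @export
#' @examples
#' h <- hierarchy_frame("Satisfaction", data.frame(
#'   indicator = c("A1", "A2", "B1"), criterion = c("A", "A", "B")
#' ))
#' w <- weight_set(h, c(A = 0.6, B = 0.4),
#'                 list(A = c(A1 = 0.75, A2 = 0.25), B = c(B1 = 1)))
#' score_hierarchy(h, w, c(A1 = 0.8, A2 = 0.4, B1 = 0.9))
score_hierarchy <- function(hierarchy, weights, satisfaction) {
  hierarchy <- as_hierarchy_frame(hierarchy)
  if (inherits(weights, "useis_ahp")) weights <- weights$weights
  stopifnot(inherits(weights, "useis_weights"))
  satisfaction <- as_satisfaction_vector(satisfaction)

  ind <- weights$indicators
  missing_s <- setdiff(ind$indicator, names(satisfaction))
  if (length(missing_s) > 0) {
    abort(paste0("no satisfaction value for indicator(s): ",
                 paste(missing_s, collapse = ", ")),
          class = "useis_validation_error")
  }
  s <- satisfaction[ind$indicator]
  if (any(s < 0 | s > 1)) {
    abort("satisfaction values must lie in [0, 1]",
          class = "useis_validation_error")
  }

  indicators <- ind |>
    dplyr::mutate(satisfaction = unname(s))
  criteria <- indicators |>
    dplyr::summarise(
      satisfaction = sum(.data$local_weight * .data$satisfaction),
      .by = "criterion"
    ) |>
    dplyr::left_join(weights$criteria, by = "criterion") |>
    dplyr::select("criterion", "weight", "satisfaction") |>
    dplyr::arrange(match(.data$criterion, hierarchy$criteria))

  overall <- sum(indicators$global_weight * indicators$satisfaction)
  overall_by_criterion <- sum(criteria$weight * criteria$satisfaction)
  if (abs(overall - overall_by_criterion) > 1e-12) {
    abort("aggregation identity violated; weights are inconsistent",
          class = "useis_internal_error")
  }
  structure(
    list(
      target = hierarchy$target,
      indicators = indicators,
      criteria = criteria,
      overall = overall,
      overall_by_criterion = overall_by_criterion
    ),
    class = "useis_scored"
  )
}

as_satisfaction_vector <- function(satisfaction) {
  if (is.data.frame(satisfaction)) {
    key <- intersect(c("indicator", "topic"), names(satisfaction))[1]
    val <- intersect(c("satisfaction", "positive_share"), names(satisfaction))[1]
    if (is.na(key) || is.na(val)) {
      abort("satisfaction table needs an indicator/topic and a satisfaction/positive_share column",
            class = "useis_validation_error")
    }
    satisfaction <- setNames(satisfaction[[val]], satisfaction[[key]])
  }
  if (is.null(names(satisfaction))) {
    abort("satisfaction values must be named by indicator",
          class = "useis_validation_error")
  }
  satisfaction
}

#' @export
print.useis_scored <- function(x, ...) {
  cat("<scored hierarchy>", x$target, "\n")
  for (i in seq_len(nrow(x$criteria))) {
    cr <- x$criteria[i, ]
    cat(sprintf("  %s (%.4f)\n", cr$criterion, cr$satisfaction))
    leaves <- x$indicators[x$indicators$criterion == cr$criterion, ]
    for (j in seq_len(nrow(leaves))) {
      cat(sprintf("    %-36s %.4f\n", leaves$indicator[j], leaves$satisfaction[j]))
    }
  }
  cat(sprintf("  overall satisfaction: %.4f\n", x$overall))
  invisible(x)
}

#' Rank indicators by improvement priority
#'
#' Targets improvement effort where importance is high and satisfaction is
#' low: priority = global weight x (1 - satisfaction), ranked descending.
#' Ties break by global weight (heavier first), then indicator label.
#'
#' @param scored A `useis_scored` from [score_hierarchy()].
#' @return A tibble with columns `indicator`, `criterion`, `global_weight`,
#'   `satisfaction`, `priority`, `rank`.
#' @export
improvement_priorities <- function(scored) {
  stopifnot(inherits(scored, "useis_scored"))
  scored$indicators |>
    dplyr::mutate(priority = .data$global_weight * (1 - .data$satisfaction)) |>
    dplyr::arrange(
      dplyr::desc(.data$priority), dplyr::desc(.data$global_weight),
      .data$indicator
    ) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("indicator", "criterion", "global_weight", "satisfaction",
                  "priority", "rank")
}

#' Write scored results as CSV and JSON
#'
#' The CSV mirrors the published table layout: one row per criterion with
#' its satisfaction in parentheses, indicator rows beneath, and an overall
#' satisfaction footer; values at 4 decimal places.
#'
#' @param scored A `useis_scored`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the paths written.
#' @export
write_scored_hierarchy <- function(scored, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(scored, "useis_scored"))
  if (!is.null(csv_path)) {
    rows <- list()
    for (i in seq_len(nrow(scored$criteria))) {
      cr <- scored$criteria[i, ]
      rows[[length(rows) + 1]] <- data.frame(
        layer = sprintf("%s (%.4f)", cr$criterion, cr$satisfaction),
        satisfaction = ""
      )
      leaves <- scored$indicators[scored$indicators$criterion == cr$criterion, ]
      for (j in seq_len(nrow(leaves))) {
        rows[[length(rows) + 1]] <- data.frame(
          layer = paste0("  ", leaves$indicator[j]),
          satisfaction = sprintf("%.4f", leaves$satisfaction[j])
        )
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      layer = "Overall satisfaction",
      satisfaction = sprintf("%.4f", scored$overall)
    )
    write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        target = scored$target,
        indicators = scored$indicators,
        criteria = scored$criteria,
        overall = round(scored$overall, 4)
      ),
      json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  invisible(list(csv = csv_path, json = json_path))
}
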
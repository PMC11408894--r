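#' Define a target / criterion / indicator hierarchy
#'
#' An evaluation indicator system is a three-layer decision hierarchy: a
#' single target (user satisfaction), a criterion layer grouping related
#' factors, and an indicator layer whose leaves correspond to review topics.
#' Every indicator belongs to exactly one criterion and every criterion has
#' at least one indicator.
#'
#' @param target Target-layer label (a single string).
#' @param indicators A data frame with columns `indicator` and `criterion`.
#' @param criteria Optional character vector fixing criterion order; defaults
#'   to order of first appearance in `indicators`.
#'
#' @return A list of class `useis_hierarchy` with elements `target`,
#'   `criteria`, and `indicators` (a tibble).
#' @export
#' @examples
#' hierarchy_frame(
#'   "User satisfaction",
#'   data.frame(
#'     indicator = c("Convenience", "Page design", "Fee"),
#'     criterion = c("Usability", "Usability", "Cost")
#'   )
#' )
hierarchy_frame <- function(target, indicators, criteria = NULL) {
  if (!is.character(target) || length(target) != 1) {
    abort("target must be a single label", class = "useis_validation_error")
  }
  indicators <- tibble::as_tibble(indicators)
  if (!all(c("indicator", "criterion") %in% names(indicators))) {
    abort("indicators need columns 'indicator' and 'criterion'",
          class = "useis_validation_error")
  }
  if (anyDuplicated(indicators$indicator)) {
    abort("indicator labels must be unique (each belongs to one criterion)",
          class = "useis_validation_error")
  }
  if (is.null(criteria)) criteria <- unique(indicators$criterion)
  orphan <- setdiff(indicators$criterion, criteria)
  if (length(orphan) > 0) {
    abort(paste0("criteria not declared: ", paste(orphan, collapse = ", ")),
          class = "useis_validation_error")
  }
  empty <- setdiff(criteria, indicators$criterion)
  if (length(empty) > 0) {
    abort(paste0("criteria without indicators: ", paste(empty, collapse = ", ")),
          class = "useis_validation_error")
  }
  indicators <- indicators[order(match(indicators$criterion, criteria)), ]
  structure(
    list(
      target = target,
      criteria = criteria,
      indicators = indicators[, c("indicator", "criterion")]
    ),
    class = "useis_hierarchy"
  )
}

as_hierarchy_frame <- function(x) {
  if (inherits(x, "useis_hierarchy")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) return(read_hierarchy(x))
  abort("expected a useis_hierarchy or a path to one",
        class = "useis_validation_error")
}

#' Read a hierarchy definition from JSON or YAML
#'
#' The file holds an object with a `target` string and a `criteria` array,
#' each element having a `name` and an `indicators` array of leaf labels.
#'
#' @param path File path (`.json`, `.yaml`, or `.yml`).
#' @return A `useis_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (is.null(spec$target) || is.null(spec$criteria)) {
    abort("hierarchy file needs 'target' and 'criteria' entries",
          class = "useis_validation_error")
  }
  ind <- purrr::map_dfr(spec$criteria, function(cr) {
    tibble::tibble(
      indicator = unlist(cr$indicators),
      criterion = cr$name
    )
  })
  hierarchy_frame(spec$target, ind,
                  criteria = vapply(spec$criteria, `[[`, character(1), "name"))
}

#' Write a hierarchy definition to JSON
#'
#' @param hierarchy A `useis_hierarchy`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, path) {
  hierarchy <- as_hierarchy_frame(hierarchy)
  spec <- list(
    target = hierarchy$target,
    criteria = lapply(hierarchy$criteria, function(cr) {
      list(
        name = cr,
        indicators = hierarchy$indicators$indicator[
          hierarchy$indicators$criterion == cr
        ]
      )
    })
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.useis_hierarchy <- function(x, ...) {
  cat("<evaluation hierarchy> target:", x$target, "\n")
  for (cr in x$criteria) {
    leaves <- x$indicators$indicator[x$indicators$criterion == cr]
    cat("  ", cr, ": ", paste(leaves, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
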
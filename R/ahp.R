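# Analytic hierarchy process driven by review-frequency proportions.
#
# Instead of expert questionnaires, pairwise importance judgments are read
# off the review corpus: the larger the gap between two topics' review
# frequency proportions, the stronger the importance ratio assigned on the
# 1-9 scale. Weights come from the principal eigenvector of each judgment
# matrix, gated by Saaty's consistency ratio.

# Saaty's random index, mean CI of random reciprocal matrices, by order n.
SAATY_RI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Build an importance-scale correspondence table
#'
#' Maps absolute differences of review-frequency proportions onto the 1-9
#' importance scale. With `d_max` the maximum pairwise difference within
#' the comparison set, the default mapping partitions `[0, d_max]` into
#' equal-width steps: `scale = 1 + floor(8 * d / d_max)`, clamped to 9, so
#' a difference of 0 maps to scale 1 (equal importance) and a difference of
#' `d_max` maps to scale 9 (extreme importance). When every proportion is
#' equal the table is degenerate and maps everything to 1.
#'
#' @param proportions Numeric vector of proportions in `[0, 1]`, length >= 2.
#' @return A list of class `useis_scale_table`.
#' @export
#' @examples
#' st <- build_scale_table(c(0.5, 0.3, 0.2))
#' scale_value(st, 0.3) # maximum difference -> 9
build_scale_table <- function(proportions) {
  check_proportions(proportions)
  if (length(proportions) < 2) {
    abort("need at least two proportions to compare",
          class = "useis_validation_error")
  }
  d_max <- max(abs(outer(proportions, proportions, `-`)))
  scale_table(d_max)
}

scale_table <- function(d_max, breaks = NULL, scales = NULL) {
  if (!is.null(breaks)) {
    if (length(breaks) != length(scales) || any(diff(scales) < 0) ||
        any(diff(breaks) <= 0)) {
      abort("scale table bins must be increasing with non-decreasing scales",
            class = "useis_validation_error")
    }
    scales <- as.integer(scales)
  }
  structure(list(d_max = d_max, breaks = breaks, scales = scales),
            class = "useis_scale_table")
}

#' Look up the importance scale for a proportion difference
#'
#' @param table A `useis_scale_table`.
#' @param d Non-negative difference(s) of proportions.
#' @return Integer scale value(s) in 1..9.
#' @export
scale_value <- function(table, d) {
  stopifnot(inherits(table, "useis_scale_table"))
  if (!is.null(table$breaks)) {
    # user-supplied correspondence table: right-closed bin lookup
    return(vapply(d, function(di) {
      if (di <= 0) return(table$scales[1])
      hit <- which(table$breaks >= di - 1e-12)
      if (length(hit) == 0) return(table$scales[length(table$scales)])
      table$scales[min(hit)]
    }, integer(1)))
  }
  if (table$d_max <= 0) return(rep(1L, length(d)))
  pmin(9L, 1L + as.integer(floor(8 * pmax(d, 0) / table$d_max)))
}

#' Read a custom scale table from CSV
#'
#' The file needs columns `upper` (right-closed upper bound of each
#' difference bin, increasing) and `scale` (integer 1..9, non-decreasing),
#' letting users supply their own correspondence table in place of the
#' equal-width default.
#'
#' @param path CSV file path.
#' @return A `useis_scale_table`.
#' @export
read_scale_table <- function(path) {
  df <- read.csv(path)
  if (!all(c("upper", "scale") %in% names(df))) {
    abort("scale table file needs columns 'upper' and 'scale'",
          class = "useis_validation_error")
  }
  df <- df[order(df$upper), ]
  scale_table(max(df$upper), breaks = df$upper, scales = df$scale)
}

check_proportions <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("proportions must be numeric in [0, 1]",
          class = "useis_validation_error")
  }
  invisible(p)
}

#' Build a pairwise-comparison judgment matrix from proportions
#'
#' Entry `(i, j)` is the scale value of `|p_i - p_j|` when `p_i > p_j`, its
#' reciprocal when `p_i < p_j`, and 1 on ties and the diagonal, giving a
#' positive reciprocal matrix with entries in `{1..9}` and reciprocals.
#'
#' @param proportions Numeric vector of proportions, length >= 2.
#' @param scale A `useis_scale_table`; by default rebuilt from `proportions`,
#'   so each comparison set is scaled by its own maximum difference.
#' @return An `n x n` numeric matrix, named after `proportions` if named.
#' @export
#' @examples
#' build_judgment_matrix(c(0.5, 0.3, 0.2))
build_judgment_matrix <- function(proportions, scale = NULL) {
  check_proportions(proportions)
  n <- length(proportions)
  if (n < 2) {
    abort("a judgment matrix needs at least two elements",
          class = "useis_validation_error")
  }
  if (is.null(scale)) scale <- build_scale_table(proportions)
  m <- matrix(1, n, n, dimnames = list(names(proportions), names(proportions)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- scale_value(scale, abs(proportions[i] - proportions[j]))
      if (proportions[i] > proportions[j]) {
        m[i, j] <- s
        m[j, i] <- 1 / s
      } else if (proportions[i] < proportions[j]) {
        m[i, j] <- 1 / s
        m[j, i] <- s
      }
    }
  }
  m
}

validate_reciprocal <- function(m, tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || any(m <= 0)) {
    abort("judgment matrix must be square and positive",
          class = "useis_validation_error")
  }
  if (any(abs(diag(m) - 1) > tol) || any(abs(m * t(m) - 1) > 1e-8)) {
    abort("judgment matrix must be reciprocal with unit diagonal",
          class = "useis_validation_error")
  }
  invisible(m)
}

#' Principal eigenpair of a judgment matrix by power iteration
#'
#' Positive matrices have a simple dominant eigenvalue with a positive
#' eigenvector (Perron-Frobenius), so power iteration converges to the
#' principal eigenpair. The eigenvector is L1-normalised to give the weight
#' vector.
#'
#' @param m A positive reciprocal matrix.
#' @param tol Convergence tolerance on the weight vector (default 1e-12).
#' @param max_iter Iteration cap (default 10000).
#' @return A list with `lambda_max` and `weights` (summing to 1).
#' @export
#' @examples
#' principal_eigenvector(build_judgment_matrix(c(0.5, 0.3, 0.2)))
principal_eigenvector <- function(m, tol = 1e-12, max_iter = 10000) {
  validate_reciprocal(m)
  n <- nrow(m)
  w <- rep(1 / n, n)
  lambda <- n
  for (it in seq_len(max_iter)) {
    v <- drop(m %*% w)
    lambda_new <- sum(v)       # since sum(w) == 1, Rayleigh-type estimate
    w_new <- v / lambda_new
    if (max(abs(w_new - w)) < tol && abs(lambda_new - lambda) < tol * n) {
      w_out <- setNames(w_new, rownames(m))
      return(list(lambda_max = lambda_new, weights = w_out, iterations = it))
    }
    w <- w_new
    lambda <- lambda_new
  }
  abort(
    sprintf("power iteration did not converge in %d iterations (n=%d, last lambda=%.6f)",
            max_iter, n, lambda),
    class = "useis_convergence_error"
  )
}

#' Random index for a matrix order
#'
#' @param n Matrix order.
#' @param ri_table Optional replacement/extension of the standard table,
#'   a numeric vector indexed by order.
#' @return The random index value.
#' @export
saaty_ri <- function(n, ri_table = NULL) {
  tab <- if (is.null(ri_table)) SAATY_RI else ri_table
  if (n > length(tab)) {
    abort(
      sprintf("no random index for n = %d (table covers up to %d); supply ri_table",
              n, length(tab)),
      class = "useis_validation_error"
    )
  }
  if (n < 1) abort("n must be >= 1", class = "useis_validation_error")
  tab[n]
}

#' Consistency test for a judgment matrix
#'
#' Computes the consistency index `CI = (lambda_max - n) / (n - 1)` and the
#' consistency ratio `CR = CI / RI` against the random index for order `n`.
#' A matrix passes when `CR <= 0.1`. Matrices of order 1 or 2 are always
#' consistent by construction (`CR = 0`).
#'
#' @param m A positive reciprocal matrix.
#' @param lambda_max Optional precomputed principal eigenvalue; computed via
#'   [principal_eigenvector()] when missing.
#' @param ri_table Optional random-index table (see [saaty_ri()]).
#' @return A list of class `useis_consistency` with `n`, `lambda_max`, `CI`,
#'   `RI`, `CR`, and `pass`.
#' @export
consistency_check <- function(m, lambda_max = NULL, ri_table = NULL) {
  n <- nrow(m)
  if (is.null(lambda_max)) {
    lambda_max <- if (n >= 2) principal_eigenvector(m)$lambda_max else 1
  }
  if (n <= 2) {
    ci <- 0
    ri <- saaty_ri(max(n, 1), ri_table)
    cr <- 0
  } else {
    ci <- (lambda_max - n) / (n - 1)
    ri <- saaty_ri(n, ri_table)
    cr <- ci / ri
  }
  structure(
    list(n = n, lambda_max = lambda_max, CI = ci, RI = ri, CR = cr,
         pass = cr <= 0.1),
    class = "useis_consistency"
  )
}

#' @export
print.useis_consistency <- function(x, ...) {
  cat(sprintf(
    "<consistency> n=%d lambda_max=%.6f CI=%.6f RI=%.2f CR=%.6f [%s]\n",
    x$n, x$lambda_max, x$CI, x$RI, x$CR, if (x$pass) "pass" else "FAIL"
  ))
  invisible(x)
}

#' Explicit weight set for a hierarchy
#'
#' Bundles criterion weights and per-criterion local indicator weights into
#' the object [score_hierarchy()] consumes, computing the comprehensive
#' (global) indicator weights `W_criterion * w_indicator`. Use this to score
#' with externally supplied weights; [ahp_weights()] produces the same
#' structure from review proportions.
#'
#' @param hierarchy A `useis_hierarchy`.
#' @param criterion_weights Named numeric vector over the criteria, summing
#'   to 1.
#' @param local_weights Named list: per criterion, a named numeric vector of
#'   indicator weights summing to 1.
#' @return A list of class `useis_weights` with tibbles `criteria`
#'   (`criterion`, `weight`) and `indicators` (`indicator`, `criterion`,
#'   `local_weight`, `global_weight`).
#' @export
weight_set <- function(hierarchy, criterion_weights, local_weights) {
  hierarchy <- as_hierarchy_frame(hierarchy)
  if (!setequal(names(criterion_weights), hierarchy$criteria)) {
    abort("criterion_weights must be named by the hierarchy criteria",
          class = "useis_validation_error")
  }
  if (abs(sum(criterion_weights) - 1) > 1e-9) {
    abort("criterion weights must sum to 1", class = "useis_validation_error")
  }
  ind <- hierarchy$indicators
  local <- numeric(nrow(ind))
  for (cr in hierarchy$criteria) {
    leaves <- ind$indicator[ind$criterion == cr]
    lw <- local_weights[[cr]]
    if (is.null(lw) || !setequal(names(lw), leaves)) {
      abort(paste0("local weights for criterion '", cr,
                   "' must be named by its indicators"),
            class = "useis_validation_error")
    }
    if (abs(sum(lw) - 1) > 1e-9) {
      abort(paste0("local weights for criterion '", cr, "' must sum to 1"),
            class = "useis_validation_error")
    }
    local[ind$criterion == cr] <- lw[leaves]
  }
  structure(
    list(
      criteria = tibble::tibble(
        criterion = hierarchy$criteria,
        weight = unname(criterion_weights[hierarchy$criteria])
      ),
      indicators = tibble::tibble(
        indicator = ind$indicator,
        criterion = ind$criterion,
        local_weight = local,
        global_weight = local *
          unname(criterion_weights[ind$criterion])
      )
    ),
    class = "useis_weights"
  )
}

#' Synthesise comprehensive weights and combined consistency
#'
#' Performs the hierarchical total ranking: every indicator's comprehensive
#' (global) weight is its criterion weight times its local weight, and the
#' combined consistency ratio pools the single-level tests as
#' `sum(W_c * CI_c) / sum(W_c * RI_c)` over the indicator blocks. Synthesis
#' refuses to run if any single-level consistency test failed, naming the
#' offending matrix.
#'
#' @param hierarchy A `useis_hierarchy`.
#' @param criterion_weights Named numeric vector over criteria.
#' @param local_weights Named list of per-criterion indicator weight vectors.
#' @param reports Named list of `useis_consistency` reports: one entry
#'   `"criteria"` for the criterion-level matrix plus one per criterion.
#' @return A list: `weights` (a `useis_weights`), `combined` (a list with
#'   `CR` and `pass`).
#' @export
synthesize_weights <- function(hierarchy, criterion_weights, local_weights,
                               reports) {
  failed <- names(reports)[!vapply(reports, `[[`, logical(1), "pass")]
  if (length(failed) > 0) {
    abort(
      paste0("cannot synthesise weights: consistency failed for ",
             paste(failed, collapse = ", ")),
      class = "useis_consistency_error"
    )
  }
  hierarchy <- as_hierarchy_frame(hierarchy)
  ws <- weight_set(hierarchy, criterion_weights, local_weights)
  wc <- setNames(ws$criteria$weight, ws$criteria$criterion)
  block <- reports[hierarchy$criteria]
  ci_sum <- sum(wc * vapply(block, `[[`, numeric(1), "CI"))
  ri_sum <- sum(wc * vapply(block, `[[`, numeric(1), "RI"))
  combined_cr <- if (ri_sum > 0) ci_sum / ri_sum else 0
  list(
    weights = ws,
    combined = list(CR = combined_cr, pass = combined_cr <= 0.1)
  )
}

#' Derive hierarchy weights from review proportions
#'
#' Runs the full proportion-driven weighting pass: per comparison set (the
#' criterion layer, then the indicators inside each criterion) it builds an
#' importance-scale table from that set's maximum proportion difference,
#' constructs the judgment matrix, extracts the principal eigenvector as the
#' local weight vector, and runs the consistency test. Single-indicator
#' criteria get local weight 1 and a trivially consistent report. Finally it
#' synthesises comprehensive weights and the combined consistency ratio.
#'
#' @param hierarchy A `useis_hierarchy`.
#' @param proportions Either the output of [topic_proportions()] or a named
#'   numeric vector of per-indicator proportions.
#' @param scale Optional `useis_scale_table` applied to every comparison set
#'   instead of the per-set default.
#' @param ri_table Optional random-index table.
#' @param tol,max_iter Passed to [principal_eigenvector()].
#' @return A list of class `useis_ahp` with elements `weights`
#'   (`useis_weights`), `consistency` (tibble of per-matrix reports),
#'   `combined` (combined CR and pass flag), `matrices` (the judgment
#'   matrices), and `proportions`.
#' @export
#' @examples
#' h <- hierarchy_frame("Satisfaction", data.frame(
#'   indicator = c("A1", "A2", "B1", "B2"),
#'   criterion = c("A", "A", "B", "B")
#' ))
#' p <- c(A1 = 0.4, A2 = 0.3, B1 = 0.2, B2 = 0.1)
#' fit <- ahp_weights(h, p)
#' fit$weights$indicators
ahp_weights <- function(hierarchy, proportions, scale = NULL, ri_table = NULL,
                        tol = 1e-12, max_iter = 10000) {
  hierarchy <- as_hierarchy_frame(hierarchy)
  if (is.data.frame(proportions)) {
    proportions <- setNames(proportions$proportion, proportions$topic)
  }
  ind <- hierarchy$indicators
  missing_p <- setdiff(ind$indicator, names(proportions))
  if (length(missing_p) > 0) {
    abort(paste0("no proportion for indicator(s): ",
                 paste(missing_p, collapse = ", ")),
          class = "useis_validation_error")
  }
  p_ind <- proportions[ind$indicator]
  p_crit <- vapply(
    hierarchy$criteria,
    function(cr) sum(p_ind[ind$criterion == cr]),
    numeric(1)
  )

  solve_set <- function(p, label) {
    if (length(p) == 1) {
      return(list(
        weights = setNames(1, names(p)), matrix = NULL,
        report = structure(
          list(n = 1L, lambda_max = 1, CI = 0, RI = 0, CR = 0, pass = TRUE),
          class = "useis_consistency"
        )
      ))
    }
    m <- build_judgment_matrix(p, scale = scale)
    eig <- principal_eigenvector(m, tol = tol, max_iter = max_iter)
    rep <- consistency_check(m, lambda_max = eig$lambda_max, ri_table = ri_table)
    list(weights = eig$weights, matrix = m, report = rep)
  }

  crit_fit <- solve_set(p_crit, "criteria")
  block_fits <- lapply(hierarchy$criteria, function(cr) {
    solve_set(p_ind[ind$criterion == cr], cr)
  })
  names(block_fits) <- hierarchy$criteria

  reports <- c(list(criteria = crit_fit$report),
               lapply(block_fits, `[[`, "report"))
  synth <- synthesize_weights(
    hierarchy,
    criterion_weights = crit_fit$weights,
    local_weights = lapply(block_fits, `[[`, "weights"),
    reports = reports
  )

  consistency <- purrr::imap_dfr(reports, function(r, nm) {
    tibble::tibble(
      set = nm, n = r$n, lambda_max = r$lambda_max,
      CI = r$CI, RI = r$RI, CR = r$CR, pass = r$pass
    )
  })
  structure(
    list(
      weights = synth$weights,
      consistency = consistency,
      combined = synth$combined,
      matrices = c(list(criteria = crit_fit$matrix),
                   lapply(block_fits, `[[`, "matrix")),
      proportions = list(indicator = p_ind, criterion = p_crit)
    ),
    class = "useis_ahp"
  )
}

#' @export
print.useis_ahp <- function(x, ...) {
  cat("<proportion-driven AHP weights>\n")
  print(x$weights$indicators)
  cat(sprintf("max single-level CR: %.4f; combined CR: %.4f [%s]\n",
              max(x$consistency$CR), x$combined$CR,
              if (all(x$consistency$pass) && x$combined$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Round-trip a judgment matrix through CSV
#'
#' @param m A judgment matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_judgment_matrix <- function(m, path) {
  validate_reciprocal(m)
  df <- as.data.frame(m)
  write.csv(df, path, row.names = !is.null(rownames(m)))
  invisible(path)
}

#' @rdname write_judgment_matrix
#' @export
read_judgment_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!is.numeric(df[[1]])) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  } else {
    m <- as.matrix(df)
    rownames(m) <- colnames(m)
  }
  validate_reciprocal(m)
  m
}
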
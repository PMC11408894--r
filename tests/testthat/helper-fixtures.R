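# Shared in-code fixtures: a tiny handmade corpus, incidence matrices, and
# a random reciprocal-matrix generator.

make_corpus <- function(rating, polarity = rep("positive", length(rating)),
                        topic = rep("A", length(rating)),
                        market = rep("US", length(rating)),
                        text = sprintf("nice little review %d", seq_along(rating)),
                        app_id = rep("app01", length(rating)),
                        author_id = sprintf("user%03d", seq_along(rating))) {
  n <- length(rating)
  review_corpus(tibble::tibble(
    review_id = sprintf("r%03d", seq_len(n)),
    app_id = app_id,
    market = market,
    rating = as.integer(rating),
    text = text,
    author_id = author_id,
    timestamp = format(
      as.POSIXct("2023-04-01", tz = "UTC") + seq_len(n), "%Y-%m-%dT%H:%M:%SZ"
    ),
    topic = topic,
    polarity = polarity
  ))
}

tiny_catalog <- function(n_demands = 10, n_dimensions = 2) {
  demand_catalog(tibble::tibble(
    id = sprintf("d%02d", seq_len(n_demands)),
    label = sprintf("demand %d", seq_len(n_demands)),
    dimension = sprintf("dim%d", rep_len(seq_len(n_dimensions), n_demands))
  ))
}

make_fit <- function(incidence, catalog, app_id = "app01") {
  colnames(incidence) <- catalog$demands$id
  fit_matrix(app_id, incidence, catalog)
}

# random positive reciprocal matrix with Saaty-scale entries
random_reciprocal <- function(n) {
  m <- diag(n)
  vals <- c(1:9, 1 / (2:9))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- sample(vals, 1)
      m[j, i] <- 1 / m[i, j]
    }
  }
  m
}

cohort_summary_from_spec <- function(spec) {
  apps <- simulate_fit_matrices(spec)
  cohort_summary(apps, attr(apps, "catalog"))
}

# brute-force availability oracle: plain loops over rows/columns
brute_force_rates <- function(incidence) {
  n_fun <- nrow(incidence)
  n_dem <- ncol(incidence)
  fun_used <- 0
  for (i in seq_len(n_fun)) {
    hit <- FALSE
    for (j in seq_len(n_dem)) if (incidence[i, j] == 1) hit <- TRUE
    if (hit) fun_used <- fun_used + 1
  }
  dem_met <- 0
  for (j in seq_len(n_dem)) {
    hit <- FALSE
    for (i in seq_len(n_fun)) if (incidence[i, j] == 1) hit <- TRUE
    if (hit) dem_met <- dem_met + 1
  }
  c(utilization = fun_used / n_fun, satisfaction = dem_met / n_dem)
}
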
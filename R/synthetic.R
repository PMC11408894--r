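# Seedable synthetic inputs. The generators emulate the statistical
# structure the analysis assumes - per-topic review-frequency proportions,
# per-topic positive shares, rating/sentiment concordance, realistic
# contamination, and function-demand incidence with a controllable
# fulfillment rate - so every stage is testable without any scraped data.

#' Specify a synthetic review corpus
#'
#' @param market `"US"` or `"CN"`.
#' @param n_reviews Number of reviews to draw.
#' @param topics A data frame with columns `topic`, `proportion` (summing to
#'   1), and `positive_share` (per-topic probability that a review is
#'   positive); an optional `criterion` column is carried along.
#' @param contamination Named list of injection rates in `[0, 1]` for
#'   `duplicate`, `blank`, `garbled`, `ad`, `bot`, and `polarity_mismatch`
#'   records; unnamed kinds default to 0.
#' @param rating_model List with `p5` (chance a positive review gets 5 stars
#'   rather than 4), `p1` (chance a negative review gets 1 star rather than
#'   2), and `p3` (mass on the ambiguous 3-star rating). Only the
#'   concordance of rating and polarity matters downstream, so these only
#'   shape the marginal rating distribution.
#' @param n_apps,n_authors Pool sizes for app and author identifiers.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return A list of class `useis_corpus_spec`.
#' @export
corpus_spec <- function(market, n_reviews, topics,
                        contamination = list(),
                        rating_model = list(p5 = 0.7, p1 = 0.6, p3 = 0),
                        n_apps = 10, n_authors = max(50, n_reviews %/% 20),
                        seed = 1) {
  topics <- tibble::as_tibble(topics)
  if (!all(c("topic", "proportion", "positive_share") %in% names(topics))) {
    abort("topics need columns 'topic', 'proportion', 'positive_share'",
          class = "useis_validation_error")
  }
  if (abs(sum(topics$proportion) - 1) > 1e-9) {
    abort("topic proportions must sum to 1", class = "useis_validation_error")
  }
  if (any(topics$positive_share < 0 | topics$positive_share > 1)) {
    abort("positive shares must lie in [0, 1]", class = "useis_validation_error")
  }
  kinds <- c("duplicate", "blank", "garbled", "ad", "bot", "polarity_mismatch")
  rates <- setNames(rep(0, length(kinds)), kinds)
  extra <- setdiff(names(contamination), kinds)
  if (length(extra) > 0) {
    abort(paste0("unknown contamination kind(s): ", paste(extra, collapse = ", ")),
          class = "useis_validation_error")
  }
  rates[names(contamination)] <- unlist(contamination)
  if (any(rates < 0 | rates > 1) || sum(rates) >= 1) {
    abort("contamination rates must lie in [0, 1] and sum below 1",
          class = "useis_validation_error")
  }
  if (!market %in% c("US", "CN")) {
    abort("market must be 'US' or 'CN'", class = "useis_validation_error")
  }
  rm_def <- list(p5 = 0.7, p1 = 0.6, p3 = 0)
  rating_model <- modifyList(rm_def, rating_model)
  structure(
    list(market = market, n_reviews = as.integer(n_reviews), topics = topics,
         contamination = as.list(rates), rating_model = rating_model,
         n_apps = n_apps, n_authors = n_authors, seed = as.integer(seed)),
    class = "useis_corpus_spec"
  )
}

#' Simulate a labeled review corpus
#'
#' Draws each review's topic from the spec's proportion vector, its polarity
#' from the topic's positive share, and a concordant star rating (positive
#' reviews get 4-5 stars, negative 1-2, with optional 3-star mass). Each
#' review is independently designated clean or one of the contamination
#' kinds at the spec rates: duplicates copy an earlier clean review's app,
#' author, and text; blank, garbled, and advertisement-like reviews get the
#' corresponding text defects; bot reviews get `bot:`-prefixed author ids
#' (flag them with [flag_bot_authors()]); polarity-mismatch reviews get a
#' star rating contradicting their polarity. Review text is a tagged
#' placeholder in the market's script, not natural language.
#'
#' @param spec A [corpus_spec()].
#' @return A `useis_corpus` tibble; byte-identical for identical specs.
#' @export
simulate_reviews <- function(spec) {
  stopifnot(inherits(spec, "useis_corpus_spec"))
  n <- spec$n_reviews
  withr::with_seed(spec$seed, {
    rates <- unlist(spec$contamination)
    kind <- sample(
      c("clean", names(rates)), n, replace = TRUE,
      prob = c(1 - sum(rates), unname(rates))
    )
    topic_i <- sample.int(nrow(spec$topics), n, replace = TRUE,
                          prob = spec$topics$proportion)
    topic <- spec$topics$topic[topic_i]
    share <- spec$topics$positive_share[topic_i]
    positive <- rbinom(n, 1, share) == 1
    polarity <- ifelse(positive, "positive", "negative")

    rm <- spec$rating_model
    u3 <- stats::runif(n)
    hi <- ifelse(rbinom(n, 1, rm$p5) == 1, 5L, 4L)
    lo <- ifelse(rbinom(n, 1, rm$p1) == 1, 1L, 2L)
    rating <- ifelse(u3 < rm$p3, 3L, ifelse(positive, hi, lo))

    app_id <- sprintf("app%02d", sample.int(spec$n_apps, n, replace = TRUE))
    author_id <- sprintf("user%05d", sample.int(spec$n_authors, n, replace = TRUE))
    idx <- seq_len(n)
    text <- if (spec$market == "CN") {
      sprintf("关于%s的评论第%d条", topic, idx)
    } else {
      sprintf("review about %s item %d", topic, idx)
    }

    # contamination overlays (clean rows are never touched)
    is_dup <- kind == "duplicate"
    clean_idx <- which(kind == "clean")
    if (any(is_dup) && length(clean_idx) > 0) {
      src <- clean_idx[sample.int(length(clean_idx), sum(is_dup), replace = TRUE)]
      app_id[is_dup] <- app_id[src]
      author_id[is_dup] <- author_id[src]
      text[is_dup] <- text[src]
      topic[is_dup] <- topic[src]
      polarity[is_dup] <- polarity[src]
      rating[is_dup] <- rating[src]
    }
    text[kind == "blank"] <- ""
    text[kind == "garbled"] <- "@#$%!! ~~ ***"
    ad_i <- which(kind == "ad")
    text[ad_i] <- if (spec$market == "CN") {
      sprintf("优惠码 promo code %d", ad_i)
    } else {
      sprintf("use promo code %d for a discount", ad_i)
    }
    bot_i <- which(kind == "bot")
    author_id[bot_i] <- sprintf("bot:%05d", bot_i)
    mm <- kind == "polarity_mismatch"
    rating[mm] <- ifelse(polarity[mm] == "positive", 1L, 5L)

    review_corpus(tibble::tibble(
      review_id = sprintf("r%07d", idx),
      app_id = app_id,
      market = spec$market,
      rating = as.integer(rating),
      text = text,
      author_id = author_id,
      timestamp = format(
        as.POSIXct("2023-04-01 00:00:00", tz = "UTC") + idx,
        "%Y-%m-%dT%H:%M:%SZ"
      ),
      topic = topic,
      polarity = polarity
    ))
  })
}

#' Bot-author predicate for synthetic corpora
#'
#' Flags the `bot:`-prefixed author ids [simulate_reviews()] assigns to its
#' injected bot reviews; pass it to [apply_filters()] as `bot_predicate`.
#' Real corpora need an external bot-detection model in its place.
#'
#' @param corpus A `useis_corpus`.
#' @return Logical vector.
#' @export
flag_bot_authors <- function(corpus) {
  grepl("^bot:", corpus$author_id)
}

#' Specify a synthetic app cohort
#'
#' @param n_apps Number of apps.
#' @param target_rate Probability that any given demand is met by an app;
#'   the cohort mean demand-satisfaction rate concentrates on this value.
#' @param catalog Optional `useis_demand_catalog`; generated when `NULL`.
#' @param n_demands,n_dimensions Catalog shape when generating one.
#' @param functions_range Inclusive range for the number of candidate
#'   functions per app; each met demand is attached to one of them.
#' @param allow_dead_functions Keep candidate functions that ended up
#'   covering no demand (all-zero rows). The default drops them, so every
#'   generated function meets at least one demand and the functional
#'   utilization rate is 1, matching how real app functions are catalogued
#'   from what apps actually do.
#' @param seed Integer seed.
#' @return A list of class `useis_cohort_spec`.
#' @export
cohort_spec <- function(n_apps, target_rate, catalog = NULL,
                        n_demands = 55, n_dimensions = 10,
                        functions_range = c(3, 8),
                        allow_dead_functions = FALSE, seed = 1) {
  if (target_rate < 0 || target_rate > 1) {
    abort("target_rate must lie in [0, 1]", class = "useis_validation_error")
  }
  if (n_apps < 1) abort("need at least one app", class = "useis_validation_error")
  if (is.null(catalog)) {
    catalog <- demand_catalog(tibble::tibble(
      id = sprintf("d%02d", seq_len(n_demands)),
      label = sprintf("demand %02d", seq_len(n_demands)),
      dimension = sprintf("dim%02d", rep_len(seq_len(n_dimensions), n_demands))
    ))
  }
  structure(
    list(n_apps = as.integer(n_apps), target_rate = target_rate,
         catalog = catalog, functions_range = functions_range,
         allow_dead_functions = allow_dead_functions, seed = as.integer(seed)),
    class = "useis_cohort_spec"
  )
}

#' Simulate an app cohort's function-demand incidence matrices
#'
#' Each catalog demand is met by each app independently with probability
#' `target_rate`; met demands are distributed over a random number of
#' functions, so one function may serve several demands.
#'
#' @param spec A [cohort_spec()].
#' @return A list of `useis_fit_matrix` objects (one per app) with the
#'   shared catalog attached as attribute `catalog`.
#' @export
simulate_fit_matrices <- function(spec) {
  stopifnot(inherits(spec, "useis_cohort_spec"))
  catalog <- spec$catalog
  n_dem <- nrow(catalog$demands)
  apps <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_apps), function(a) {
      met <- rbinom(n_dem, 1, spec$target_rate) == 1
      n_fun <- sample(spec$functions_range[1]:spec$functions_range[2], 1)
      inc <- matrix(
        0L, nrow = n_fun, ncol = n_dem,
        dimnames = list(sprintf("f%02d", seq_len(n_fun)), catalog$demands$id)
      )
      if (any(met)) {
        assignee <- sample.int(n_fun, sum(met), replace = TRUE)
        inc[cbind(assignee, which(met))] <- 1L
      }
      if (!spec$allow_dead_functions) {
        inc <- inc[rowSums(inc) > 0, , drop = FALSE]
      }
      fit_matrix(sprintf("app%03d", a), inc, catalog)
    })
  })
  attr(apps, "catalog") <- catalog
  apps
}

#' Default synthetic evaluation scenario
#'
#' A fixed single-market scenario used throughout examples and end-to-end
#' checks: six criteria with review proportions 0.45, 0.20, 0.12, 0.10,
#' 0.08, 0.05 and two to three indicator topics each, with per-topic
#' positive shares spanning the satisfied-to-dissatisfied range observed in
#' app-store data, plus moderate contamination of every kind.
#'
#' @param n_reviews Corpus size (default 50000).
#' @param seed Integer seed.
#' @param contamination Contamination rates; set to `list()` zeros for a
#'   clean corpus.
#' @return A list with `hierarchy` (a `useis_hierarchy`), `topics` (the
#'   topic table with proportions and shares), and `spec` (a
#'   [corpus_spec()] ready for [simulate_reviews()]).
#' @export
default_scenario <- function(n_reviews = 50000, seed = 1,
                             contamination = list(
                               duplicate = 0.03, blank = 0.01, garbled = 0.01,
                               ad = 0.01, bot = 0.02, polarity_mismatch = 0.02
                             )) {
  topics <- tibble::tribble(
    ~topic,                                ~criterion,            ~proportion, ~positive_share,
    "Convenience",                         "Usability",           0.25,        0.79,
    "Page design",                         "Usability",           0.12,        0.86,
    "Advertising distribution",            "Usability",           0.08,        0.21,
    "Blood pressure tracking",             "Monitoring function", 0.12,        0.83,
    "Heart rate monitoring",               "Monitoring function", 0.08,        0.59,
    "Reliability",                         "Availability",        0.07,        0.30,
    "Compatibility",                       "Availability",        0.03,        0.43,
    "Stability",                           "Availability",        0.02,        0.52,
    "Measurement accuracy",                "Monitoring effect",   0.06,        0.77,
    "Effect of blood pressure management", "Monitoring effect",   0.04,        0.87,
    "Data synchronization",                "Data management",     0.05,        0.21,
    "Data sharing",                        "Data management",     0.03,        0.52,
    "Fee",                                 "Cost",                0.03,        0.43,
    "Subscription",                        "Cost",                0.02,        0.81
  )
  hierarchy <- hierarchy_frame(
    "User satisfaction",
    topics[, c("topic", "criterion")] |> dplyr::rename(indicator = "topic")
  )
  list(
    hierarchy = hierarchy,
    topics = topics,
    spec = corpus_spec("US", n_reviews, topics,
                       contamination = contamination, seed = seed)
  )
}
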
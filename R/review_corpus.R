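#' Construct a validated review corpus
#'
#' A review corpus is a tibble with one row per app-store review, carrying
#' the star rating, market, free-text body, and (after upstream topic
#' modelling and sentiment classification) a topic label and a binary
#' sentiment polarity. `review_corpus()` validates a data frame against this
#' contract and returns it as a classed tibble; all downstream cleaning and
#' summarisation functions expect this class.
#'
#' @param x A data frame with columns `review_id`, `app_id`, `market`
#'   (`"US"` or `"CN"`), `rating` (integer 1-5), `text`, `author_id`,
#'   `timestamp` (ISO-8601 string), `topic` (character, may be `NA`), and
#'   `polarity` (`"positive"`, `"negative"`, or `NA`).
#'
#' @return A tibble of class `useis_corpus`.
#' @export
#' @examples
#' review_corpus(data.frame(
#'   review_id = "r1", app_id = "a1", market = "US", rating = 5L,
#'   text = "works great", author_id = "u1",
#'   timestamp = "2023-04-01T00:00:00Z", topic = "Convenience",
#'   polarity = "positive"
#' ))
review_corpus <- function(x) {
  required <- c(
    "review_id", "app_id", "market", "rating", "text", "author_id",
    "timestamp", "topic", "polarity"
  )
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0("corpus is missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "useis_validation_error"
    )
  }
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) {
    abort("corpus has zero reviews", class = "useis_empty_input_error")
  }
  bad_market <- setdiff(unique(x$market), c("US", "CN"))
  if (length(bad_market) > 0) {
    abort(
      paste0("unknown market value(s): ", paste(bad_market, collapse = ", ")),
      class = "useis_validation_error"
    )
  }
  x$rating <- as.integer(x$rating)
  if (anyNA(x$rating) || !all(x$rating %in% 1:5)) {
    abort("rating must be an integer in 1..5", class = "useis_validation_error")
  }
  bad_pol <- setdiff(unique(x$polarity[!is.na(x$polarity)]), c("positive", "negative"))
  if (length(bad_pol) > 0) {
    abort(
      paste0("polarity must be 'positive' or 'negative', got: ",
             paste(bad_pol, collapse = ", ")),
      class = "useis_validation_error"
    )
  }
  x$text <- as.character(x$text)
  x$text[is.na(x$text)] <- ""
  class(x) <- c("useis_corpus", class(tibble::tibble()))
  x
}

#' Read a review corpus from CSV or JSON-lines
#'
#' @param path File path. CSV files need the standard header
#'   (`review_id,app_id,market,rating,text,author_id,timestamp,topic,polarity`);
#'   JSON-lines files need one review object per line with the same fields.
#' @param format `"csv"` or `"jsonl"`; guessed from the file extension by
#'   default.
#'
#' @return A `useis_corpus` tibble.
#' @export
read_reviews <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  df <- switch(format,
    csv = read.csv(path, colClasses = "character", na.strings = character(0),
                   fileEncoding = "UTF-8", check.names = FALSE),
    jsonl = {
      lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      purrr::map_dfr(lines, function(l) {
        rec <- jsonlite::fromJSON(l)
        rec[vapply(rec, is.null, logical(1))] <- NA
        tibble::as_tibble(rec)
      })
    }
  )
  for (col in c("topic", "polarity")) {
    if (col %in% names(df)) df[[col]][df[[col]] %in% c("", "NA")] <- NA_character_
  }
  review_corpus(df)
}

#' Filtering configuration for review preprocessing
#'
#' Controls the rule-based cleaning pass over a raw labeled corpus. Defaults
#' reflect bilingual (US/China) app-store review data: Latin script is the
#' target for the US market and Han script for the Chinese market.
#'
#' @param languages Named character vector mapping each market to a regex
#'   character class for its target script.
#' @param min_informative_chars Minimum number of letter characters (any
#'   script) a review must contain to not be considered garbled.
#' @param ad_keywords Character vector of advertisement marker patterns
#'   (matched case-insensitively as fixed substrings).
#'
#' @return A list of class `useis_filter_config`.
#' @export
filter_config <- function(languages = c(US = "[A-Za-z]", CN = "[\\x{4E00}-\\x{9FFF}]"),
                          min_informative_chars = 2,
                          ad_keywords = c("promo code", "coupon code", "click here to download",
                                          "limited time offer")) {
  stopifnot(is.character(languages), !is.null(names(languages)))
  structure(
    list(
      languages = languages,
      min_informative_chars = min_informative_chars,
      ad_keywords = ad_keywords
    ),
    class = "useis_filter_config"
  )
}

count_chars <- function(text, class_regex) {
  vapply(
    text,
    function(t) {
      m <- gregexpr(class_regex, t, perl = TRUE)[[1]]
      if (m[1] == -1L) 0L else length(m)
    },
    integer(1),
    USE.NAMES = FALSE
  )
}

# Duplicate key: same app, same author, same whitespace-normalised
# case-folded text. Narrower keys would delete legitimate repeats of a
# common phrase across apps or users.
duplicate_key <- function(corpus) {
  norm <- tolower(gsub("\\s+", " ", trimws(corpus$text)))
  paste(corpus$app_id, corpus$author_id, norm, sep = "\r")
}

#' Detect rating / sentiment-polarity mismatch
#'
#' A review is polarity-mismatched when its star rating and its classified
#' sentiment disagree: 4-5 stars with negative polarity, or 1-2 stars with
#' positive polarity. A 3-star rating is ambiguous and never counts as a
#' mismatch.
#'
#' @param rating Integer vector of star ratings in 1..5.
#' @param polarity Character vector, `"positive"` or `"negative"`; `NA` is an
#'   error (unlabeled reviews cannot be checked).
#'
#' @return Logical vector.
#' @export
#' @examples
#' polarity_mismatch(c(5, 1, 3), c("negative", "positive", "negative"))
polarity_mismatch <- function(rating, polarity) {
  if (anyNA(polarity)) {
    abort("polarity_mismatch() requires non-missing polarity labels",
          class = "useis_validation_error")
  }
  rating <- as.integer(rating)
  (rating >= 4L & polarity == "negative") | (rating <= 2L & polarity == "positive")
}

#' Clean a review corpus
#'
#' Applies the rule-based preprocessing pass in a fixed, deterministic order:
#' bot accounts (via the injected predicate), blank reviews, garbled text,
#' non-target-language text, advertisement-like reviews, duplicates, and
#' finally reviews whose rating contradicts their sentiment polarity. Each
#' removed review is attributed to exactly one reason (the first matching
#' stage), so the per-reason counts plus the retained count always add back
#' to the input size. The pass is idempotent: re-filtering its own output
#' removes nothing.
#'
#' @param corpus A `useis_corpus` (or coercible data frame).
#' @param config A [filter_config()].
#' @param bot_predicate Optional function taking the corpus tibble and
#'   returning a logical vector flagging bot-authored reviews. The default
#'   flags nothing (bot detection is an external concern, injected here).
#'
#' @return A list with elements `corpus` (the retained reviews, a
#'   `useis_corpus`) and `report` (a `useis_filter_report` with per-reason
#'   removal counts).
#' @export
apply_filters <- function(corpus, config = filter_config(), bot_predicate = NULL) {
  corpus <- review_corpus(corpus)
  n_input <- nrow(corpus)
  reason <- rep(NA_character_, n_input)
  alive <- function() is.na(reason)

  mark <- function(flag, why) {
    flag <- flag & alive()
    reason[flag] <<- why
  }

  if (!is.null(bot_predicate)) {
    mark(as.logical(bot_predicate(corpus)), "bot")
  }
  mark(!nzchar(trimws(corpus$text)), "blank")

  informative <- count_chars(corpus$text, "[\\p{L}]")
  mark(informative < config$min_informative_chars, "garbled")

  lang_class <- config$languages[corpus$market]
  if (anyNA(lang_class)) {
    abort("filter config lacks a language class for some market",
          class = "useis_validation_error")
  }
  target_chars <- mapply(
    function(t, cls) count_chars(t, cls),
    corpus$text, lang_class, USE.NAMES = FALSE
  )
  mark(target_chars < config$min_informative_chars, "non_target_language")

  if (length(config$ad_keywords) > 0) {
    ad_hit <- Reduce(
      `|`,
      lapply(config$ad_keywords,
             function(k) grepl(k, corpus$text, ignore.case = TRUE, fixed = FALSE))
    )
    mark(ad_hit, "advertisement")
  }

  key <- duplicate_key(corpus)
  key[!alive()] <- NA  # already-removed rows do not shadow survivors
  mark(duplicated(key, incomparables = NA), "duplicate")

  can_check <- alive() & !is.na(corpus$polarity)
  mismatch <- rep(FALSE, n_input)
  mismatch[can_check] <- polarity_mismatch(
    corpus$rating[can_check], corpus$polarity[can_check]
  )
  mark(mismatch, "polarity_mismatch")

  reasons <- c("bot", "blank", "garbled", "non_target_language",
               "advertisement", "duplicate", "polarity_mismatch")
  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE), integer(1))
  report <- structure(
    list(input = n_input, retained = sum(alive()), removed = as.list(counts)),
    class = "useis_filter_report"
  )
  clean <- corpus[alive(), , drop = FALSE]
  if (nrow(clean) == 0) {
    abort("filtering removed every review", class = "useis_empty_input_error")
  }
  class(clean) <- class(corpus)
  list(corpus = clean, report = report)
}

#' @export
print.useis_filter_report <- function(x, ...) {
  cat("<review filter report>\n")
  cat("  input:   ", x$input, "\n", sep = "")
  cat("  retained:", x$retained, "\n")
  for (r in names(x$removed)) {
    if (x$removed[[r]] > 0) cat(sprintf("  removed %-20s %d\n", paste0(r, ":"), x$removed[[r]]))
  }
  invisible(x)
}

#' Write a filter report as JSON
#'
#' @param report A `useis_filter_report` from [apply_filters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Per-topic review-frequency proportions
#'
#' The share of a market's cleaned reviews that fall under each topic. These
#' frequency proportions are the objective basis for pairwise importance
#' comparisons in the hierarchy-weighting stage: a topic users mention more
#' often is treated as more important to them.
#'
#' @param corpus A cleaned `useis_corpus`.
#' @param market Market to summarise (`"US"` or `"CN"`).
#'
#' @return A tibble with columns `market`, `topic`, `n`, `proportion`;
#'   proportions sum to 1 within the market.
#' @export
topic_proportions <- function(corpus, market) {
  corpus <- review_corpus(corpus)
  if (!market %in% c("US", "CN")) {
    abort(paste0("unknown market: ", market), class = "useis_validation_error")
  }
  sub <- corpus[corpus$market == market, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(paste0("no reviews for market ", market),
          class = "useis_empty_input_error")
  }
  if (anyNA(sub$topic)) {
    abort(
      paste0(sum(is.na(sub$topic)), " review(s) in market ", market,
             " lack a topic label; label or drop them before summarising"),
      class = "useis_validation_error"
    )
  }
  sub |>
    dplyr::count(.data$topic, name = "n") |>
    dplyr::mutate(market = market, proportion = .data$n / sum(.data$n)) |>
    dplyr::select("market", "topic", "n", "proportion")
}

#' Criterion-level review proportions
#'
#' Sums member-topic frequency proportions within each criterion of a
#' hierarchy, yielding the criterion-layer comparison basis.
#'
#' @param proportions Output of [topic_proportions()].
#' @param hierarchy A [hierarchy_frame()] whose indicators match the topics.
#' @return A tibble with columns `criterion`, `proportion`, ordered as in the
#'   hierarchy.
#' @export
criterion_proportions <- function(proportions, hierarchy) {
  hierarchy <- as_hierarchy_frame(hierarchy)
  missing_topics <- setdiff(hierarchy$indicators$indicator, proportions$topic)
  if (length(missing_topics) > 0) {
    abort(
      paste0("hierarchy indicators absent from the corpus: ",
             paste(missing_topics, collapse = ", ")),
      class = "useis_validation_error"
    )
  }
  hierarchy$indicators |>
    dplyr::left_join(proportions, by = c(indicator = "topic")) |>
    dplyr::summarise(proportion = sum(.data$proportion), .by = "criterion") |>
    dplyr::arrange(match(.data$criterion, hierarchy$criteria))
}

#' Positive review share for one topic
#'
#' The proportion of a topic's polarity-labeled reviews that are positive;
#' used as the topic's initial satisfaction value. Reviews without a
#' polarity label are excluded from the denominator.
#'
#' @param corpus A cleaned `useis_corpus`.
#' @param topic Topic label.
#' @return A value in `[0, 1]`.
#' @export
positive_share <- function(corpus, topic) {
  corpus <- review_corpus(corpus)
  sub <- corpus[!is.na(corpus$topic) & corpus$topic == topic, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(paste0("topic not present in corpus: ", topic),
          class = "useis_empty_input_error")
  }
  labeled <- sub$polarity[!is.na(sub$polarity)]
  if (length(labeled) == 0) {
    abort(paste0("topic has no polarity-labeled reviews: ", topic),
          class = "useis_empty_input_error")
  }
  mean(labeled == "positive")
}

#' Positive review share for every topic in a market
#'
#' @param corpus A cleaned `useis_corpus`.
#' @param market Market to summarise.
#' @return A tibble with columns `topic`, `n_labeled`, `positive_share`.
#' @export
positive_shares <- function(corpus, market) {
  corpus <- review_corpus(corpus)
  sub <- corpus[corpus$market == market & !is.na(corpus$topic) &
                  !is.na(corpus$polarity), , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(paste0("no polarity-labeled reviews for market ", market),
          class = "useis_empty_input_error")
  }
  sub |>
    dplyr::summarise(
      n_labeled = dplyr::n(),
      positive_share = mean(.data$polarity == "positive"),
      .by = "topic"
    )
}
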
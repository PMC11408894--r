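test_that("the corpus generator is a pure function of its spec", {
  spec <- corpus_spec("US", 300, default_scenario()$topics,
                      contamination = list(duplicate = 0.05, bot = 0.03),
                      seed = 17)
  a <- simulate_reviews(spec)
  b <- simulate_reviews(spec)
  expect_identical(a, b)
  c_ <- simulate_reviews(corpus_spec("US", 300, default_scenario()$topics,
                                     contamination = list(duplicate = 0.05, bot = 0.03),
                                     seed = 18))
  expect_false(identical(a, c_))
})

test_that("clean simulated corpora recover the specified positive share", {
  topics <- tibble::tibble(topic = "A", proportion = 1, positive_share = 0.9)
  n <- 10000
  corpus <- simulate_reviews(corpus_spec("US", n, topics, seed = 4))
  res <- apply_filters(corpus)
  expect_true(all(unlist(res$report$removed) == 0))
  share <- positive_share(res$corpus, "A")
  expect_gte(share, qbinom(0.005, n, 0.9) / n)
  expect_lte(share, qbinom(0.995, n, 0.9) / n)
})

test_that("injected contamination is recovered by the filters at the injected rates", {
  n <- 1000
  rates <- list(duplicate = 0.1, blank = 0.04, garbled = 0.04, ad = 0.04,
                bot = 0.05, polarity_mismatch = 0.05)
  for (seed in c(8, 9)) {
    spec <- corpus_spec("US", n, default_scenario()$topics,
                        contamination = rates, seed = seed)
    res <- apply_filters(simulate_reviews(spec), bot_predicate = flag_bot_authors)
    for (kind in names(rates)) {
      key <- if (kind == "ad") "advertisement" else kind
      count <- res$report$removed[[key]]
      expect_gte(count, qbinom(0.005, n, rates[[kind]]))
      expect_lte(count, qbinom(0.995, n, rates[[kind]]))
    }
  }
})

test_that("Chinese-market corpora survive the language filter", {
  topics <- tibble::tibble(topic = c("A", "B"), proportion = c(0.6, 0.4),
                           positive_share = c(0.8, 0.5))
  corpus <- simulate_reviews(corpus_spec("CN", 500, topics, seed = 3))
  res <- apply_filters(corpus)
  expect_true(all(unlist(res$report$removed) == 0))
})

test_that("cohort generator hits the target demand-satisfaction rate", {
  spec <- cohort_spec(91, 0.559, n_demands = 55, n_dimensions = 10, seed = 12)
  apps <- simulate_fit_matrices(spec)
  expect_length(apps, 91)
  expect_identical(apps[[1]]$incidence,
                   simulate_fit_matrices(spec)[[1]]$incidence)
  summ <- cohort_summary(apps, attr(apps, "catalog"))
  # every generated function covers >= 1 demand, so utilization is 1
  expect_equal(summ$mean_utilization, 1)
  # 99% binomial band for the mean over 91 * 55 independent demand draws
  n_draws <- 91 * 55
  expect_gte(summ$mean_demand_satisfaction, qbinom(0.005, n_draws, 0.559) / n_draws)
  expect_lte(summ$mean_demand_satisfaction, qbinom(0.995, n_draws, 0.559) / n_draws)

  full <- simulate_fit_matrices(cohort_spec(5, 1, n_demands = 12, seed = 1))
  rates <- vapply(full, demand_satisfaction_rate, numeric(1))
  expect_true(all(rates == 1))
})

test_that("dead functions appear only when explicitly allowed", {
  spec <- cohort_spec(20, 0.5, n_demands = 20, allow_dead_functions = TRUE,
                      seed = 6)
  apps <- simulate_fit_matrices(spec)
  utils_ <- vapply(apps, utilization_rate, numeric(1))
  expect_true(any(utils_ < 1))
  spec2 <- cohort_spec(20, 0.5, n_demands = 20, seed = 6)
  utils2 <- vapply(simulate_fit_matrices(spec2), utilization_rate, numeric(1))
  expect_true(all(utils2 == 1))
})

test_that("bundled US/CN fixtures carry the published structure and values", {
  fx <- fixture_us_cn()
  expect_length(fx$us$hierarchy$criteria, 6)
  expect_equal(nrow(fx$us$hierarchy$indicators), 12)
  expect_length(fx$cn$hierarchy$criteria, 6)
  expect_equal(nrow(fx$cn$hierarchy$indicators), 10)
  expect_equal(fx$us$satisfaction[["Reliability"]], 0.2977)
  expect_equal(fx$cn$satisfaction[["Fee"]], 0.4303)
  # weight sets are valid: globals sum to 1, locals sum to 1 per criterion
  for (side in fx) {
    expect_equal(sum(side$weights$indicators$global_weight), 1, tolerance = 1e-9)
    expect_equal(sum(side$weights$criteria$weight), 1, tolerance = 1e-9)
    sums <- tapply(side$weights$indicators$local_weight,
                   side$weights$indicators$criterion, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    # the three published comprehensive weights are reproduced
    gw <- setNames(side$weights$indicators$global_weight,
                   side$weights$indicators$indicator)
    ref <- side$reference$top_global_weights
    expect_equal(round(gw[names(ref)], 4), ref)
    # and they are the three largest
    expect_equal(sort(names(sort(gw, decreasing = TRUE)[1:3])),
                 sort(names(ref)))
  }
})

test_that("invalid specs are rejected", {
  topics <- tibble::tibble(topic = "A", proportion = 0.5, positive_share = 0.5)
  expect_error(corpus_spec("US", 10, topics), class = "useis_validation_error")
  topics$proportion <- 1
  expect_error(corpus_spec("US", 10, topics, contamination = list(blank = 2)),
               class = "useis_validation_error")
  expect_error(corpus_spec("US", 10, topics, contamination = list(spam = 0.1)),
               class = "useis_validation_error")
  expect_error(corpus_spec("EU", 10, topics), class = "useis_validation_error")
  expect_error(cohort_spec(0, 0.5), class = "useis_validation_error")
  expect_error(cohort_spec(5, 1.5), class = "useis_validation_error")
})
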
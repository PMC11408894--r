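# Bundled US/China hypertension-app evaluation systems.
#
# The hierarchies, indicator satisfaction values, criterion satisfaction
# values, overall satisfaction, and the three largest comprehensive weights
# per country are published values. The full weight vectors are not, so the
# fixture carries a SYNTHETIC weight reconstruction: local weights of
# two-indicator criteria are uniquely determined by their published
# criterion satisfaction; the published top comprehensive weights pin three
# criterion weights; the remaining degrees of freedom are closed by fixed,
# documented choices plus the sum-to-1 and published-overall constraints.
# The reconstruction reproduces every published aggregate exactly but is
# not the original weighting.

# Local weights of a 2-indicator criterion from its satisfaction values and
# criterion satisfaction: unique solution of w*s1 + (1-w)*s2 = S.
local2 <- function(s, S) {
  w <- (S - s[[2]]) / (s[[1]] - s[[2]])
  setNames(c(w, 1 - w), names(s))
}

us_fixture <- function() {
  sat <- list(
    "Availability" = c("Reliability" = 0.2977, "Compatibility" = 0.4316),
    "Usability" = c("Convenience" = 0.7865, "Page design" = 0.8552,
                    "Advertising distribution" = 0.2058),
    "Monitoring function" = c("Blood pressure tracking" = 0.8347,
                              "Heart rate monitoring" = 0.5863),
    "Monitoring effect" = c("Effect of blood pressure management" = 0.8701,
                            "Measurement accuracy" = 0.7723),
    "Data management" = c("Data synchronization" = 0.2145,
                          "Data sharing" = 0.5200),
    "Cost" = c("Fee" = 0.8093)
  )
  crit_sat <- c(
    "Availability" = 0.3647, "Usability" = 0.7353,
    "Monitoring function" = 0.7726, "Monitoring effect" = 0.8457,
    "Data management" = 0.3163, "Cost" = 0.8093
  )
  overall <- 0.6861

  local <- list(
    "Availability" = local2(sat$Availability, crit_sat[["Availability"]]),
    "Monitoring function" = local2(sat$`Monitoring function`,
                                   crit_sat[["Monitoring function"]]),
    "Monitoring effect" = local2(sat$`Monitoring effect`,
                                 crit_sat[["Monitoring effect"]]),
    "Data management" = local2(sat$`Data management`,
                               crit_sat[["Data management"]]),
    "Cost" = c("Fee" = 1)
  )
  # criterion weights pinned by published comprehensive weights
  W <- c(
    "Monitoring function" = 0.1495 / local$`Monitoring function`[["Blood pressure tracking"]],
    "Data management" = 0.0791 / local$`Data management`[["Data synchronization"]],
    "Usability" = 0.48,          # free choice
    "Monitoring effect" = 0.09   # free choice
  )
  # usability locals: convenience share fixed by its comprehensive weight,
  # page/ads split recovers the published criterion satisfaction
  s_u <- sat$Usability
  w_conv <- 0.4199 / W[["Usability"]]
  rest <- 1 - w_conv
  w_page <- (crit_sat[["Usability"]] - s_u[[1]] * w_conv - s_u[[3]] * rest) /
    (s_u[[2]] - s_u[[3]])
  local$Usability <- c(
    "Convenience" = w_conv, "Page design" = w_page,
    "Advertising distribution" = rest - w_page
  )
  # remaining two criterion weights from sum-to-1 and the published overall
  budget <- 1 - sum(W)
  rhs <- overall - sum(W * crit_sat[names(W)])
  W[["Cost"]] <- (rhs - crit_sat[["Availability"]] * budget) /
    (crit_sat[["Cost"]] - crit_sat[["Availability"]])
  W[["Availability"]] <- budget - W[["Cost"]]

  assemble_fixture("US", sat, crit_sat, overall, W, local,
                   top_global = c("Convenience" = 0.4199,
                                  "Blood pressure tracking" = 0.1495,
                                  "Data synchronization" = 0.0791))
}

cn_fixture <- function() {
  sat <- list(
    "Availability" = c("Reliability" = 0.8356, "Compatibility" = 0.4419),
    "Usability" = c("Convenience" = 0.8909, "Page design" = 0.7028),
    "Monitoring function" = c("Heart rate monitoring" = 0.8358,
                              "Blood pressure tracking" = 0.8127),
    "Monitoring effect" = c("Measurement accuracy" = 0.6188,
                            "Real-time monitoring" = 0.6656),
    "Data management" = c("Data privacy" = 0.7396),
    "Cost" = c("Fee" = 0.4303)
  )
  crit_sat <- c(
    "Availability" = 0.7044, "Usability" = 0.8721,
    "Monitoring function" = 0.8243, "Monitoring effect" = 0.6305,
    "Data management" = 0.7396, "Cost" = 0.4303
  )
  overall <- 0.7891

  local <- list(
    "Availability" = local2(sat$Availability, crit_sat[["Availability"]]),
    "Usability" = local2(sat$Usability, crit_sat[["Usability"]]),
    "Monitoring function" = local2(sat$`Monitoring function`,
                                   crit_sat[["Monitoring function"]]),
    "Monitoring effect" = local2(sat$`Monitoring effect`,
                                 crit_sat[["Monitoring effect"]]),
    "Data management" = c("Data privacy" = 1),
    "Cost" = c("Fee" = 1)
  )
  W <- c(
    "Usability" = 0.5246 / local$Usability[["Convenience"]],
    "Availability" = 0.0978 / local$Availability[["Reliability"]],
    "Monitoring effect" = 0.0900 / local$`Monitoring effect`[["Measurement accuracy"]],
    "Cost" = 0.05  # free choice
  )
  budget <- 1 - sum(W)
  rhs <- overall - sum(W * crit_sat[names(W)])
  W[["Monitoring function"]] <-
    (rhs - crit_sat[["Data management"]] * budget) /
    (crit_sat[["Monitoring function"]] - crit_sat[["Data management"]])
  W[["Data management"]] <- budget - W[["Monitoring function"]]

  assemble_fixture("CN", sat, crit_sat, overall, W, local,
                   top_global = c("Convenience" = 0.5246,
                                  "Reliability" = 0.0978,
                                  "Measurement accuracy" = 0.0900))
}

assemble_fixture <- function(market, sat, crit_sat, overall, W, local,
                             top_global) {
  criteria <- names(sat)
  hierarchy <- hierarchy_frame(
    "User satisfaction",
    purrr::imap_dfr(sat, function(s, cr) {
      tibble::tibble(indicator = names(s), criterion = cr)
    }),
    criteria = criteria
  )
  weights <- weight_set(hierarchy, W[criteria], local[criteria])
  list(
    market = market,
    hierarchy = hierarchy,
    satisfaction = unlist(unname(sat)),
    weights = weights,
    reference = list(
      overall = overall,
      criterion_satisfaction = crit_sat,
      top_global_weights = top_global
    )
  )
}

#' Bundled US and Chinese hypertension-app evaluation systems
#'
#' Returns the two published user-satisfaction evaluation hierarchies for
#' hypertension management apps - 6 criteria with 12 indicators (US) and 6
#' criteria with 10 indicators (China) - together with the published
#' per-indicator satisfaction values, reference aggregates (criterion
#' satisfaction, overall satisfaction, and the three largest comprehensive
#' weights per country), and a synthetic weight reconstruction consistent
#' with all of those published values (the full original weight vectors are
#' not public; see the package vignette for the reconstruction).
#'
#' @return A list with elements `us` and `cn`, each containing `hierarchy`,
#'   `satisfaction` (named vector), `weights` (a `useis_weights`), and
#'   `reference` (published aggregates).
#' @export
#' @examples
#' fx <- fixture_us_cn()
#' scored <- score_hierarchy(fx$us$hierarchy, fx$us$weights, fx$us$satisfaction)
#' round(scored$overall, 4)
fixture_us_cn <- function() {
  list(us = us_fixture(), cn = cn_fixture())
}
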
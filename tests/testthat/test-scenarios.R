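test_that("detection-versus-cost tables carry the right responses", {
  cur <- detection_cost_curves(L = 1, k = 0:10)
  mb <- cur[cur$method == "metabarcode", ]
  expect_gt(mb$response[mb$k == 5], 0.99)
  se <- cur[cur$method == "seine" & cur$scenario == "baseline", ]
  expect_equal(se$response[se$k == 10], 1 - 0.75^10, tolerance = 1e-12)

  # no sites visited: no detection, fixed cost only
  p <- default_cost_params("goby_metabarcode")
  expect_equal(mb$response[mb$k == 0], 0)
  expect_equal(mb$cost_hours_per_location[mb$k == 0],
               fixed_cost(p, effort_design(L = 1)))
})

test_that("within a scenario, detection and cost rise monotonically with
           effort", {
  cur <- detection_cost_curves(L = c(1, 10, 100))
  combos <- unique(cur[c("method", "scenario", "L")])
  for (i in seq_len(nrow(combos))) {
    sub <- cur[cur$method == combos$method[i] &
                 cur$scenario == combos$scenario[i] &
                 cur$L == combos$L[i], ]
    sub <- sub[order(sub$k), ]
    expect_true(all(diff(sub$response) >= 0))
    expect_true(all(diff(sub$cost_hours_per_location) > 0))
    expect_true(all(sub$ci_low <= sub$response &
                      sub$response <= sub$ci_high))
  }
})

test_that("sharing fixed costs over more locations lowers per-location
           cost", {
  cur <- detection_cost_curves(L = c(1, 10, 100))
  key <- c("method", "scenario", "k")
  for (pair in list(c(1, 10), c(10, 100))) {
    a <- cur[cur$L == pair[1], ]
    b <- cur[cur$L == pair[2], ]
    m <- merge(a, b, by = key)
    expect_true(all(m$cost_hours_per_location.y <=
                      m$cost_hours_per_location.x))
  }
})

test_that("crossover ranking finds qPCR cheapest with a validated assay and
           never seining", {
  cur <- detection_cost_curves(L = c(1, 10, 100))
  cross <- summarize_crossovers(cur)

  at99 <- cross[cross$threshold == 0.99, ]
  l10 <- at99[at99$L == 10, ]
  qpcr_val <- l10$cost_at_threshold[l10$method == "qPCR" &
                                      l10$scenario == "assay_validated"]
  mb <- l10$cost_at_threshold[l10$method == "metabarcode"]
  expect_lt(qpcr_val, mb)

  # seining is never the cheapest route to confident detection, even with
  # its permitting and environmental costs stripped
  expect_false(any(at99$cheapest[at99$method == "seine"]))
  seine_best <- min(at99$cost_at_threshold[at99$method == "seine"],
                    na.rm = TRUE)
  qpcr_pub <- at99$cost_at_threshold[at99$method == "qPCR" &
                                       at99$scenario == "assay_published"]
  expect_true(all(seine_best > qpcr_pub))

  # a single method is trivially ranked first everywhere
  solo <- summarize_crossovers(cur[cur$method == "seine" &
                                     cur$scenario == "baseline", ])
  expect_true(all(solo$rank[!is.na(solo$rank)] == 1))
})

make_fit <- function(truth, n_max = 2, noise = 0.02, seed = 1) {
  grid <- expand.grid(n = seq_len(n_max), k = 1:25)
  set.seed(seed)
  grid$median_S <- predict_richness(truth, n = grid$n, k = grid$k) *
    exp(rnorm(nrow(grid), 0, noise))
  fit_polce_kunin(grid)
}

test_that("richness-versus-cost curves: two samples beat one, at less than
           twice the price", {
  mb_fit <- make_fit(c(a = 1, b = 1, c = 0.8, z = 1.4), seed = 2)
  se_fit <- make_fit(c(a = 1, b = 1.5, c = 0.9, z = 1.1), seed = 3)
  strat <- default_richness_strategies(mb_fit, se_fit)
  cur <- richness_cost_curves(strat, L = 1, k = 1:25)

  single <- cur[cur$strategy == "single_barcode", ]
  double <- cur[cur$strategy == "double_barcode", ]
  expect_true(all(double$response >= single$response))
  # not twice as many species, and not twice the cost: fixed costs shared
  expect_true(all(double$response < 2 * single$response))
  expect_true(all(double$cost_hours_per_location <
                    2 * single$cost_hours_per_location))

  # the smallest effort point sits at the fitted single-sample curve start
  expect_equal(single$response[single$k == 1],
               predict_richness(mb_fit, n = 1, k = 1))
})

test_that("unconverged accumulation fits are refused with diagnostics", {
  bad <- fit_polce_kunin(data.frame(n = 1:6, k = 1, median_S = 5))
  strat <- list(list(strategy = "s", method = "seine", cost = "fish_seine",
                     fit = bad, n = 1, scenario = "baseline",
                     overrides = list()))
  expect_error(richness_cost_curves(strat), "refusing")
  expect_error(detection_cost_curves(params = default_cost_params()[1],
                                     scenarios = default_scenario_set()),
               "no cost parameters")
})
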
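test_that("inverse logit behaves as the logistic CDF", {
  expect_equal(inverse_logit(0), 0.5)
  expect_equal(round(inverse_logit(1.08 - 2.2), 2), 0.25)
  expect_lt(inverse_logit(-20), 1e-8)
  p <- seq(0.001, 0.999, by = 0.007)
  expect_equal(inverse_logit(stats::qlogis(p)), p, tolerance = 1e-12)
  x <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(inverse_logit(x)) > 0))
})

test_that("logistic fit recovers a single-cell proportion", {
  rec <- data.frame(site_id = "a", method = "qPCR",
                    detected = rep(c(1, 0), each = 10))
  est <- fit_detection_glm(rec)
  expect_equal(nrow(est), 1L)
  expect_equal(est$gamma, 0.5, tolerance = 1e-9)
  expect_equal(est$coefficient, 0, tolerance = 1e-9)
  expect_true(est$ci_low < 0.5 && est$ci_high > 0.5)
})

test_that("fitted cell probabilities match empirical logits on an exactly
           additive balanced design", {
  # cell proportions chosen so the empirical logits are exactly additive:
  # the 3-parameter additive fit then reproduces every cell proportion
  cells <- expand.grid(site_id = c("s1", "s2"), method = c("m1", "m2"),
                       stringsAsFactors = FALSE)
  cells$n <- 100
  cells$hits <- c(50, 20, 80, 50)  # logits 0, -1.386, 1.386, 0
  rec <- records_from_counts(cells)
  est <- fit_detection_glm(rec, reference_site = "s1",
                           reference_method = "m1")
  est <- est[order(est$site_id, est$method), ]
  emp <- cells[order(cells$site_id, cells$method), ]
  expect_equal(est$gamma, emp$hits / emp$n, tolerance = 1e-6)
  expect_true(all(est$ci_low <= est$gamma & est$gamma <= est$ci_high))
})

test_that("degenerate all-detected cells are flagged, not silently extreme", {
  rec <- rbind(
    data.frame(site_id = "lagoon", method = "qPCR", detected = rep(1, 18)),
    data.frame(site_id = "river", method = "qPCR",
               detected = rep(c(1, 0), c(15, 5)))
  )
  expect_warning(est <- fit_detection_glm(rec), "separation")
  expect_true(est$separation[est$site_id == "lagoon"])
  expect_false(est$separation[est$site_id == "river"])
})

test_that("records must be binary and mixed", {
  expect_error(fit_detection_glm(data.frame(site_id = "a", method = "m",
                                            detected = c(1, 2))), "coded 0")
  expect_error(fit_detection_glm(data.frame(site_id = "a", method = "m",
                                            detected = c(1, 1))),
               "at least one detection and one non-detection")
  expect_error(fit_detection_glm(data.frame(site_id = "a", method = "m",
                                            detected = 1)), "at least two")
})

test_that("cumulative detection follows 1 - (1 - gamma)^(nk)", {
  expect_gt(cumulative_detection(0.62, n = 1, k = 5)$d, 0.99)
  expect_equal(cumulative_detection(0.62, n = 5, k = 1)$d,
               1 - 0.38^5, tolerance = 1e-12)
  expect_equal(cumulative_detection(0.31, n = 1, k = 1)$d, 0.31)
  expect_equal(cumulative_detection(0, n = 3, k = 7)$d, 0)
  expect_equal(cumulative_detection(0.25, n = 1, k = 10)$d, 0.94369,
               tolerance = 1e-5)

  # monotone in effort and in gamma; approaches 1
  d <- cumulative_detection(0.2, n = 1, k = 0:40)
  expect_true(all(diff(d$d) >= 0))
  expect_equal(d$d[1], 0)
  expect_gt(d$d[41], 0.9998)
  expect_true(all(diff(cumulative_detection(seq(0.1, 0.9, 0.1), 5)$d) > 0))

  # interval endpoints transform monotonically and preserve ordering
  est <- rare_case_estimates()
  d2 <- cumulative_detection(est[est$method == "seine", ], n = 1, k = 1:25)
  expect_true(all(d2$ci_low <= d2$d & d2$d <= d2$ci_high))
  expect_equal(d2$ci_low, 1 - (1 - 0.12)^(1:25))
})

test_that("minimum sample count hits the target exactly at the boundary", {
  expect_identical(min_samples(0.62, 0.99), 5L)
  expect_identical(min_samples(0.25, 0.99), 17L)  # 0.75^16 > 0.01 > 0.75^17
  expect_identical(min_samples(0.999999, 0.9), 1L)
  for (g in c(0.05, 0.3, 0.77)) {
    for (tg in c(0.5, 0.95, 0.99)) {
      m <- min_samples(g, tg)
      expect_gte(1 - (1 - g)^m, tg)
      if (m > 1) expect_lt(1 - (1 - g)^(m - 1), tg)
    }
  }
  expect_error(min_samples(0, 0.99), "gamma")
  expect_error(min_samples(0.5, 1), "target")
})

test_that("rare-case estimates encode one shared eDNA detectability", {
  est <- rare_case_estimates()
  expect_equal(est$gamma[est$method == "qPCR"],
               est$gamma[est$method == "metabarcode"])
  expect_equal(est$gamma[est$method == "seine"], 0.25)
  expect_true(all(est$ci_low <= est$gamma & est$gamma <= est$ci_high))
})
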
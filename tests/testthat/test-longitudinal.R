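# Longitudinal change detection and trend classification.

test_that("the 10%-in-6-months weight-loss limit flags 80->72 but not 80->73", {
  spec <- change_spec("relative_percent", "decrease", 10, window_months = 6)
  s <- rc_series("body_weight", c("2023-01-01", "2023-06-01"), c(80, 72))
  res <- detect_change(s, spec, as_of = "2023-06-01")
  expect_true(res$flag)
  expect_equal(res$magnitude, -10)   # (72 - 80) / 80 * 100

  s2 <- rc_series("body_weight", c("2023-01-01", "2023-06-01"), c(80, 73))
  res2 <- detect_change(s2, spec, as_of = "2023-06-01")
  expect_false(res2$flag)            # -8.75% does not reach the limit

  # same drop over more than 6 months: no qualifying pair
  s3 <- rc_series("body_weight", c("2023-01-01", "2023-08-15"), c(80, 72))
  expect_false(detect_change(s3, spec, as_of = "2023-08-15")$flag)
})

test_that("a constant series is a decided FALSE with zero magnitude; single point is unknown", {
  spec <- change_spec("relative_percent", "decrease", 10, window_months = 6)
  s <- rc_series("w", c("2023-01-01", "2023-02-01", "2023-03-01"), c(70, 70, 70))
  res <- detect_change(s, spec, as_of = "2023-03-01")
  expect_false(res$flag)
  expect_equal(res$magnitude, 0)
  s1 <- rc_series("w", "2023-01-01", 70)
  expect_identical(detect_change(s1, spec, as_of = "2023-06-01")$flag, NA)
})

test_that("any qualifying pair triggers, not only the endpoints", {
  spec <- change_spec("relative_percent", "decrease", 10, window_months = 6)
  # drops 80 -> 70 mid-series, then regains: still a significant loss episode
  s <- rc_series("w", c("2023-01-01", "2023-03-01", "2023-06-01"), c(80, 70, 80))
  expect_true(detect_change(s, spec, as_of = "2023-06-01")$flag)
})

test_that("detect_change matches the exhaustive-pair oracle on random series", {
  set.seed(300)
  brute <- function(s, spec, as_of) {
    keep <- s$time <= as.Date(as_of)
    t <- s$time[keep]; v <- s$value[keep]
    if (length(t) < 2) return(NA)
    found <- FALSE
    for (i in seq_along(t)) for (j in seq_along(t)) {
      if (t[j] <= t[i]) next
      within <- if (!is.null(spec$window_months)) {
        t[j] <= respcoach:::add_months(t[i], spec$window_months)
      } else {
        as.numeric(t[j] - t[i]) <= spec$window_days
      }
      if (!within || v[i] == 0) next
      delta <- if (spec$mode == "relative_percent") (v[j] - v[i]) / v[i] * 100 else v[j] - v[i]
      hit <- switch(spec$direction, decrease = delta <= -spec$threshold,
                    increase = delta >= spec$threshold,
                    either = abs(delta) >= spec$threshold)
      if (hit) found <- TRUE
    }
    found
  }
  for (i in 1:60) {
    n <- sample(2:12, 1)
    times <- as.Date("2023-01-01") + sort(sample(0:360, n))
    vals <- round(runif(n, 50, 100), 1)
    s <- rc_series("w", times, vals)
    spec <- change_spec(sample(c("relative_percent", "absolute"), 1),
                        sample(c("decrease", "increase", "either"), 1),
                        threshold = sample(c(3, 5, 10, 20), 1),
                        window_days = sample(c(30, 90, 180), 1))
    as_of <- times[n]
    expect_identical(detect_change(s, spec, as_of)$flag, brute(s, spec, as_of),
                     info = paste("series", i))
  }
})

test_that("detect_change ignores points after as_of and relative magnitude is scale-invariant", {
  spec <- change_spec("relative_percent", "decrease", 10, window_months = 6)
  s <- rc_series("w", c("2023-01-01", "2023-05-01"), c(80, 71))
  base <- detect_change(s, spec, as_of = "2023-05-01")
  s_more <- rc_series("w", c("2023-01-01", "2023-05-01", "2023-07-01"), c(80, 71, 40))
  expect_identical(detect_change(s_more, spec, as_of = "2023-05-01")[c("flag", "magnitude")],
                   base[c("flag", "magnitude")])
  s_scaled <- rc_series("w", c("2023-01-01", "2023-05-01"), c(80, 71) * 3.7)
  scaled <- detect_change(s_scaled, spec, as_of = "2023-05-01")
  expect_identical(scaled$flag, base$flag)
  expect_equal(scaled$magnitude, base$magnitude)
})

test_that("series timestamps must strictly increase", {
  expect_error(rc_series("w", c("2023-01-02", "2023-01-01"), c(1, 2)),
               "strictly increasing")
  expect_error(rc_series("w", c("2023-01-01", "2023-01-01"), c(1, 2)),
               "strictly increasing")
})

test_that("trend classification matches the closed-form regression oracle", {
  # rising control score over 3 months, higher is better -> improving
  t <- as.Date("2023-01-01") + seq(0, 90, by = 10)
  s_up <- rc_series("control", t, seq(10, 20, length.out = length(t)))
  expect_identical(series_trend(s_up, 90, as_of = t[length(t)]), "improving")
  expect_identical(series_trend(s_up, 90, as_of = t[length(t)],
                                higher_is_better = FALSE), "worsening")
  # two points only -> unknown
  s2 <- rc_series("control", t[1:2], c(10, 20))
  expect_identical(series_trend(s2, 90, as_of = t[2]), "unknown")

  # noisy slopes: sign agrees with lm() whenever outside the dead band
  set.seed(77)
  for (i in 1:30) {
    slope <- runif(1, -0.2, 0.2)
    vals <- 50 + slope * seq(0, 90, by = 10) + rnorm(10, sd = 0.5)
    s <- rc_series("x", t, vals)
    cls <- series_trend(s, 90, as_of = t[length(t)])
    fit <- stats::lm(vals ~ as.numeric(t))
    b <- unname(stats::coef(fit)[2])
    band <- 0.05 * diff(range(vals)) / 90
    if (abs(b) <= band) {
      expect_identical(cls, "stable")
    } else {
      expect_identical(cls, if (b > 0) "improving" else "worsening")
    }
  }
})

test_that("derived variables materialize into the record before evaluation", {
  kb <- demo_kb()
  p <- demo_patient()
  p$series <- list(rc_series("body_weight", c("2023-01-01", "2023-06-01"), c(80, 72)))
  res <- trigger_rules(kb, p)
  expect_true("rule_weight" %in% res$fired$rule_id)
  p$series <- list(rc_series("body_weight", c("2023-01-01", "2023-06-01"), c(80, 75)))
  res2 <- trigger_rules(kb, p)
  expect_true("rule_weight" %in% res2$false)
})
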
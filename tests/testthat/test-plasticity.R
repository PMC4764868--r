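test_that("turnover formula worked examples", {
  expect_equal(turnover(20, 20, 0, 0), 0)
  expect_equal(turnover(7, 7, 1, 1), 100 * 2 / 14) # 14.2857...%
  expect_equal(turnover(5, 5, 5, 5), 100)
  expect_warning(res <- turnover(0, 0, 0, 0), "undefined")
  expect_true(is.na(res))
})

test_that("foldChange rounds the ratio and guards the denominator", {
  expect_equal(foldChange(6, 3), 2)
  expect_equal(foldChange(1, 3, digits = 3L), 0.333)
  expect_error(foldChange(1, 0), "zero")
})

test_that("survival fraction is 1 at t0 and tracks the presence of the t0
           cohort", {
  presence <- rbind(c(TRUE, TRUE, TRUE),
                    c(TRUE, TRUE, FALSE),
                    c(FALSE, TRUE, TRUE))
  tr <- list(presence = presence, nTimepoints = 3L, intervalMin = 30)
  class(tr) <- "punctaTracks"
  sf <- survivalFraction(tr)
  expect_equal(unname(sf[1]), 1)
  expect_equal(unname(sf), c(1, 1, 0.5)) # t0 cohort has 2 members
})

test_that("interval rates use the interval-start count as denominator", {
  presence <- rbind(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))
  tr <- list(presence = presence, nTimepoints = 2L, intervalMin = 30)
  class(tr) <- "punctaTracks"
  r <- intervalRates(tr)
  expect_equal(r$per_interval$gain_pct[1], 100 * 1 / 2)
  expect_equal(r$per_interval$loss_pct[1], 100 * 1 / 2)
  expect_equal(r$gain_pct_per_interval, 50)
})

test_that("summarizeTurnover conserves counts on random presence matrices", {
  set.seed(61)
  for (rep in 1:20) {
    presence <- matrix(runif(8 * 7) < 0.6, 8, 7)
    presence <- presence[rowSums(presence) > 0, , drop = FALSE]
    if (nrow(presence) == 0) next
    tr <- list(presence = presence, nTimepoints = 7L, intervalMin = 30,
               tracks = data.frame(track_id = seq_len(nrow(presence))))
    class(tr) <- "punctaTracks"
    sm <- summarizeTurnover(tr)
    expect_equal(sm$n_t3h, sm$n_t0 + sm$n_gain - sm$n_lost)
    if (sm$n_t0 + sm$n_t3h > 0) {
      expect_gte(sm$turnover_pct, 0)
    }
  }
})

test_that("groupTests reproduces a direct t-test and runs a two-way ANOVA", {
  set.seed(62)
  df <- data.frame(turnover_pct = c(rnorm(6, 25, 3), rnorm(6, 11, 3)),
                   age = rep(c("immature", "mature"), each = 6),
                   treatment = rep(c("ctrl", "occl"), 6))
  tt <- groupTests(df, group = "age")
  ref <- t.test(df$turnover_pct[df$age == "immature"],
                df$turnover_pct[df$age == "mature"])
  expect_equal(tt$p.value, ref$p.value)
  av <- groupTests(df, group = "age", group2 = "treatment")
  expect_true(inherits(av, "summary.aov") || inherits(av, "listof"))
  expect_error(groupTests(df, group = "nope"), "group")
})

test_that("thresholdRobustness reports agreement between multipliers on a
           clean series", {
  cfg <- tinyConfig(seed = 63L)
  s <- imageSeries(generateSeries(cfg))
  rb <- thresholdRobustness(s)
  expect_true(all(c("summary_high", "summary_low", "n_paired",
                    "agreement_rate") %in% names(rb)))
  for (sm in list(rb$summary_high, rb$summary_low))
    expect_equal(sm$n_t3h, sm$n_t0 + sm$n_gain - sm$n_lost)
  expect_gt(rb$n_paired, 0L)
})
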
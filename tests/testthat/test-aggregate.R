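# Builds a small two-study table by hand: sorter A is perfect, sorter B is
# mediocre, and unit SNRs straddle the threshold.
toy_table <- function(missing = data.frame(sorter = character(),
                                           recording = character())) {
  units <- expand.grid(sorter = c("A", "B"), recording = c("r1", "r2", "r3"),
                       gt_label = 1:3, stringsAsFactors = FALSE)
  units$snr <- rep(c(9, 10, 3), each = 6)
  units$accuracy <- ifelse(units$sorter == "A",
                           rep(c(0.9, 0.7, 0.1), each = 6),
                           rep(c(0.6, 0.5, 0.05), each = 6))
  units$precision <- units$accuracy
  units$recall <- pmin(1, units$accuracy + 0.05)
  units$num_events <- 100
  if (nrow(missing)) {
    drop <- paste(units$sorter, units$recording) %in%
      paste(missing$sorter, missing$recording)
    units <- units[!drop, ]
  }
  studies <- data.frame(recording = c("r1", "r2", "r3"),
                        study = c("s1", "s1", "s2"),
                        study_set = "set1")
  study_results(units, studies, missing)
}

test_that("average metric honors the SNR threshold and mean-of-means roll-up", {
  tab <- toy_table()
  avg <- average_metric(tab, aggregation_params(snr_threshold = 8))
  # units with SNR {9,10} qualify, the SNR-3 unit does not: mean(.9,.7) = .8
  a_s1 <- avg$study$value[avg$study$sorter == "A" & avg$study$study == "s1"]
  expect_equal(a_s1, 0.8)
  # threshold 0 admits all units
  avg0 <- average_metric(tab, aggregation_params(snr_threshold = 0))
  expect_equal(avg0$study$value[avg0$study$sorter == "A" &
                                  avg0$study$study == "s1"],
               mean(c(0.9, 0.7, 0.1)))
  # study-set value is the unweighted mean of study means
  expect_equal(avg$study_set$value[avg$study_set$sorter == "A"],
               mean(avg$study$value[avg$study$sorter == "A"]))
  # raising the threshold never admits more units
  for (thr in c(0, 3, 8, 11)) {
    n_in <- sum(tab$units$snr[tab$units$sorter == "A"] >= thr)
    n_in_higher <- sum(tab$units$snr[tab$units$sorter == "A"] >= thr + 1)
    expect_lte(n_in_higher, n_in)
  }
})

test_that("count_above applies the accuracy threshold, never imputes, flags incomplete", {
  tab <- toy_table()
  cnt <- count_above(tab, aggregation_params(accuracy_threshold = 0.8))
  # study s1 x sorter A: accuracies {.9,.7,.1} on two recordings -> 2 units
  expect_identical(cnt$count[cnt$sorter == "A" & cnt$study == "s1"], 2L)
  expect_false(any(cnt$incomplete))

  # dropping one of A's recordings removes its units and flags the row
  tabm <- toy_table(missing = data.frame(sorter = "A", recording = "r1"))
  cntm <- count_above(tabm, aggregation_params(accuracy_threshold = 0.8))
  expect_identical(cntm$count[cntm$sorter == "A" & cntm$study == "s1"], 1L)
  expect_true(cntm$incomplete[cntm$sorter == "A" & cntm$study == "s1"])

  # monotone in the accuracy threshold
  counts <- vapply(c(0, 0.5, 0.8, 0.95), function(th) {
    sum(count_above(tab, aggregation_params(accuracy_threshold = th))$count)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("imputation recovers an exact linear dependence and never moves observed cells", {
  set.seed(14)
  a <- runif(10, 0.3, 0.9)
  vals <- rbind(A = a, B = 0.5 * a + 0.1)
  colnames(vals) <- paste0("r", 1:10)
  mask <- matrix(FALSE, 2, 10, dimnames = dimnames(vals))
  mask["B", c(2, 5, 9)] <- TRUE
  obs <- vals
  obs["B", c(2, 5, 9)] <- NA
  filled <- impute_missing(obs, mask)
  expect_equal(filled["B", c(2, 5, 9)], vals["B", c(2, 5, 9)],
               tolerance = 1e-8)
  expect_identical(filled["A", ], vals["A", ])
  expect_identical(filled["B", -c(2, 5, 9)], vals["B", -c(2, 5, 9)])
  expect_true(all(attr(filled, "imputed")["B", c(2, 5, 9)]))

  # imputed values are clipped to [0, 1]
  vals2 <- rbind(A = seq(0.1, 1, length.out = 10),
                 B = seq(0.3, 3, length.out = 10))
  mask2 <- matrix(FALSE, 2, 10, dimnames = list(c("A", "B"), NULL))
  mask2["B", 10] <- TRUE
  obs2 <- vals2; obs2["B", 10] <- NA
  filled2 <- impute_missing(obs2, mask2)
  # the linear prediction at r10 would be 3; the imputed cell is clipped
  expect_identical(unname(filled2["B", 10]), 1)
  expect_true(all(filled2[attr(filled2, "imputed")] >= 0 &
                    filled2[attr(filled2, "imputed")] <= 1))

  # under-determined fit falls back to the sorter's observed mean
  vals3 <- rbind(A = a, B = 0.5 * a + 0.1, C = a^2)
  mask3 <- matrix(FALSE, 3, 10,
                  dimnames = list(c("A", "B", "C"), colnames(vals)))
  mask3["C", 3:10] <- TRUE  # only 2 observations, 2 predictors + intercept
  obs3 <- vals3; obs3["C", 3:10] <- NA
  expect_message(filled3 <- impute_missing(obs3, mask3), "fallback")
  expect_equal(unname(filled3["C", 3]), mean(vals3["C", 1:2]))
})

test_that("imputation is a no-op on complete data and feeds the average", {
  tab <- toy_table()
  p_imp <- aggregation_params(impute = TRUE)
  p_no <- aggregation_params(impute = FALSE)
  expect_equal(average_metric(tab, p_imp)$study,
               average_metric(tab, p_no)$study)

  # with B = f(A) linear per recording, a missing B recording is recovered
  tabm <- toy_table(missing = data.frame(sorter = "B", recording = "r2"))
  avg <- average_metric(tabm, aggregation_params(snr_threshold = 8))
  full <- average_metric(toy_table(), aggregation_params(snr_threshold = 8))
  got <- avg$study$value[avg$study$sorter == "B" & avg$study$study == "s1"]
  want <- full$study$value[full$study$sorter == "B" &
                             full$study$study == "s1"]
  expect_equal(got, want, tolerance = 1e-8)
  expect_true(avg$study$imputed[avg$study$sorter == "B" &
                                  avg$study$study == "s1"])
})

test_that("accuracy predictor recovers a realizable linear model and nests single predictors", {
  set.seed(23)
  n <- 200
  units <- data.frame(snr = runif(n, 2, 15), firing_rate = runif(n, 0.5, 30),
                      isi_violation_ratio = rlnorm(n, -1, 1))
  units$accuracy <- 0.1 + 0.03 * units$snr + 0.005 * units$firing_rate -
    0.04 * log(units$isi_violation_ratio)
  fit <- fit_accuracy_predictor(units)
  expect_equal(unname(coef(fit)), c(0.1, 0.03, 0.005, -0.04),
               tolerance = 1e-8)
  expect_equal(fit$correlation, 1, tolerance = 1e-8)
  expect_equal(predict(fit, units), fit$fitted, tolerance = 1e-10)

  # pure noise: correlation near zero
  units$accuracy <- runif(n)
  fit2 <- fit_accuracy_predictor(units)
  expect_lt(abs(fit2$correlation), 0.3)

  # the 3-predictor fit is at least as correlated as any single predictor
  units$accuracy <- 0.2 + 0.04 * units$snr + rnorm(n, sd = 0.05)
  fit3 <- fit_accuracy_predictor(units)
  singles <- vapply(c("snr", "firing_rate"), function(v) {
    abs(stats::cor(units[[v]], units$accuracy))
  }, numeric(1))
  expect_gte(fit3$correlation + 1e-12, max(singles))

  # zero ISI ratios are floored, not dropped
  units$isi_violation_ratio[1:5] <- 0
  expect_silent(fit_accuracy_predictor(units))
})
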
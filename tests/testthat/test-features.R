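test_that("feature assembly produces one complete row per particle", {
  fit <- fixture_fit()
  fits <- list(fit, fit, fit)
  tab <- assemble_features(fits, labels = c("a", "b", "a"))
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab), 3)
  expect_setequal(
    names(tab),
    c("f1_A", "f1_freq_hz", "f1_width_hz", "f2_A", "f2_freq_hz",
      "f2_width_hz", "f3_A", "f3_freq_hz", "f3_width_hz",
      "gamma_v_per_m", "radius_f1_m", "radius_f2_m", "radius_f3_m",
      "mass_kg", "class"))
  expect_false(anyNA(tab))
})

test_that("particles with non-converged fits are excluded and counted", {
  good <- fixture_fit()
  bad <- good
  bad$fits$f3$converged <- FALSE
  expect_message(tab <- assemble_features(list(good, bad, good)),
                 "1 particle")
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "n_excluded"), 1)
})

test_that("the worked IQR example removes exactly the extreme row", {
  # column [1,2,3,4,100]: median 3, Q1 2, Q3 4 (linear interpolation),
  # fence 3 +/- 1.5*2 -> only 100 is out
  d <- data.frame(a = c(1, 2, 3, 4, 100), b = rep(1, 5),
                  class = factor(rep("s", 5)))
  res <- remove_outliers(d)
  expect_equal(nrow(res$table), 4)
  expect_equal(res$removed$a, 100)
  expect_match(res$removed$reason, "a")
  expect_equal(unname(res$stats$median[["a"]]), 3)
  expect_equal(unname(res$stats$iqr[["a"]]), 2)
})

test_that("identical rows survive: the fence is a strict inequality", {
  d <- data.frame(a = rep(2, 6), b = rep(-1, 6))
  res <- remove_outliers(d)
  expect_equal(nrow(res$table), 6)
  expect_equal(nrow(res$removed), 0)
})

test_that("one outlying column suffices to remove a row", {
  set.seed(8)
  d <- data.frame(a = rnorm(9), b = rnorm(9), c = rnorm(9))
  d[5, "b"] <- 50  # typical in a and c
  res <- remove_outliers(d)
  expect_false(5 %in% as.integer(rownames(res$table)))
  expect_match(res$removed$reason[res$removed$b == 50], "b")
})

test_that("degenerate tables pass through with a warning", {
  d <- data.frame(a = c(1, 2, 3))
  expect_warning(res <- remove_outliers(d), "fewer than 4")
  expect_equal(nrow(res$table), 3)
})

test_that("survivors match brute-force enumeration and the filter is a
           single frozen pass", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- as.data.frame(matrix(rt(12 * 4, df = 2), 12, 4))
    res <- remove_outliers(d, k = 1.5)
    # brute force over rows x columns with type-7 quartiles
    keep <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(d))) for (j in seq_len(ncol(d))) {
      med <- median(d[[j]])
      iqr <- quantile(d[[j]], 0.75) - quantile(d[[j]], 0.25)
      if (abs(d[i, j] - med) > 1.5 * iqr) keep[i] <- FALSE
    }
    expect_equal(nrow(res$table), sum(keep))
    # re-applying the rule with the ORIGINAL statistics changes nothing
    st <- res$stats
    again <- vapply(seq_len(nrow(res$table)), function(i)
      any(abs(unlist(res$table[i, ]) - st$median) > 1.5 * st$iqr), TRUE)
    expect_false(any(again))
  }
})

test_that("per-class filtering screens within each class", {
  # 200 is an outlier within class v, but the pooled (bimodal) IQR is so
  # wide that the global rule does not see it
  d <- data.frame(a = c(1, 2, 3, 4, 5, 100, 101, 102, 103, 200),
                  class = factor(rep(c("u", "v"), each = 5)))
  expect_equal(nrow(remove_outliers(d)$table), 10)
  res_class <- remove_outliers(d, per_class = TRUE)
  expect_equal(nrow(res_class$table), 9)
  expect_equal(res_class$removed$a, 200)
})
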
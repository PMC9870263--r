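# Bland-Altman agreement, regression, error metrics, paired comparisons.

test_that("bland_altman handles constant offsets and the RPC closed form", {
  x <- sin(1:200) * 30
  ba <- bland_altman(x + 2, x)
  expect_equal(ba$m_dif, 2)
  expect_equal(ba$sd, 0)
  expect_equal(ba$rpc, 0)
  expect_equal(ba$ula, 2)
  expect_equal(ba$lla, 2)
  # a difference series with sample sd exactly 1 gives RPC exactly 1.96
  d <- c(-1, 0, 1) / sd(c(-1, 0, 1))
  expect_equal(sd(d), 1)
  ba1 <- bland_altman(d, rep(0, 3))
  expect_equal(ba1$rpc, 1.96)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("bland_altman matches the direct-formula oracle on random pairs", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:80, 1)
    s <- rnorm(n, 10, 8); r <- s + rnorm(n, 1, 2)
    ba <- bland_altman(s, r)
    o <- ba_oracle(s, r)
    expect_equal(ba$m_dif, o$m_dif, tolerance = 1e-12)
    expect_equal(ba$sd, o$sd, tolerance = 1e-12)
    expect_equal(ba$rpc, o$rpc, tolerance = 1e-12)
    expect_equal(ba$ula, o$ula, tolerance = 1e-12)
    expect_equal(ba$lla, o$lla, tolerance = 1e-12)
    expect_equal(ba$ula - ba$lla, 2 * ba$rpc, tolerance = 1e-12)
    expect_equal(ba$rpc, 1.96 * ba$sd, tolerance = 1e-12)
  }
})

test_that("agreement symmetry, scale and zeroing-shift properties hold", {
  set.seed(42)
  s <- rnorm(300, 20, 10); r <- s + rnorm(300, 2, 3)
  f <- bland_altman(s, r); g <- bland_altman(r, s)
  expect_equal(g$m_dif, -f$m_dif)
  expect_equal(g$ula, -f$lla)
  expect_equal(g$lla, -f$ula)
  expect_equal(g$rpc, f$rpc)
  ef <- error_metrics(s, r); eg <- error_metrics(r, s)
  expect_equal(eg$mae, ef$mae)
  expect_equal(eg$rmse, ef$rmse)
  # scale equivariance
  k <- -2.5
  fk <- bland_altman(k * s, k * r)
  expect_equal(fk$rpc, abs(k) * f$rpc, tolerance = 1e-12)
  expect_equal(fk$m_dif, k * f$m_dif, tolerance = 1e-12)
  expect_equal(error_metrics(k * s, k * r)$rmse, abs(k) * ef$rmse,
               tolerance = 1e-12)
  expect_equal(linear_fit(k * s, k * r)$r2, linear_fit(s, r)$r2,
               tolerance = 1e-12)
  # re-zeroing the reference by c moves the bias by +c, spread unchanged
  c0 <- 4.2
  fz <- bland_altman(s, r - c0)
  expect_equal(fz$m_dif, f$m_dif + c0, tolerance = 1e-12)
  expect_equal(fz$sd, f$sd, tolerance = 1e-12)
})

test_that("linear_fit recovers exact lines and matches the OLS oracle", {
  x <- seq(-20, 60, length.out = 200)
  f <- linear_fit(x, 0.85 * x + 2)
  expect_equal(f$m, 0.85, tolerance = 1e-12)
  expect_equal(f$b, 2, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  ident <- linear_fit(x, x)
  expect_equal(ident$m, 1, tolerance = 1e-12)
  expect_equal(ident$b, 0, tolerance = 1e-10)
  set.seed(43)
  for (i in 1:100) {
    n <- sample(10:100, 1)
    s <- rnorm(n, 15, 12); r <- 0.9 * s + 1 + rnorm(n, 0, 2)
    f <- linear_fit(s, r)
    o <- ols_oracle(s, r)
    expect_equal(f$m, o$m, tolerance = 1e-9)
    expect_equal(f$b, o$b, tolerance = 1e-9)
    expect_equal(f$r2, o$r2, tolerance = 1e-9)
  }
  # orientation switch swaps predictor and response
  s <- rnorm(50, 0, 10); r <- 2 * s + rnorm(50)
  sw <- linear_fit(s, r, orientation = "sensor_on_ref")
  o2 <- ols_oracle(r, s)
  expect_equal(sw$m, o2$m, tolerance = 1e-9)
  expect_error(linear_fit(rep(3, 10), rnorm(10)), "zero-variance")
})

test_that("error metrics match hand-computed values", {
  x <- rep(0, 4)
  e <- error_metrics(c(-1, 0, 1, 2), x)
  expect_equal(e$mae, 1)
  expect_equal(e$rmse, sqrt(1.5))
  same <- error_metrics(x, x)
  expect_equal(same$mae, 0)
  expect_equal(same$rmse, 0)
  off <- error_metrics(x + 3, x)
  expect_equal(off$mae, 3)
  expect_equal(off$rmse, 3)
  expect_lte(e$mae, e$rmse)
  expect_error(error_metrics(1:3, 1:4), "length mismatch")
})

metric_table <- function(participants, seed) {
  set.seed(seed)
  df <- data.frame(participant = participants)
  for (m in c("m_dif", "rpc", "ula", "lla", "r2", "m", "b", "mae", "rmse")) {
    df[[m]] <- rnorm(length(participants))
  }
  df
}

test_that("compare_timepoints matches the textbook paired-t oracle", {
  t1 <- metric_table(sprintf("P%02d", 1:12), seed = 44)
  t2 <- metric_table(sprintf("P%02d", 1:12), seed = 45)
  cmp <- compare_timepoints(t1, t2, alpha = 0.05)
  expect_identical(nrow(cmp), 9L)
  for (i in seq_len(nrow(cmp))) {
    m <- cmp$metric[i]
    o <- paired_t_oracle(t2[[m]], t1[[m]])
    expect_equal(cmp$t_stat[i], o$t, tolerance = 1e-9)
    expect_equal(cmp$p_value[i], o$p, tolerance = 1e-9)
    expect_equal(cmp$mean_diff[i], mean(t2[[m]] - t1[[m]]), tolerance = 1e-12)
    expect_identical(cmp$significant[i], cmp$p_value[i] < 0.05)
  }
  # identical tables: zero differences, p = 1 (degenerate, warned per metric)
  w <- capture_warnings(same <- compare_timepoints(t1, t1))
  expect_length(w, 9)
  expect_true(all(grepl("zero-variance", w)))
  expect_true(all(same$mean_diff == 0))
  expect_true(all(same$p_value == 1))
  expect_false(any(same$significant))
  # constant shift: zero-variance differences with non-zero mean -> p = 0
  t2c <- t1
  t2c$mae <- t1$mae + 3
  shift <- suppressWarnings(compare_timepoints(t1, t2c))
  expect_equal(shift$p_value[shift$metric == "mae"], 0)
  expect_true(shift$significant[shift$metric == "mae"])
})

test_that("compare_timepoints validates the participant sets", {
  t1 <- metric_table(c("P01", "P02", "P03"), seed = 46)
  t2 <- metric_table(c("P01", "P02", "P04"), seed = 47)
  expect_error(compare_timepoints(t1, t2), "P0[34]")
  # order of rows must not matter
  t2b <- metric_table(c("P03", "P01", "P02"), seed = 48)
  cmp <- compare_timepoints(t1, t2b)
  o <- paired_t_oracle(t2b$mae[match(t1$participant, t2b$participant)], t1$mae)
  expect_equal(cmp$t_stat[cmp$metric == "mae"], o$t, tolerance = 1e-9)
})

test_that("summarize_cohort averages metrics and pools samples", {
  one <- metric_table("P01", seed = 49)
  one$joint <- "hip"; one$timepoint <- "T1"; one$variant <- "raw"
  s1 <- summarize_cohort(one)
  expect_equal(s1$cohort$m_dif_mean, one$m_dif)
  expect_equal(s1$cohort$m_dif_sd, 0)
  many <- do.call(rbind, lapply(1:8, function(i) {
    df <- metric_table(sprintf("P%02d", i), seed = 50 + i)
    df$joint <- "knee"; df$timepoint <- "T2"; df$variant <- "zeroed"
    df
  }))
  s2 <- summarize_cohort(many)
  expect_equal(s2$cohort$rpc_mean, mean(many$rpc), tolerance = 1e-12)
  expect_equal(s2$cohort$rpc_sd, sd(many$rpc), tolerance = 1e-12)
  # pooling concatenates participants before one agreement pass
  set.seed(59)
  cells <- lapply(1:3, function(i) {
    s <- rnorm(100, 20, 10)
    list(sensor = s, reference = s + rnorm(100, 1, 2))
  })
  s3 <- summarize_cohort(one, pooled_pairs = list(hip.T1.raw = cells))
  all_s <- unlist(lapply(cells, `[[`, "sensor"))
  all_r <- unlist(lapply(cells, `[[`, "reference"))
  expect_identical(s3$pooled$hip.T1.raw$errors$n, 300L)
  expect_equal(s3$pooled$hip.T1.raw$bland_altman$m_dif, mean(all_s - all_r),
               tolerance = 1e-12)
})
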
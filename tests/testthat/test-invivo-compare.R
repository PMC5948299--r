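test_that("subject peaks are the maximal-magnitude samples", {
  tr <- generate_load_traces(default_activity_specs(), n_subjects = 2,
                             seed = 8)
  pk <- extract_peaks_and_range(tr)
  expect_equal(nrow(pk$peaks), 2)
  expect_equal(pk$peaks$magnitude_N, rep(2700, 2), tolerance = 1e-9)
  expect_equal(pk$peaks$activity, rep("walking", 2))
  expect_error(extract_peaks_and_range(tr[0, ]), "empty")
})

test_that("peak extraction is invariant to row order and ties break earliest", {
  tr <- generate_load_traces(default_activity_specs(), 3, seed = 12)
  set.seed(1)
  shuf <- tr[sample(nrow(tr)), ]
  a <- extract_peaks_and_range(tr)
  b <- extract_peaks_and_range(shuf)
  expect_equal(a$peaks$magnitude_N, b$peaks$magnitude_N)
  expect_equal(a$inclination_range, b$inclination_range)
  ## two equal maxima: the earliest sample wins
  tt <- data.frame(subject = "S1", activity = "x",
                   time_s = c(0.1, 0.2, 0.3),
                   f_ml_N = c(0, 0, 0), f_ap_N = 0,
                   f_vert_N = c(500, 900, 900))
  pk <- extract_peaks_and_range(tt)
  expect_equal(pk$peaks$time_s, 0.2)
})

test_that("group summaries reproduce the published mean and SD rows", {
  tab <- table2_fixture()
  so <- summarize_mean_sd(tab$cov_opt)
  expect_equal(so$mean, 139.29, tolerance = 0.005)
  expect_equal(so$sd, 9.17, tolerance = 0.005)
  si <- summarize_mean_sd(tab$cov_init)
  expect_equal(si$mean, 467.67, tolerance = 0.005)
  expect_equal(si$sd, 394.86, tolerance = 0.005)
  expect_equal(summarize_mean_sd(rep(5, 4))$sd, 0)
  one <- summarize_mean_sd(3)
  expect_false(one$sd_defined)
})

test_that("summaries match a brute-force two-pass oracle", {
  set.seed(2)
  for (rep in 1:5) {
    x <- rnorm(sample(5:40, 1), 10, 4)
    s <- summarize_mean_sd(x)
    expect_lt(abs(s$mean - sum(x) / length(x)), 1e-12)
    expect_lt(abs(s$sd - sqrt(sum((x - sum(x) / length(x))^2) /
                                (length(x) - 1))), 1e-12)
  }
})

test_that("the CoV pairs give W = 0 and the exact enumeration p", {
  tab <- table2_fixture()
  w <- wilcoxon_signed_rank(tab$cov_init, tab$cov_opt)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 2 / 2^10, tolerance = 1e-9)
  expect_equal(w$p_value, wilcoxon_enum_oracle(tab$cov_init, tab$cov_opt),
               tolerance = 1e-12)
  ## the normal approximation is exposed behind a flag
  wn <- wilcoxon_signed_rank(tab$cov_init, tab$cov_opt, exact = FALSE)
  expect_equal(wn$method, "normal approximation")
  expect_gt(wn$p_value, w$p_value)
})

test_that("exact p equals full sign enumeration on random pairs", {
  set.seed(6)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    before <- rnorm(n, 10, 2)
    after <- before - rnorm(n, 0.5, 1.5)
    expect_equal(wilcoxon_signed_rank(before, after)$p_value,
                 wilcoxon_enum_oracle(before, after), tolerance = 1e-12)
  }
})

test_that("symmetric alternating pairs show no effect", {
  d <- c(1, -1.2, 1.4, -1.6, 1.8, -2, 2.2, -2.4)
  before <- rep(10, 8)
  w <- wilcoxon_signed_rank(before, before - d)
  expect_gt(w$p_value, 0.5)
  expect_error(wilcoxon_signed_rank(rep(1, 8), rep(1, 8)), "zero")
  expect_error(wilcoxon_signed_rank(1:3, c(2, 3, 4)), "at least 5")
})

test_that("comparison reports carry summaries, ranges and deltas", {
  pred <- data.frame(magnitude_N = rep(3000, 5),
                     inclination_deg = rep(20, 5))
  invv <- data.frame(magnitude_N = rep(3000, 5),
                     inclination_deg = rep(20, 5))
  same <- compare_invivo(pred, invv, c(-20, 100), c(3.7, 66.6))
  expect_equal(same$delta_magnitude, 0)
  expect_equal(same$delta_inclination, 0)

  pred2 <- data.frame(magnitude_N = c(3000, 3200),
                      inclination_deg = c(20, 20))
  invv2 <- data.frame(magnitude_N = c(2700, 2700),
                      inclination_deg = c(18.2, 18.2))
  cmp <- compare_invivo(pred2, invv2)
  expect_equal(cmp$delta_inclination, 1.8, tolerance = 1e-9)
  one <- compare_invivo(pred2[1, ], invv2[1, ])
  expect_false(one$predicted$magnitude$sd_defined)
  expect_error(compare_invivo(pred2, invv2, predicted_range = c(5, 1)),
               "min <= max")
})

test_that("comparison reports write a CSV and a text rendering", {
  pred <- data.frame(magnitude_N = c(3000, 3200),
                     inclination_deg = c(20, 22))
  invv <- data.frame(magnitude_N = c(2700, 2500),
                     inclination_deg = c(18, 17))
  cmp <- compare_invivo(pred, invv, c(-20, 100), c(3.7, 66.6))
  p <- file.path(tempdir(), "cmp.csv")
  write_comparison_report(cmp, p)
  back <- utils::read.csv(p)
  expect_equal(nrow(back), 2)
  expect_true(file.exists(sub("\\.csv$", ".txt", p)))
})
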
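test_that("descriptive reproduces the bundled cohort T1 table at one decimal", {
  tab <- cohort_t1_table()
  expect_equal(round(descriptive(tab$gm_t1), 1), c(mean = 1442.8, sd = 179.7))
  expect_equal(round(descriptive(tab$wm_t1), 1), c(mean = 900.2, sd = 60.7))
  expect_equal(round(descriptive(tab$csf_t1), 1), c(mean = 4042.9, sd = 115.8))
})

test_that("descriptive reproduces the bundled rCBF table and handles edge cases", {
  tab <- cohort_rcbf_table()
  expect_equal(round(descriptive(tab$rcbf_regular), 1), c(mean = 558.0, sd = 72.1))
  expect_equal(round(descriptive(tab$rcbf_adaptive), 1), c(mean = 572.2, sd = 70.0))
  expect_equal(descriptive(c(5, 5, 5)), c(mean = 5, sd = 0))
  expect_error(descriptive(7), class = "aslbs_data_error")
  expect_error(descriptive(c(1, NA)), class = "aslbs_data_error")
})

test_that("descriptive is permutation-invariant and translation-equivariant", {
  set.seed(12)
  x <- rnorm(20)
  p <- descriptive(x)
  expect_equal(descriptive(sample(x)), p)
  q <- descriptive(x + 100)
  expect_equal(q[["mean"]], p[["mean"]] + 100)
  expect_equal(q[["sd"]], p[["sd"]])
})

test_that("the exact Wilcoxon test reproduces the rCBF comparison", {
  tab <- cohort_rcbf_table()
  res <- wilcoxon_signed_rank_exact(tab$rcbf_regular, tab$rcbf_adaptive)
  expect_equal(res$n_effective, 10L)
  expect_equal(res$w_statistic, 0)     # every adaptive value is larger
  expect_equal(res$p_two_sided, 2 / 1024)
  expect_lt(res$p_two_sided, 0.005)
})

test_that("hand-enumerated three-pair case gives W = 0, p = 0.25", {
  res <- wilcoxon_signed_rank_exact(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$w_statistic, 0)
  expect_equal(res$p_two_sided, 0.25)
})

test_that("degenerate and malformed inputs are rejected", {
  expect_error(wilcoxon_signed_rank_exact(1:4, 1:4), class = "aslbs_data_error")
  expect_error(wilcoxon_signed_rank_exact(1:4, 1:5), class = "aslbs_data_error")
  expect_error(wilcoxon_signed_rank_exact(1:25, 25:1), class = "aslbs_parameter_error")
})

test_that("exact p agrees with brute-force sign enumeration on random data", {
  set.seed(2024)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    x <- sample(0:8, n, replace = TRUE)
    y <- sample(0:8, n, replace = TRUE)
    if (all(x == y)) next
    res <- wilcoxon_signed_rank_exact(x, y)
    expect_equal(res$p_two_sided, oracle_wilcoxon_p(x, y),
                 info = sprintf("case %d: x=%s y=%s", i,
                                paste(x, collapse = ","),
                                paste(y, collapse = ",")))
    expect_gte(res$p_two_sided, 0)
    expect_lte(res$p_two_sided, 1)
    expect_lte(res$w_statistic, res$n_effective * (res$n_effective + 1) / 2)
  }
})

test_that("for a constant positive shift, p decreases as the cohort grows", {
  ps <- vapply(5:10, function(n) {
    x <- seq_len(n) * 10
    wilcoxon_signed_rank_exact(x, x + 3)$p_two_sided
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("tally_ratings reproduces the bundled reader-study sum row", {
  tal <- tally_ratings(reader_ratings_table())
  get <- function(rd, cat) tal$sum[tal$reader == rd & tal$category == cat]
  expect_equal(get(1, "noise"), 7)
  expect_equal(get(2, "noise"), 3)
  expect_equal(get(1, "cortical_structures"), 5)
  expect_equal(get(2, "cortical_structures"), 3)
  expect_equal(get(1, "artifacts"), -1)
  expect_equal(get(2, "artifacts"), -1)
})

test_that("tally_ratings handles zero tables and rejects off-scale values", {
  tab <- expand.grid(case = 1:4, reader = 1:2,
                     category = c("noise", "artifacts"))
  tab$rating <- 0L
  tal <- tally_ratings(tab)
  expect_true(all(tal$sum == 0))
  tab$rating[1] <- 2L
  expect_error(tally_ratings(tab), class = "aslbs_data_error")
  expect_error(tally_ratings(data.frame()), class = "aslbs_data_error")
})
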
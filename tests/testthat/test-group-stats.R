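test_that("describe_sample returns the sample moments", {
  expect_equal(describe_sample(c(2, 2, 2)),
               list(n = 3, mean = 2, sd = 0, min = 2, max = 2))
  expect_equal(describe_sample(c(1, 2, 3)),
               list(n = 3, mean = 2, sd = 1, min = 1, max = 3))
  expect_error(describe_sample(numeric(0)), "empty")
  s <- describe_sample(c(NA, 5))
  expect_equal(s$n, 1)
  expect_true(is.na(s$sd))
})

test_that("spearman_cor handles monotone, tied, and degenerate inputs", {
  expect_equal(spearman_cor(1:10, exp(1:10))$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10)^3)$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
  # agreement with the reference implementation, with and without ties
  set.seed(42)
  for (i in 1:20) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- x + rnorm(12, 0, 2)
    ours <- spearman_cor(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(ours$rho, unname(ref$estimate))
  }
})

test_that("midranks match the brute-force tie-enumeration oracle", {
  for (x in list(c(3, 1, 1, 2), c(5, 5, 5, 1, 2), c(2, 4, 4, 2, 4, 1))) {
    expect_equal(rank(x), midranks_by_enumeration(x))
  }
  # hence rho on a tied sample equals the enumeration-based correlation
  x <- c(3, 1, 1, 2, 2, 4)
  y <- c(10, 3, 4, 4, 6, 9)
  expect_equal(spearman_cor(x, y)$rho,
               cor(midranks_by_enumeration(x), midranks_by_enumeration(y)))
})

test_that("the t-approximate p-value matches its closed form and the exact p is calibrated", {
  x <- c(1, 4, 2, 8, 5, 7, 3)
  y <- c(2, 5, 1, 9, 4, 8, 2.5)
  res <- spearman_cor(x, y)
  tref <- res$rho * sqrt(5 / (1 - res$rho^2))
  expect_equal(res$statistic, tref)
  expect_equal(res$p_value, 2 * pt(-abs(tref), 5))
  ex <- spearman_cor(x, y, method = "exact")
  expect_equal(ex$rho, res$rho)
  expect_gte(ex$p_value, 1 / factorial(7))
  expect_lte(ex$p_value, 1)
  # exact p agrees with cor.test's exact method on an untied sample
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(ex$p_value, ref$p.value, tolerance = 1e-10)
  expect_error(spearman_cor(1:9, 9:1, method = "exact"), "n <= 8")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(1)
  x <- rnorm(30); y <- x + rnorm(30)
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, base)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, base)
  expect_equal(spearman_cor(1 / (1 + exp(-x)), y)$rho, base)
})

test_that("welch_t_from_summary matches t.test on raw data", {
  set.seed(2)
  x <- rnorm(15, 10, 2); y <- rnorm(40, 11, 5)
  ours <- welch_t(x, y)
  ref <- t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p_value, ref$p.value)
})

test_that("welch from summaries: degenerate and pooled-identity cases", {
  s <- list(n = 10, mean = 3, sd = 1.5)
  same <- welch_t_from_summary(s, s)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # equal n and sd: Welch equals the pooled-variance t exactly
  s1 <- list(n = 12, mean = 5, sd = 2); s2 <- list(n = 12, mean = 6.5, sd = 2)
  ours <- welch_t_from_summary(s1, s2)
  pooled_t <- (5 - 6.5) / (2 * sqrt(2 / 12))
  expect_equal(ours$statistic, pooled_t)
  expect_equal(ours$df, 22)
  expect_error(welch_t_from_summary(list(n = 1, mean = 0, sd = 0), s), "n >= 2")
})

test_that("published posture summaries separate standing from lying areas", {
  a <- list(n = 185, mean = 0.288, sd = 0.026)
  ll <- list(n = 30, mean = 0.486, sd = 0.040)
  expect_lt(welch_t_from_summary(a, ll)$p_value, 0.001)
})

test_that("pairwise comparison gives one letter to indistinguishable groups", {
  sm <- data.frame(group = c("g1", "g2", "g3"), n = c(10, 10, 10),
                   mean = c(5, 5, 5), sd = c(1, 1, 1))
  pw <- pairwise_group_comparison(summaries = sm)
  expect_true(all(pw$pairs$p_adj > 0.99))
  expect_equal(unname(pw$letters), c("a", "a", "a"))
})

test_that("two-group Tukey equals the closed-form studentized-range p", {
  sm <- data.frame(group = c("x", "y"), n = c(8, 14),
                   mean = c(2.0, 3.1), sd = c(0.9, 1.1))
  pw <- pairwise_group_comparison(summaries = sm)
  mse <- (7 * 0.9^2 + 13 * 1.1^2) / 20
  q <- abs(2.0 - 3.1) / sqrt(mse / 2 * (1 / 8 + 1 / 14))
  expect_equal(pw$pairs$p_adj, ptukey(q, 2, 20, lower.tail = FALSE))
})

test_that("pairwise comparison agrees with TukeyHSD on raw data", {
  set.seed(3)
  d <- data.frame(g = rep(c("a", "b", "c", "d"), times = c(8, 12, 9, 15)))
  d$v <- rnorm(nrow(d), mean = c(a = 0, b = 0.5, c = 2, d = 0.2)[d$g])
  pw <- pairwise_group_comparison(d$v, d$g)
  ref <- TukeyHSD(aov(v ~ g, data = d))$g
  key <- paste(pw$pairs$group2, pw$pairs$group1, sep = "-")
  expect_equal(pw$pairs$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-8)
  expect_equal(-pw$pairs$diff, unname(ref[key, "diff"]))
})

test_that("Tukey-adjusted p-values are never smaller than the unadjusted pair p", {
  set.seed(4)
  d <- data.frame(g = rep(letters[1:5], each = 10), v = rnorm(50))
  pw <- pairwise_group_comparison(d$v, d$g)
  for (r in seq_len(nrow(pw$pairs))) {
    raw <- t.test(d$v[d$g == pw$pairs$group1[r]],
                  d$v[d$g == pw$pairs$group2[r]], var.equal = TRUE)$p.value
    expect_gte(pw$pairs$p_adj[r] + 1e-12, raw)
  }
  expect_true(all(pw$pairs$p_adj >= 0 & pw$pairs$p_adj <= 1))
})

test_that("a weight cohort matched to the study singles out E vs CS", {
  # stochastic direction check over a fixed seed: the only pair expected
  # to differ is the lightest (E) vs heaviest (CS) group
  set.seed(5)
  d <- do.call(rbind, lapply(seq_len(13), function(i) {
    r <- study_tab[i, ]
    data.frame(g = r$posture,
               w = rnorm(r$n_images, r$weight_mean, r$weight_sd))
  }))
  pw <- pairwise_group_comparison(d$w, d$g)
  sig <- pw$pairs[pw$pairs$p_adj < 0.05, ]
  expect_true(any(sig$group1 == "CS" & sig$group2 == "E" |
                  sig$group1 == "E" & sig$group2 == "CS"))
  expect_lte(nrow(sig), 2)
  expect_equal(nchar(pw$letters[["E"]]), 1)
  expect_false(grepl(pw$letters[["E"]], pw$letters[["CS"]], fixed = TRUE))
})

test_that("significance letters split and absorb correctly on a known pattern", {
  pairs <- data.frame(group1 = c("a", "a", "b"), group2 = c("b", "c", "c"),
                      p_adj = c(0.01, 0.20, 0.30))
  out <- significance_letters(pairs, c("a", "b", "c"))
  expect_false(any(strsplit(out[["a"]], "")[[1]] %in%
                   strsplit(out[["b"]], "")[[1]]))
  expect_true(any(strsplit(out[["a"]], "")[[1]] %in%
                  strsplit(out[["c"]], "")[[1]]))
  expect_true(any(strsplit(out[["b"]], "")[[1]] %in%
                  strsplit(out[["c"]], "")[[1]]))
})
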
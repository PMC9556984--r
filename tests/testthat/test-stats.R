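# The signed-rank conventions (smaller rank sum, tie-corrected sigma, no
# continuity correction, normal approximation at any n) are checked against
# closed forms, hand rankings and base R oracles.

test_that("signed-rank Z matches hand computation on canonical inputs", {
  # all same sign, no ties: T = 0
  w11 <- wilcoxon_signed_rank(1:11)
  expect_near(w11$statistic, -2.934)
  expect_near(w11$p, 0.003)
  w3 <- wilcoxon_signed_rank(-(1:3))
  expect_near(w3$statistic, -1.604)
  expect_near(w3$p, 0.109)
  # hand ranking: {1,2,3,-4,5} -> T- = 4
  w5 <- wilcoxon_signed_rank(c(1, 2, 3, -4, 5))
  expect_near(w5$t_minus, 4)
  expect_near(w5$statistic, -0.944)
  expect_near(w5$p, 0.345)
  # smaller rank sums 2 (n=3) and 10 (n=11)
  expect_near(wilcoxon_signed_rank(c(1, -2, 3))$statistic, -0.535)
  expect_near(wilcoxon_signed_rank(c(1:9, -10, 11))$statistic, -2.045)
})

test_that("all-same-sign Z follows the closed form for n = 3..20", {
  for (n in 3:20) {
    z <- wilcoxon_signed_rank(seq_len(n))$statistic
    expect_equal(z, -(n * (n + 1) / 4) / sqrt(n * (n + 1) * (2 * n + 1) / 24),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank agrees with the base R normal-approximation oracle", {
  set.seed(11)
  for (i in 1:10) {
    d <- round(stats::rnorm(12), 2)
    d <- d[d != 0]
    ours <- wilcoxon_signed_rank(d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = FALSE))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("signed-rank is invariant under monotone magnitude transforms", {
  d <- c(0.3, -1.2, 2.5, 4.1, -0.7, 3.3)
  a <- wilcoxon_signed_rank(d)
  b <- wilcoxon_signed_rank(sign(d) * abs(d)^3)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p, b$p)
})

test_that("degenerate signed-rank inputs are rejected", {
  expect_error(wilcoxon_signed_rank(rep(0, 5)), class = "vaaflow_undefined_test")
  expect_error(wilcoxon_signed_rank(c(1, NA)), class = "vaaflow_data_error")
})

test_that("two-sample t behaves as Student/Welch with graceful degeneracies", {
  r <- student_t_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_near(r$statistic, -3.674)
  expect_equal(r$df, 4)
  expect_near(r$p, 0.021)
  # symmetry
  r2 <- student_t_two_sample(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p, r$p)
  # identical degenerate groups
  same <- student_t_two_sample(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(student_t_two_sample(c(2, 2), c(3, 3)), class = "vaaflow_infinite_t")
  # Welch mode against base R
  a <- c(1.1, 2.3, 2.9, 4.2); b <- c(2.0, 6.5, 8.1)
  expect_equal(student_t_two_sample(a, b, welch = TRUE)$p,
               stats::t.test(a, b)$p.value)
})

test_that("Fisher exact two-sided p follows the probability-sum rule", {
  expect_near(fisher_exact_2x2(matrix(c(6, 0, 3, 5), 2))$p, 0.031)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p, 2 / 252,
               tolerance = 1e-10)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               class = "vaaflow_invalid_table")
})

test_that("Fisher p equals brute-force enumeration and the base R oracle", {
  # enumeration oracle over all tables with fixed margins
  enum_p <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    a_all <- max(0, r1 + c1 - n):min(r1, c1)
    pr <- vapply(a_all, function(a) {
      choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
    }, numeric(1))
    p_obs <- pr[a_all == tab[1, 1]]
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
  set.seed(4)
  for (i in 1:12) {
    tab <- matrix(stats::rpois(4, 4), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)$p
    expect_equal(p, enum_p(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("chi-square is uncorrected Pearson with the low-count warning", {
  z <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(z$statistic, 0)
  expect_equal(z$p, 1)
  expect_warning(chi_square_2x2(matrix(c(6, 0, 3, 5), 2)), "Fisher")
  t1 <- suppressWarnings(chi_square_2x2(matrix(c(6, 0, 3, 5), 2)))
  t2 <- suppressWarnings(chi_square_2x2(t(matrix(c(6, 0, 3, 5), 2))))
  expect_equal(t1$statistic, t2$statistic)
  ref <- suppressWarnings(stats::chisq.test(matrix(c(6, 0, 3, 5), 2),
                                            correct = FALSE))
  expect_equal(t1$statistic, unname(ref$statistic))
  expect_equal(t1$p, ref$p.value)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 5), 2)),
               class = "vaaflow_undefined_test")
})

test_that("p-values are valid and monotone in |Z|", {
  zs <- c(); ps <- c()
  for (n in 3:12) {
    w <- wilcoxon_signed_rank(seq_len(n))
    zs <- c(zs, w$statistic); ps <- c(ps, w$p)
  }
  expect_true(all(ps >= 0 & ps <= 1))
  ord <- order(abs(zs))
  expect_true(all(diff(ps[ord]) <= 1e-12))
})

test_that("the region battery tabulates strata, metrics and comparisons", {
  # synthetic summaries: aneurysm cell always above para in 'high' models,
  # below in 'low' models, distinct magnitudes (no ties)
  mk_summary <- function(an, up, dn) {
    metrics <- matrix(0, 3, 5, dimnames = list(
      c("aneurysm", "upstream", "downstream"),
      c("tawss_pa", "osi", "wssg_nm3", "afi", "wssmax_pa")))
    metrics["aneurysm", ] <- an
    metrics["upstream", ] <- up
    metrics["downstream", ] <- dn
    structure(list(metrics = metrics,
                   para = (metrics["upstream", ] + metrics["downstream", ]) / 2,
                   areas_m2 = rep(1e-5, 3)),
              class = "vaa_region_summary")
  }
  set.seed(2)
  summaries <- c(
    lapply(1:11, function(i) mk_summary(2 + i / 10, 1 + i / 50, 1 + i / 40)),
    lapply(1:3, function(i) mk_summary(0.2 + i / 100, 0.5 + i / 30, 0.5 + i / 20)))
  groups <- c(lapply(1:11, function(i) structure(list(group = "high"), class = "vaa_group")),
              lapply(1:3, function(i) structure(list(group = "low"), class = "vaa_group")))
  tab <- run_table3_battery(summaries, groups)
  expect_equal(nrow(tab), 45)  # 3 strata x 5 metrics x 3 comparisons
  hi <- tab[tab$stratum == "high" & tab$comparison == "para", ]
  expect_near(hi$Z, rep(-2.934, 5))
  lo <- tab[tab$stratum == "low" & tab$comparison == "para", ]
  expect_near(lo$Z, rep(-1.604, 5))
  # permutation invariance
  perm <- sample(length(summaries))
  tab2 <- run_table3_battery(summaries[perm], groups[perm])
  expect_equal(tab$Z, tab2$Z)
})
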
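test_that("Mann-Whitney exact p by enumeration: frozen and oracle cases", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(as.numeric(res$statistic), 0)
  expect_equal(res$p_value, 0.1)   # 2/20 labelings as extreme
  # identical multisets: complete overlap
  expect_equal(mann_whitney_u(c(1, 2, 5), c(1, 2, 5))$p_value, 1)
  # cross-check exact enumeration against the independent implementation
  set.seed(3)
  for (i in 1:5) {
    x <- stats::rnorm(5); y <- stats::rnorm(6)
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney exact and asymptotic p agree within 0.02 at n=8+8", {
  set.seed(11)
  for (i in 1:10) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    pe <- mann_whitney_u(x, y, mode = "exact")$p_value
    pa <- mann_whitney_u(x, y, mode = "asymptotic")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("asymptotic mode handles ties like the tie-corrected reference", {
  x <- c(1, 2, 2, 3, 5, 5, 5); y <- c(2, 3, 3, 4, 5, 6)
  res <- mann_whitney_u(x, y, mode = "asymptotic")
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(as.numeric(res$statistic), as.numeric(ref$statistic))
})

test_that("Kruskal-Wallis: frozen rank-arithmetic value, ties, degeneracy", {
  # independent rank arithmetic for [1,2],[3,4],[5,6]:
  # H = 12/(6*7) * (3^2/2 + 7^2/2 + 11^2/2) - 3*7 = 32/7
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(as.numeric(res$statistic), 32 / 7, tolerance = 1e-12)
  expect_equal(res$p_value,
               stats::pchisq(32 / 7, 2, lower.tail = FALSE))
  # all identical observations
  res0 <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(as.numeric(res0$statistic), 0)
  expect_equal(res0$p_value, 1)
  # tie-corrected H matches the independent implementation
  set.seed(5)
  g <- list(sample(1:4, 8, TRUE), sample(1:4, 7, TRUE), sample(1:4, 9, TRUE))
  expect_equal(as.numeric(kruskal_wallis(g)$statistic),
               as.numeric(stats::kruskal.test(g)$statistic),
               tolerance = 1e-12)
})

test_that("two-group Kruskal-Wallis equals asymptotic Mann-Whitney without
           continuity correction", {
  set.seed(8)
  for (i in 1:5) {
    x <- stats::rnorm(9); y <- stats::rnorm(7) + 0.5
    pk <- kruskal_wallis(list(x, y))$p_value
    pm <- mann_whitney_u(x, y, mode = "asymptotic",
                         continuity = FALSE)$p_value
    expect_lt(abs(pk - pm), 1e-6)
  }
})

test_that("Dunn post hoc matches hand rank-sum arithmetic and Bonferroni
           monotonicity", {
  g <- list(a = c(1, 3, 5, 7), b = c(2, 4, 6, 8), c = c(10, 11, 12, 13))
  res <- dunn_posthoc(g, adjustment = "bonferroni")
  tab <- res$pairwise
  # hand computation: ranks 1..12 (no ties), mean ranks 4, 5, 10.5;
  # sigma^2 = N(N+1)/12 = 13, se = sqrt(13 * 2/4)
  se <- sqrt(13 * 0.5)
  expect_equal(tab$z[tab$group_i == "a" & tab$group_j == "b"], -1 / se,
               tolerance = 1e-12)
  expect_equal(tab$z[tab$group_i == "a" & tab$group_j == "c"], -6.5 / se,
               tolerance = 1e-12)
  expect_true(all(tab$p_adjusted >= tab$p))
  # two identical groups among three: their z is 0, p 1
  g2 <- list(x = c(1, 2), y = c(1, 2), z = c(9, 10))
  t2 <- dunn_posthoc(g2, adjustment = "none")$pairwise
  row <- t2[t2$group_i == "x" & t2$group_j == "y", ]
  expect_equal(row$z, 0)
  expect_equal(row$p, 1)
  expect_error(dunn_posthoc(list(1:3, 4:6)), ">= 3 groups")
})

test_that("pooled t test: symmetry, identity on summaries, degeneracy", {
  set.seed(13)
  x <- stats::rnorm(9, 1); y <- stats::rnorm(12, 0.2)
  res <- students_t(x, y)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(as.numeric(res$statistic), as.numeric(ref$statistic),
               tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # swapping negates t, p unchanged
  swapped <- students_t(y, x)
  expect_equal(as.numeric(swapped$statistic), -as.numeric(res$statistic))
  expect_equal(swapped$p_value, res$p_value)
  # x == y
  expect_equal(students_t(x, x)$p_value, 1)
  expect_equal(as.numeric(students_t(x, x)$statistic), 0)
  # t from summary statistics equals t from raw data
  t_summary <- function(m1, s1, n1, m2, s2, n2) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  expect_equal(as.numeric(res$statistic),
               t_summary(mean(x), sd(x), 9, mean(y), sd(y), 12),
               tolerance = 1e-12)
  # zero pooled variance
  expect_true(students_t(c(1, 1), c(1, 1))$degenerate)
  expect_equal(students_t(c(1, 1), c(2, 2))$p_value, 0)
})

test_that("Fisher exact: frozen enumerations and invariances", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2))$p_value, 0.4857143,
               tolerance = 1e-6)
  expect_equal(fisher_exact(matrix(c(0, 5, 5, 0), 2))$p_value, 2 / 252)
  # independence: proportional rows
  for (ab in list(c(2, 5), c(1, 1), c(4, 2)))
    expect_equal(fisher_exact(rbind(ab, ab))$p_value, 1)
  # zero margin is degenerate
  expect_true(fisher_exact(matrix(c(0, 0, 3, 4), 2))$degenerate)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2))$p_value, 1)
  # symmetry under transposition and row/column swaps; reference agreement
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(stats::rpois(4, 5), 2)
    p <- fisher_exact(m)$p_value
    expect_equal(fisher_exact(t(m))$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact(m[2:1, ])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact(m[, 2:1])$p_value, p, tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("rank tests are invariant under monotone transformations", {
  set.seed(31)
  x <- stats::rnorm(10); y <- stats::rnorm(12, 0.8)
  f <- function(v) exp(v)         # strictly increasing
  expect_equal(mann_whitney_u(x, y)$p_value,
               mann_whitney_u(f(x), f(y))$p_value)
  expect_equal(kruskal_wallis(list(x, y))$p_value,
               kruskal_wallis(list(f(x), f(y)))$p_value)
})

test_that("group_summary reports sem = sd/sqrt(n)", {
  s <- group_summary(c(1, 2, 3, 4), name = "g")
  expect_equal(s$sem, sd(1:4) / 2)
  expect_equal(s$n, 4)
})

# the 2000-replicate null-calibration (type-I error) check lives in
# test-acceptance.R
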
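test_that("the total SVD score counts each marker once", {
  expect_equal(total_svd_score(2, 1, 3, 1, 3), 4L)
  expect_equal(total_svd_score(0, 0, 0, 0, 0), 0L)
  expect_equal(total_svd_score(0, 0, 2, 1, 1), 1L)  # confluent deep WMH only
  expect_equal(total_svd_score(0, 0, 1, 3, 0), 1L)  # periventricular grade 3
  expect_error(total_svd_score(1, 1, 4, 1, 1), "0-3")
  expect_error(total_svd_score(-1, 0, 0, 0, 0), ">= 0")
})

test_that("the score spans exactly 0-4 over the full marker lattice and is monotone", {
  lattice <- expand.grid(lac = 0:2, cmb = 0:2, dwmh = 0:3, pvh = 0:3, pvs = 0:4)
  scores <- total_svd_score(lattice$lac, lattice$cmb, lattice$dwmh,
                            lattice$pvh, lattice$pvs)
  expect_setequal(sort(unique(scores)), 0:4)
  expect_equal(max(scores), 4L)
  # monotone non-decreasing in each marker
  base <- total_svd_score(lattice$lac, lattice$cmb, lattice$dwmh,
                          lattice$pvh, lattice$pvs)
  expect_true(all(total_svd_score(lattice$lac + 1, lattice$cmb, lattice$dwmh,
                                  lattice$pvh, lattice$pvs) >= base))
  expect_true(all(total_svd_score(lattice$lac, lattice$cmb,
                                  pmin(lattice$dwmh + 1, 3),
                                  lattice$pvh, lattice$pvs) >= base))
})

test_that("weighted kappa is 1 for identical ratings and -1 for reversed balanced binaries", {
  x <- c(0, 1, 2, 1, 0, 2, 2, 1)
  expect_equal(weighted_kappa(x, x), 1)
  expect_equal(weighted_kappa(x, x), weighted_kappa(x, x))  # trivially symmetric
  y <- c(0, 1, 0, 1, 0, 1)
  expect_equal(weighted_kappa(y, 1 - y), -1)
  expect_error(weighted_kappa(rep(1, 5), rep(1, 5)), "fewer than 2")
})

test_that("weighted kappa matches the hand-expanded formula on a printed table", {
  tab <- matrix(c(4, 1, 0, 1, 3, 1, 0, 1, 4), 3, 3, byrow = TRUE)
  # reconstruct rating vectors from the contingency table
  a <- rep(rep(1:3, each = 3), as.vector(t(tab)))
  b <- rep(rep(1:3, times = 3), as.vector(t(tab)))
  expect_equal(weighted_kappa(a, b), oracle_weighted_kappa(tab))
  expect_equal(weighted_kappa(b, a), weighted_kappa(a, b))  # symmetry
})

test_that("descriptive summaries use the reporting conventions", {
  df <- tibble::tibble(
    g = rep(c("a", "b"), c(35, 34)),
    x = c(1, 2, 3, rnorm(66, 10, 2)),
    female = c(rep(TRUE, 31), rep(FALSE, 38)),
    grade = rep(c(0, 1, 3, 6, 9), length.out = 69)
  )
  tb <- cohort_table(df, c("x", "female", "grade"), grouping = "g")
  # binary with 31 of 69 positive prints "31 (44.9)"
  expect_equal(tb$overall[tb$variable == "female"], "31 (44.9)")
  expect_equal(tb$kind[tb$variable == "grade"], "ordinal")
  # median/IQR of {0,1,3,6,9} -> 3 (1-6)
  sub <- tibble::tibble(v = c(0, 1, 3, 6, 9))
  expect_equal(cohort_table(sub, "v")$overall, "3 (1-6)")
  smp <- tibble::tibble(v = c(1, 2, 3))
  expect_match(cohort_table(smp, "v")$overall, "^2")
  expect_error(cohort_table(df[0, ], "x", grouping = "g"), "at least one")
})

test_that("group comparisons pick the appropriate test and detect degeneracy", {
  df <- tibble::tibble(g = rep(c("a", "b"), each = 20),
                       const = rep(1, 40),
                       bin = rep(c(TRUE, FALSE), 20))
  expect_equal(compare_groups(df, "const", "g")$test, "not applicable")
  # 2x2 [[3,1],[1,3]] against exact hypergeometric enumeration
  df2 <- tibble::tibble(g = rep(c("a", "b"), each = 4),
                        y = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  got <- compare_groups(df2, "y", "g")
  expect_equal(got$test, "fisher")
  expect_equal(got$p_value, oracle_fisher_2x2(table(df2$y, df2$g)))
  # Fisher agrees with enumeration across random small tables
  set.seed(33)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    g <- sample(c("a", "b"), n, replace = TRUE)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tab <- table(factor(y, c(FALSE, TRUE)), factor(g, c("a", "b")))
    if (any(dim(tab) != 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher_2x2(tab),
                 tolerance = 1e-10)
  }
})

test_that("hypertension-like group imbalance reaches chi-square significance", {
  # 34/42 vs 10/27 exposed: the arm contrast reported as p < 0.001
  df <- tibble::tibble(
    g = rep(c("sporadic", "cadasil"), c(42, 27)),
    htn = c(rep(TRUE, 34), rep(FALSE, 8), rep(TRUE, 10), rep(FALSE, 17)))
  res <- compare_groups(df, "htn", "g")
  expect_equal(res$test, "chi-square")
  expect_lt(res$p_value, 0.001)
})

test_that("the univariable screen uses a strict p < 0.1 rule plus forced covariates", {
  res <- tibble::tibble(variable = c("a", "b", "c", "d"),
                        p_value = c(0.10, 0.099, 0.5, NA))
  got <- univariable_screen(res, always_include = c("ps_nawm", "cvr_wmh"))
  expect_setequal(got, c("b", "ps_nawm", "cvr_wmh"))
  # hand-filter oracle on a random result table
  set.seed(8)
  rt <- tibble::tibble(variable = paste0("v", 1:50), p_value = runif(50))
  expect_setequal(univariable_screen(rt), rt$variable[rt$p_value < 0.1])
})

test_that("spearman is used for ordinal-ordinal association", {
  df <- tibble::tibble(svd = rep(0:4, each = 8),
                       hot = rep(0:4, each = 8) + rep(c(0, 1), 20))
  res <- compare_groups(df, "hot", "svd")
  expect_equal(res$test, "spearman")
  expect_gt(res$statistic, 0.8)
})
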
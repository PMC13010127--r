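# Exhaustive-enumeration oracle for the two-sided exact Mann-Whitney p:
# all C(n1+n2, n1) assignments of the pooled ranks.
mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  # two-sided: assignments at least as extreme (as far from the mean)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

test_that("exact Mann-Whitney p matches exhaustive enumeration", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  cmp <- compare_two_groups(x, y, force_test = "mann_whitney")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 0.100)
  expect_equal(mw_exact_p(x, y), 0.100)
  set.seed(9)
  for (k in 1:5) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    pool <- sample(1000, n1 + n2) # distinct values: exact branch, no ties
    a <- pool[seq_len(n1)]; b <- pool[-seq_len(n1)]
    cmp <- compare_two_groups(a, b, force_test = "mann_whitney")
    expect_equal(cmp$p_value, mw_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical samples compare with p = 1 and zero difference", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  for (ft in c("t", "mann_whitney")) {
    cmp <- compare_two_groups(x, x, force_test = ft)
    expect_equal(cmp$p_value, 1)
    expect_equal(cmp$summaries$x$mean, cmp$summaries$y$mean)
  }
})

test_that("normality gate routes Gaussian data to t, skewed data to MW", {
  set.seed(21)
  g1 <- rnorm(30); g2 <- rnorm(30, 0.5)
  cmp <- compare_two_groups(g1, g2)
  expect_equal(cmp$test, "t_unpaired")
  expect_true(all(cmp$normality_p > cmp$alpha_normality))
  e1 <- rexp(30)^3; e2 <- rexp(30)^3
  cmp2 <- compare_two_groups(e1, e2)
  expect_equal(cmp2$test, "mann_whitney_u")
})

test_that("zero-variance samples bypass the gate with a warning", {
  expect_warning(cmp <- compare_two_groups(c(5, 5, 5), c(1, 2, 3)),
                 "zero-variance")
  expect_equal(cmp$test, "mann_whitney_u")
  expect_error(compare_two_groups(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("group summaries report mean and SEM = SD/sqrt(n)", {
  s <- group_summary(c(2, 4, 6, 8))
  expect_equal(s$n, 4L)
  expect_equal(s$mean, 5)
  expect_equal(s$sem, sd(c(2, 4, 6, 8)) / 2)
  expect_true(is.na(group_summary(7)$sem))
})

test_that("ANOVA worked example gives F = 3.0 with df (2, 6)", {
  a <- anova_oneway(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4),
                         g3 = c(3, 4, 5)))
  expect_equal(a$statistic, 3.0)
  expect_equal(unname(a$df), c(2, 6))
  expect_equal(a$p_value, stats::pf(3, 2, 6, lower.tail = FALSE))
})

test_that("ANOVA degenerate inputs are rejected informatively", {
  ident <- anova_oneway(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_equal(ident$statistic, 0)
  expect_error(anova_oneway(list(a = 1:3, b = 4:6)), "compare_two_groups")
  expect_error(anova_oneway(list(a = 1:3, b = 4:6, c = 7)), "n >= 2")
})

test_that("Spearman equals Pearson on ranks, including the worked -0.5", {
  x <- c(1, 2, 3); y <- c(3, 1, 2)
  m <- spearman_matrix(data.frame(x = x, y = y))
  expect_equal(m["x", "y"], -0.5)
  expect_equal(m["x", "x"], 1)
  set.seed(33)
  a <- rnorm(25); b <- a^2 + rnorm(25, 0, 0.2)
  m2 <- spearman_matrix(data.frame(a = a, b = b))
  expect_equal(m2["a", "b"], cor(rank(a), rank(b)), tolerance = 1e-12)
  m3 <- spearman_matrix(data.frame(u = 1:10, v = -(1:10)))
  expect_equal(m3["u", "v"], -1)
})

test_that("constant columns and short pairings carry no-data entries", {
  df <- data.frame(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2),
                   c = c(4, 3, NA, NA))
  m <- spearman_matrix(df)
  expect_true(all(is.na(m["b", ])))
  expect_true(all(is.na(m[, "b"])))
  expect_true(is.na(m["a", "c"])) # only 2 complete pairs
  expect_equal(m["a", "a"], 1)
})

test_that("severity stratification reproduces the printed cohort sizes", {
  # 10 patients with VC placed 2/5/3 in the printed bins, plus 10 HV
  vc <- c(95, 90, 80, 75, 70, 65, 60, 50, 40, 30)
  rec <- data.frame(id = sprintf("s%02d", 1:20),
                    group = rep(c("LOPD", "HV"), each = 10),
                    vc_percent = c(vc, rnorm(10, 100, 5)),
                    VDP = rnorm(20, 10),
                    niv = rep(c(TRUE, FALSE), 10))
  s <- subgroup_summary(rec, "severity", metrics = "VDP")
  n_by <- setNames(s$n, as.character(s$stratum))
  expect_equal(unname(n_by[c("mild", "moderate", "severe")]), c(2L, 5L, 3L))
  expect_equal(unname(n_by["HV"]), 10L)
  expect_identical(levels(s$stratum), c("HV", "mild", "moderate", "severe"))
})

test_that("empty and singleton strata are reported but not summarized", {
  rec <- data.frame(id = c("a", "b"), group = c("HV", "LOPD"),
                    vc_percent = c(100, 95), VDP = c(5, 20),
                    niv = c(FALSE, TRUE))
  s <- subgroup_summary(rec, "severity", metrics = "VDP")
  expect_equal(s$n[s$stratum == "moderate"], 0L)
  expect_true(is.na(s$sem[s$stratum == "mild"])) # single record, no SEM
  sn <- subgroup_summary(rec, "niv", metrics = "VDP")
  expect_identical(levels(sn$stratum), c("HV", "non_NIV", "with_NIV"))
  expect_equal(sn$n[sn$stratum == "with_NIV"], 1L)
})

test_that("type-I error of the gated two-group test is near nominal", {
  # null simulations at n = 50 per group; property-level check at a loose
  # 3-SE band so routine test runs stay stable (the acceptance suite runs
  # the printed 2,000-simulation version)
  set.seed(77)
  n_sim <- 400
  rej <- logical(n_sim)
  for (k in seq_len(n_sim)) {
    p <- compare_two_groups(rnorm(50), rnorm(50))$p_value
    rej[k] <- p < 0.05
  }
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("comparison tables label adjusted p values explicitly", {
  set.seed(5)
  rec <- data.frame(group = rep(c("HV", "LOPD"), each = 8),
                    VDP = c(rnorm(8, 5), rnorm(8, 20)),
                    QDP = c(rnorm(8, 5), rnorm(8, 6)))
  tab <- compare_groups_table(rec, metrics = c("VDP", "QDP"))
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("p_value", "p_holm", "p_bh") %in% names(tab)))
  expect_true(all(tab$p_holm >= tab$p_value - 1e-15))
})
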
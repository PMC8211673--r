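test_that("fisher_exact matches enumeration oracle and stats::fisher.test", {
  expect_equal(fisher_exact(c(1, 1, 1, 1))$p_value, 1)
  expect_equal(fisher_exact(c(5, 0, 0, 5))$p_value, 2 / 252,
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact(tab)$p_value
    expect_equal(p, fisher_enum_oracle(tab), tolerance = 1e-12)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact(c(-1, 2, 3, 4)), "nonnegative")
})

test_that("chi_square_2x2 equals the cell-by-cell Pearson formula", {
  expect_equal(chi_square_2x2(c(50, 50, 50, 50))$statistic,
               c(`X-squared` = 0))
  expect_equal(chi_square_2x2(c(50, 50, 50, 50))$p_value, 1)
  set.seed(42)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 10) + 1, 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    x2 <- sum((tab - e)^2 / e)
    r <- chi_square_2x2(tab)
    expect_equal(unname(r$statistic), x2, tolerance = 1e-12)
    expect_equal(r$p_value, pchisq(x2, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(c(0, 0, 3, 4)), "margin")
})

test_that("steel_test handles ties, constants, and known shifts", {
  # constant identical data in all groups -> p = 1
  r <- steel_test(rep(1, 5), list(rep(1, 5), rep(1, 5)),
                  n_permutations = 199, seed = 1)
  expect_equal(unname(r$p_value), c(1, 1))
  # a strong shift is detected
  set.seed(43)
  r2 <- steel_test(rnorm(50) - 1, list(rnorm(50), rnorm(50)),
                   n_permutations = 1999, seed = 2)
  expect_true(all(r2$p_value < 0.001))
  # determinism given (seed, n_permutations)
  x <- rnorm(12); y <- list(rnorm(12))
  a <- steel_test(x, y, n_permutations = 299, seed = 7)
  b <- steel_test(x, y, n_permutations = 299, seed = 7)
  expect_identical(a$p_value, b$p_value)
  # p respects the permutation floor
  expect_gte(min(r2$p_value), 1 / 2000)
})

test_that("steel_test with one treatment matches a Wilcoxon permutation test", {
  set.seed(44)
  x <- rnorm(15); y <- rnorm(15) + 0.8
  st <- steel_test(x, y, n_permutations = 4999, seed = 5)
  # reference: two-sided permutation null of |z| for the same comparison
  z_obs <- abs(gutdrift:::rank_sum_z(x, y))
  pool <- c(x, y)
  set.seed(99)
  z_perm <- replicate(4999, {
    p <- sample(pool)
    abs(gutdrift:::rank_sum_z(p[1:15], p[16:30]))
  })
  p_ref <- (1 + sum(z_perm >= z_obs - 1e-12)) / 5000
  expect_equal(unname(st$p_value), p_ref, tolerance = 0.02)
})

test_that("adjusted_group_compare matches lm and flags collinearity", {
  set.seed(45)
  n <- 120
  d <- tibble::tibble(
    age = rnorm(n, 75, 6), sex = sample(c("m", "f"), n, TRUE),
    bmi = rnorm(n, 23, 3), group = sample(c("lt3", "ge3"), n, TRUE))
  d$y <- 0.2 + 0.05 * (d$group == "ge3") + 0.002 * d$age + rnorm(n, 0, 0.05)
  r <- adjusted_group_compare(d, "y", "group", c("age", "sex", "bmi"))
  fit <- lm(y ~ group + age + sex + bmi, data = d)
  expect_equal(unname(r$statistic),
               summary(fit)$coefficients["grouplt3", "t value"],
               tolerance = 1e-12)
  expect_equal(r$p_value,
               summary(fit)$coefficients["grouplt3", "Pr(>|t|)"],
               tolerance = 1e-12)
  # duplicate covariate -> rank-deficiency error naming the column
  d$age2 <- d$age
  expect_error(adjusted_group_compare(d, "y", "group",
                                      c("age", "age2")),
               "Rank-deficient.*age2")
  # listwise deletion of incomplete cases
  d2 <- d; d2$bmi[1:10] <- NA
  r2 <- adjusted_group_compare(d2, "y", "group", c("age", "bmi"))
  expect_equal(r2$n, n - 10)
})

test_that("levene_test matches car::leveneTest and rejects zero spread", {
  set.seed(46)
  vals <- c(rnorm(30, sd = 1), rnorm(30, sd = 3))
  g <- rep(c("a", "b"), each = 30)
  r <- levene_test(vals, g)
  ref <- car::leveneTest(vals ~ factor(g), center = mean)
  expect_equal(unname(r$statistic), ref$`F value`[1], tolerance = 1e-12)
  expect_equal(r$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)
  # median-centered variant = Brown-Forsythe
  rbf <- levene_test(vals, g, center = "median")
  refbf <- car::leveneTest(vals ~ factor(g), center = median)
  expect_equal(unname(rbf$statistic), refbf$`F value`[1],
               tolerance = 1e-12)
  # list interface; one constant group among varying ones is valid
  expect_s3_class(levene_test(list(rep(1, 5), rnorm(5))), "gut_test")
  expect_error(levene_test(list(rep(1, 5), rep(2, 5))),
               "zero dispersion")
})

test_that("spearman_test matches the rank-then-Pearson oracle with ties", {
  x <- c(1, 2, 2, 3, 4, 5, 5, 6)
  y <- c(2, 1, 3, 3, 5, 4, 7, 7)
  r <- spearman_test(x, y)
  rho <- cor(rank(x), rank(y))
  expect_equal(unname(r$statistic), rho, tolerance = 1e-12)
  tstat <- rho * sqrt((length(x) - 2) / (1 - rho^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), length(x) - 2),
               tolerance = 1e-12)
  expect_equal(unname(spearman_test(1:6, (1:6)^3)$statistic), 1)
  expect_equal(unname(spearman_test(1:6, -(1:6)^2)$statistic), -1)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
})

test_that("permanova matches vegan::adonis2 and is relabel-invariant", {
  set.seed(47)
  co <- random_cohort(10, 6)
  dm <- pairwise_distances(co, "jsd")
  g <- rep(c("A", "B"), each = 10)
  r <- permanova(dm, g, n_permutations = 499, seed = 3)
  ref <- vegan::adonis2(stats::as.dist(as.matrix(dm)) ~ g,
                        permutations = 499)
  expect_equal(unname(r$statistic), ref$F[1], tolerance = 1e-10)
  expect_equal(r$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_lt(abs(r$p_value - ref$`Pr(>F)`[1]), 0.05)
  # permuting sample order together with labels leaves F unchanged
  ord <- sample(20)
  r2 <- permanova(as.matrix(dm)[ord, ord], g[ord],
                  n_permutations = 99, seed = 3)
  expect_equal(unname(r2$statistic), unname(r$statistic),
               tolerance = 1e-12)
  expect_error(permanova(dm, rep("A", 20)), "2 groups")
  # determinism
  expect_identical(permanova(dm, g, 199, seed = 9)$p_value,
                   permanova(dm, g, 199, seed = 9)$p_value)
})

test_that("maximally separated groups reach the permutation p floor", {
  # two tight clusters: within-JSD ~ 0.03, between ~ 0.8
  set.seed(48)
  base1 <- c(0.97, 0.01, 0.01, 0.01)
  base2 <- c(0.01, 0.01, 0.01, 0.97)
  jitter <- function(p) { q <- p * exp(rnorm(4, 0, 0.08)); q / sum(q) }
  prof <- rbind(t(replicate(10, jitter(base1))),
                t(replicate(10, jitter(base2))))
  rownames(prof) <- sprintf("s%02d", 1:20)
  d <- matrix(0, 20, 20, dimnames = list(rownames(prof), rownames(prof)))
  for (i in 1:19) for (j in (i + 1):20) {
    d[i, j] <- d[j, i] <- jsd(prof[i, ], prof[j, ])
  }
  r <- permanova(d, rep(c("A", "B"), each = 10),
                 n_permutations = 999, seed = 4)
  expect_equal(r$p_value, 1 / 1000)
})

test_that("tidiers return one row per comparison", {
  r <- steel_test(rnorm(10), list(a = rnorm(10), b = rnorm(10)),
                  n_permutations = 99, seed = 1)
  td <- tidy(r)
  expect_equal(nrow(td), 2)
  expect_equal(td$comparison, c("a", "b"))
  gl <- glance(fisher_exact(c(2, 3, 4, 5)))
  expect_equal(nrow(gl), 1)
  expect_true(all(c("statistic", "p.value", "method") %in% names(gl)))
})
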
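test_that("kld matches direct summation and is asymmetric", {
  x <- c(0.5, 0.5); y <- c(0.25, 0.75)
  expect_equal(kld(x, x), 0)
  expect_equal(kld(x, y), 0.5 * log(2) + 0.5 * log(2 / 3),
               tolerance = 1e-14)
  expect_false(isTRUE(all.equal(kld(x, y), kld(y, x))))
  set.seed(21)
  for (i in 1:20) {
    a <- random_profile(6); b <- random_profile(6)
    expect_equal(kld(a, b), sum(a * log(a / b)), tolerance = 1e-14)
    expect_gte(kld(a, b), 0)
  }
  expect_error(kld(c(0, 1), c(0.5, 0.5)), "pseudocount")
  expect_error(kld(c(1, 0, 0), c(0.5, 0.5)), "length")
})

test_that("jsd follows the full equation chain with pseudocount", {
  expect_equal(jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # disjoint supports approach the sqrt(ln 2) bound up to pseudocount mass
  d <- jsd(c(1, 0), c(0, 1))
  expect_lt(d, sqrt(log(2)))
  expect_equal(d, 0.83255, tolerance = 1e-4)
  expect_equal(jsd(c(0.5, 0.5), c(0.25, 0.75)),
               jsd_oracle(c(0.5, 0.5), c(0.25, 0.75)), tolerance = 1e-15)
  expect_equal(jsd(c(0.5, 0.5), c(0.25, 0.75)), 0.18391, tolerance = 1e-4)
  set.seed(22)
  for (i in 1:200) {
    a <- random_profile(10); b <- random_profile(10)
    expect_equal(jsd(a, b), jsd_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("jsd is a bounded metric on pseudocounted simplices", {
  set.seed(23)
  bound <- sqrt(log(2)) + 1e-9
  for (i in 1:300) {
    a <- random_profile(7); b <- random_profile(7); c <- random_profile(7)
    dab <- jsd(a, b); dbc <- jsd(b, c); dac <- jsd(a, c)
    expect_gte(dab, 0)
    expect_lte(dab, bound)
    expect_equal(dab, jsd(b, a), tolerance = 1e-14)       # symmetry
    expect_lte(dac, dab + dbc + 1e-12)                    # triangle
  }
  # identity of indiscernibles and permutation invariance over families
  a <- random_profile(9)
  expect_equal(jsd(a, a), 0)
  perm <- sample(9)
  b <- random_profile(9)
  expect_equal(jsd(a[perm], b[perm]), jsd(a, b), tolerance = 1e-14)
})

test_that("families absent from both profiles barely move jsd", {
  set.seed(24)
  a <- random_profile(10); b <- random_profile(10)
  base <- jsd(a, b)
  padded <- jsd(c(a, rep(0, 100)), c(b, rep(0, 100)))
  expect_lt(abs(padded - base), 1e-5)
})

test_that("bray_curtis matches 1 - 2*sum(min) and vegan's vegdist", {
  expect_equal(bray_curtis(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.5, 0.5), c(0.25, 0.75)), 0.25)
  set.seed(25)
  for (i in 1:50) {
    a <- random_profile(8); b <- random_profile(8)
    expect_equal(bray_curtis(a, b), 1 - sum(pmin(a, b)),  # unit-sum rows
                 tolerance = 1e-12)
    expect_equal(bray_curtis(a, b),
                 as.numeric(vegan::vegdist(rbind(a, b), "bray")),
                 tolerance = 1e-12)
    expect_equal(bray_curtis(a, b), bray_curtis(b, a))
    expect_gte(bray_curtis(a, b), 0)
    expect_lte(bray_curtis(a, b), 1)
  }
})

test_that("pairwise_distances matches elementwise calls and relabels", {
  set.seed(26)
  co <- random_cohort(4, 6)
  p <- as.matrix(co$abundance[co$families])
  rownames(p) <- co$abundance$sample_id
  for (metric in c("jsd", "bcd")) {
    dm <- pairwise_distances(co, metric)
    expect_equal(dim(dm), c(8, 8), ignore_attr = TRUE)
    expect_equal(as.matrix(dm), t(as.matrix(dm)))
    expect_equal(diag(as.matrix(dm)), rep(0, 8), ignore_attr = TRUE)
    f <- if (metric == "jsd") jsd else bray_curtis
    for (i in 1:4) for (j in 5:8) {
      expect_equal(as.matrix(dm)[i, j], f(p[i, ], p[j, ]),
                   tolerance = 1e-12)
    }
  }
  # permuting sample order permutes rows/columns consistently
  ord <- sample(nrow(co$abundance))
  co2 <- gut_cohort(co$abundance[ord, ], co$metadata[ord, ])
  dm1 <- as.matrix(pairwise_distances(co, "jsd"))
  dm2 <- as.matrix(pairwise_distances(co2, "jsd"))
  expect_equal(dm2, dm1[rownames(dm2), colnames(dm2)], tolerance = 1e-12)
})

test_that("intra_individual pairs the right waves and omits incomplete", {
  co <- random_cohort(5, 5)
  # make subject S03 identical across waves; drop S05's second wave
  i1 <- which(co$abundance$sample_id == "S03_Y1")
  i2 <- which(co$abundance$sample_id == "S03_Y2")
  co$abundance[i2, co$families] <- co$abundance[i1, co$families]
  keep <- co$abundance$sample_id != "S05_Y2"
  co <- gut_cohort(co$abundance[keep, ], co$metadata[keep, ])
  intra <- intra_individual(co, c(1, 2), "jsd")
  expect_setequal(intra$subject_id, sprintf("S%02d", 1:4))
  expect_equal(intra$distance[intra$subject_id == "S03"], 0)
  expect_error(intra_individual(co, c(2, 2)), "increasing")
})

test_that("inter_individual covers all pairs and matches the matrix", {
  co <- random_cohort(4, 6)
  inter <- inter_individual(co, 1, "jsd")
  expect_equal(nrow(inter), choose(4, 2))
  dm <- as.matrix(pairwise_distances(co, "jsd"))
  for (r in seq_len(nrow(inter))) {
    expect_equal(inter$distance[r],
                 dm[paste0(inter$subject_a[r], "_Y1"),
                    paste0(inter$subject_b[r], "_Y1")],
                 tolerance = 1e-12)
  }
  only1 <- gut_cohort(co$abundance[1, ], co$metadata[1, ])
  expect_error(inter_individual(only1, 1), "at least 2")
})
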
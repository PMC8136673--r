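# Closed forms, the general least-squares partition, and their agreement.

test_that("single-locus population mean matches its closed form", {
  expect_equal(pop_mean(single_locus(4, 4, 0.5)), 2)
  expect_equal(pop_mean(single_locus(7, 0, 0.5)), 0)
  expect_equal(pop_mean(single_locus(4, 4, 1)), 4)
  # against the frequency-weighted mean directly
  set.seed(1)
  for (i in 1:10) {
    m <- single_locus(runif(1, -5, 5), runif(1, -5, 5), runif(1))
    expect_equal(pop_mean(m),
                 sum(hwe_frequencies(m$p) * m$values))
  }
})

test_that("average effect equals the weighted regression slope on dosage", {
  expect_equal(unname(average_effects(single_locus(4, 4, 0.5))), 4)
  expect_equal(unname(average_effects(single_locus(4, 0, 0.123))), 4)
  expect_equal(unname(average_effects(single_locus(4, 4, 0.1))), 7.2)
  set.seed(2)
  for (i in 1:10) {
    m <- single_locus(runif(1, -5, 5), runif(1, -5, 5), runif(1, 0.05, 0.95))
    slope <- oracle_wls(m$values, 0:2, hwe_frequencies(m$p))[["slope"]]
    expect_equal(unname(average_effects(m)), slope, tolerance = 1e-12)
  }
})

test_that("single-locus variance components match the regression oracle", {
  dec <- decompose_variance(single_locus(4, 4, 0.5))
  expect_equal(dec$V_A, 8)
  expect_equal(dec$V_D, 4)
  expect_equal(dec$V_G, 12)
  # V_A is the regression variance, V_D the residual variance
  w <- hwe_frequencies(0.5)
  fit <- lm(c(-4, 4, 4) ~ c(0:2), weights = w)
  expect_equal(dec$V_A, sum(w * (fitted(fit) - sum(w * fitted(fit)))^2))
  expect_equal(dec$V_D, sum(w * residuals(fit)^2))

  mono <- decompose_variance(single_locus(4, 4, 0))
  expect_equal(mono$V_G, 0)
  expect_true(is.na(mono$ratio_A))
})

test_that("two-locus additive-by-additive closed forms match the oracle", {
  # symmetric frequencies annihilate every mean term
  expect_equal(pop_mean(two_locus_aa(4, 4, 4, 0.5, 0.5)), 0)
  expect_equal(pop_mean(two_locus_aa(4, 0, 0, 1, 0.37)), 4)
  m <- two_locus_aa(4, 4, 4, 0.1, 0.9)
  expect_equal(pop_mean(m),
               sum(genotype_frequencies(0.1, 0.9) * m$values))

  expect_equal(average_effects(two_locus_aa(4, 4, 4, 0.5, 0.5)),
               c(alpha_A = 4, alpha_B = 4))
  expect_equal(average_effects(two_locus_aa(3, -2, 0, 0.2, 0.7)),
               c(alpha_A = 3, alpha_B = -2))
  expect_equal(average_effects(m), c(alpha_A = 7.2, alpha_B = 0.8))
  # marginal weighted regression slope at each locus
  fb <- hwe_frequencies(0.9)
  marg_A <- as.vector(m$values %*% fb)
  expect_equal(unname(average_effects(m)["alpha_A"]),
               oracle_wls(marg_A, 0:2, hwe_frequencies(0.1))[["slope"]])

  dec <- decompose_variance(two_locus_aa(4, 4, 4, 0.5, 0.5))
  expect_equal(dec$V_A, 16)
  expect_equal(dec$V_AA, 4)
  expect_equal(dec$V_D + dec$V_AD + dec$V_DD, 0)
  expect_equal(decompose_variance(two_locus_aa(1, 2, 0, 0.3, 0.8))$V_AA, 0)
  # all variance epistatic when a_A = a_B = 0 at p = q = 0.5
  pure <- decompose_variance(two_locus_aa(0, 0, 1, 0.5, 0.5))
  expect_equal(pure$V_A, 0)
  expect_equal(pure$V_AA, 0.25)
})

test_that("contrast scores are centered, orthogonal, with variance H", {
  d5 <- contrast_design(0.5, 0.5)
  expect_equal(unique(d5$scores[, "add_A"]), c(-1, 0, 1))
  expect_equal(sort(unique(d5$scores[, "dom_A"])), c(-0.5, 0.5))
  expect_equal(contrast_design(0.3, 0.5)$H_A, 0.42)
  for (p in c(0.1, 0.33, 0.5, 0.77)) {
    for (q in c(0.2, 0.5, 0.9)) {
      dz <- contrast_design(p, q)
      G <- t(dz$scores) %*% (dz$weights * dz$scores)
      expect_equal(colSums(dz$weights * dz$scores), rep(0, 8),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(G - diag(diag(G)), matrix(0, 8, 8),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(G["add_A", "add_A"], 2 * p * (1 - p))
      expect_equal(G["add_B", "add_B"], 2 * q * (1 - q))
    }
  }
})

test_that("general partition reproduces the classic epistatic examples", {
  dup <- decompose_variance(duplicate_factor(4, 0.5, 0.5))
  expect_equal(glance(dup)[, c("V_A", "V_D", "V_AA", "V_AD", "V_DD", "V_G")],
               tibble::tibble(V_A = 0.25, V_D = 0.125, V_AA = 0.25,
                              V_AD = 0.25, V_DD = 0.0625, V_G = 0.9375),
               tolerance = 1e-12)
  expect_equal(dup$ratio_A, 0.25 / 0.9375, tolerance = 1e-12)

  com <- decompose_variance(complementary(4, 0.5, 0.5))
  expect_equal(glance(com)[, c("V_A", "V_D", "V_AA", "V_AD", "V_DD", "V_G")],
               tibble::tibble(V_A = 2.25, V_D = 1.125, V_AA = 0.25,
                              V_AD = 0.25, V_DD = 0.0625, V_G = 3.9375),
               tolerance = 1e-12)

  const <- decompose_general(two_locus(matrix(3.7, 3, 3), 0.4, 0.6))
  expect_equal(const$V_G, 0)
  expect_equal(const$V_A + const$V_D + const$V_AA + const$V_AD + const$V_DD,
               0)
  expect_true(is.na(const$ratio_A))
})

test_that("general partition agrees with the lm-based oracle", {
  set.seed(3)
  for (i in 1:20) {
    vals <- random_table()
    p <- runif(1, 0.05, 0.95); q <- runif(1, 0.05, 0.95)
    dec <- decompose_general(two_locus(vals, p, q))
    expect_decomp_equal(dec, oracle_decompose(vals, p, q))
    expect_equal(dec$alpha_A, oracle_decompose(vals, p, q)$alpha_A,
                 tolerance = 1e-9)
  }
})

test_that("components sum to the direct weighted variance (conservation)", {
  set.seed(4)
  for (i in 1:100) {
    vals <- random_table()
    p <- runif(1); q <- runif(1)
    dec <- decompose_general(two_locus(vals, p, q))
    total <- dec$V_A + dec$V_D + dec$V_AA + dec$V_AD + dec$V_DD
    direct <- {
      w <- genotype_frequencies(p, q)
      sum(w * (vals - sum(w * vals))^2)
    }
    expect_equal(total, direct, tolerance = 1e-9)
    expect_true(all(c(dec$V_A, dec$V_D, dec$V_AA, dec$V_AD, dec$V_DD)
                    >= -1e-9))
  }
})

test_that("least-squares route reproduces both closed forms", {
  set.seed(5)
  for (i in 1:15) {
    sl <- single_locus(runif(1, -5, 5), runif(1, -5, 5), runif(1, 0.02, 0.98))
    a <- decompose_variance(sl, method = "closed_form")
    b <- decompose_variance(sl, method = "least_squares")
    expect_decomp_equal(b, a)
    expect_equal(b$alpha_A, a$alpha_A, tolerance = 1e-9)

    aa <- two_locus_aa(runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5),
                       runif(1, 0.02, 0.98), runif(1, 0.02, 0.98))
    ca <- decompose_variance(aa, method = "closed_form")
    cb <- decompose_variance(aa, method = "least_squares")
    expect_decomp_equal(cb, ca)
    expect_equal(c(cb$alpha_A, cb$alpha_B), c(ca$alpha_A, ca$alpha_B),
                 tolerance = 1e-9)
  }
  expect_error(decompose_variance(duplicate_factor(4, 0.5, 0.5),
                                  method = "closed_form"), "closed form")
})

test_that("allele relabeling leaves every component unchanged", {
  set.seed(6)
  for (i in 1:10) {
    vals <- random_table()
    p <- runif(1, 0.05, 0.95); q <- runif(1, 0.05, 0.95)
    a <- decompose_general(two_locus(vals, p, q))
    b <- decompose_general(two_locus(vals[3:1, ], 1 - p, q))
    for (f in c("V_A", "V_D", "V_AA", "V_AD", "V_DD", "V_G")) {
      expect_equal(a[[f]], b[[f]], tolerance = 1e-9, label = f)
    }
  }
})

test_that("scaling values by k scales components by k^2 and alpha by k", {
  set.seed(7)
  vals <- random_table()
  k <- 3.7
  a <- decompose_general(two_locus(vals, 0.3, 0.6))
  b <- decompose_general(two_locus(k * vals, 0.3, 0.6))
  for (f in c("V_A", "V_D", "V_AA", "V_AD", "V_DD", "V_G")) {
    expect_equal(b[[f]], k^2 * a[[f]], tolerance = 1e-9)
  }
  expect_equal(b$alpha_A, k * a$alpha_A, tolerance = 1e-9)
})

test_that("monomorphic loci zero out their components", {
  dec <- decompose_general(two_locus(random_table(), 0, 0.5))
  expect_equal(dec$V_A + dec$V_AA + dec$V_AD + dec$V_DD +
                 dec$V_D - decompose_general(
                   two_locus(dec$model$values, 0, 0.5))$V_G,
               0, tolerance = 1e-9)
  # only locus B segregates: no interaction or locus-A components
  expect_equal(dec$V_AA, 0)
  expect_equal(dec$V_AD, 0)
  expect_equal(dec$V_DD, 0)
  both <- decompose_general(two_locus(random_table(), 1, 1))
  expect_equal(both$V_G, 0)
})
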
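# Brute-force Pearson chi-square from first principles (independence
# expectations), used as the oracle for the packaged statistics.
chi2_oracle <- function(tab) {
  tab <- unclass(as.matrix(tab))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

test_that("HWE chi-square matches brute-force expected counts", {
  r <- hwe_chi2(c(25, 50, 25))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # complete heterozygote deficit at n = 200
  r <- hwe_chi2(c(100, 0, 100))
  expect_equal(r$statistic, 200)
  # reference control sample at rs738409 deviates from HWE
  counts <- c(123, 56, 48)
  n <- sum(counts)
  p <- (56 + 2 * 48) / (2 * n)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  oracle <- sum((counts - expected)^2 / expected)
  r <- hwe_chi2(counts)
  expect_equal(r$statistic, oracle, tolerance = 1e-12)
  expect_equal(r$allele_freq, p)
  expect_lt(r$p.value, 0.001)
  # monomorphic sample is trivially in equilibrium
  expect_equal(hwe_chi2(c(50, 0, 0))$p.value, 1)
})

test_that("penetrance-model collapse produces the published 2x2 layouts", {
  pnpla3 <- genotype_counts(c(92, 91, 35), c(123, 56, 48))
  dom <- collapse_genotypes(pnpla3, "dominant")
  expect_equal(unclass(dom)[1, ], c(exposed = 126, unexposed = 92))
  expect_equal(unclass(dom)[2, ], c(exposed = 104, unexposed = 123))
  gckr <- genotype_counts(c(43, 90, 85), c(49, 123, 55))
  rec <- collapse_genotypes(gckr, "recessive")
  expect_equal(unclass(rec)[1, ], c(exposed = 85, unexposed = 133))
  expect_equal(unclass(rec)[2, ], c(exposed = 55, unexposed = 172))
  # with no heterozygotes the two collapses coincide
  g <- genotype_counts(c(30, 0, 10), c(35, 0, 5))
  expect_equal(unclass(collapse_genotypes(g, "dominant")),
               unclass(collapse_genotypes(g, "recessive")),
               ignore_attr = TRUE)
})

test_that("Pearson chi-square is uncorrected and matches the 2x2 shortcut", {
  tab <- matrix(c(126, 92, 104, 123), 2, byrow = TRUE)
  r <- pearson_chi2(tab)
  expect_equal(r$statistic, 6.39, tolerance = 1e-3)
  expect_equal(r$df, 1)
  tab2 <- matrix(c(85, 133, 55, 172), 2, byrow = TRUE)
  expect_equal(pearson_chi2(tab2)$statistic, 11.2, tolerance = 5e-3)
  # proportional rows give a null statistic
  expect_equal(pearson_chi2(matrix(c(10, 20, 30, 60), 2,
                                   byrow = TRUE))$statistic, 0)
  # shortcut n(ad-bc)^2 / (margin product) and row/col permutation
  set.seed(4)
  for (i in 1:20) {
    m <- matrix(sample(5:80, 4, replace = TRUE), 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    shortcut <- sum(m) * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(pearson_chi2(m)$statistic, shortcut, tolerance = 1e-10)
    expect_equal(pearson_chi2(m[2:1, ])$statistic,
                 pearson_chi2(m)$statistic, tolerance = 1e-12)
    expect_equal(pearson_chi2(m[, 2:1])$statistic,
                 pearson_chi2(m)$statistic, tolerance = 1e-12)
  }
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("genotypic chi-square equals the sum of its cell contributions", {
  g <- genotype_counts(c(43, 90, 85), c(49, 123, 55))
  r <- snp_association(g, "genotypic")
  expect_gte(r$statistic, 0)
  expect_equal(r$df, 2)
  expect_equal(r$statistic, chi2_oracle(g), tolerance = 1e-10)
})

test_that("Woolf odds-ratio intervals match the published values", {
  r <- odds_ratio_woolf(matrix(c(126, 92, 104, 123), 2, byrow = TRUE))
  expect_equal(r$or, 1.62, tolerance = 1e-2)
  expect_equal(r$ci_low, 1.11, tolerance = 5e-3)
  expect_equal(r$ci_high, 2.36, tolerance = 5e-3)
  r <- odds_ratio_woolf(matrix(c(85, 133, 55, 172), 2, byrow = TRUE))
  expect_equal(r$or, 2.00, tolerance = 5e-3)
  expect_equal(r$ci_low, 1.32, tolerance = 5e-2)
  expect_equal(r$ci_high, 3.00, tolerance = 5e-2)
  # balanced table gives OR = 1
  expect_equal(odds_ratio_woolf(matrix(c(10, 20, 30, 60), 2,
                                       byrow = TRUE))$or, 1)
  # transposing the groups returns the reciprocal with mirrored CI
  m <- matrix(c(31, 50, 17, 80), 2, byrow = TRUE)
  r1 <- odds_ratio_woolf(m)
  r2 <- odds_ratio_woolf(m[2:1, ])
  expect_equal(r2$or, 1 / r1$or, tolerance = 1e-12)
  expect_equal(r2$ci_low, 1 / r1$ci_high, tolerance = 1e-12)
  expect_equal(r2$ci_high, 1 / r1$ci_low, tolerance = 1e-12)
  # zero cell: 0.5-corrected and flagged non-estimable
  r <- odds_ratio_woolf(matrix(c(0, 50, 10, 40), 2, byrow = TRUE))
  expect_true(r$corrected)
  expect_false(r$estimable)
})

test_that("carrier-burden enrichment behaves like a 2x2 association", {
  # identical carrier fraction in both groups: OR = 1
  status <- rep(c("case", "control"), each = 100)
  carrier <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 80, 20, 80))
  r <- carrier_burden(carrier, status)
  expect_equal(r$or, 1)
  # ~14% of 218 cases vs ~8% of 227 controls: OR near 2, p near 0.04
  status <- rep(c("case", "control"), c(218, 227))
  carrier <- c(rep(TRUE, 31), rep(FALSE, 187), rep(TRUE, 18),
               rep(FALSE, 209))
  r <- carrier_burden(carrier, status)
  expect_lt(abs(r$or - 2.0), 0.15)
  expect_lt(r$p.value, 0.06)
  # no carriers at all: flagged non-estimable
  r <- carrier_burden(rep(FALSE, 40), rep(c("case", "control"), 20))
  expect_false(r$estimable)
  # permuted labels follow the 1-df null
  set.seed(7)
  carrier <- rep(c(TRUE, FALSE), c(60, 385))
  rej <- mean(vapply(1:200, function(i) {
    carrier_burden(sample(carrier), status)$p.value < 0.05
  }, logical(1)))
  expect_lt(rej, 0.12)
})

test_that("severity classes follow the Hamaguchi grading", {
  r <- severity_classes(0:6)
  expect_equal(as.character(r$class4),
               c("absent", "mild", "mild", "moderate", "moderate",
                 "severe", "severe"))
  expect_equal(r$severe, c(rep(FALSE, 5), TRUE, TRUE))
  expect_error(severity_classes(7), "0..6")
  expect_error(severity_classes(-1), "0..6")
  expect_error(severity_classes(2.5), "0..6")
})
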
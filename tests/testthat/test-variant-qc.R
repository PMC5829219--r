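make_call <- function(dp = 50, gq = 60, af = 45, saf = 10, sar = 10) {
  data.frame(dp = dp, gq = gq, af = af, saf = saf, sar = sar)
}

test_that("the high-confidence filter applies the four rules with inclusive thresholds", {
  # boundary of every stated threshold is kept
  v <- filter_high_confidence(make_call(dp = 30, gq = 30, af = 33,
                                        saf = 10, sar = 10))
  expect_true(v$kept)
  expect_identical(v$reasons, "")
  # single-rule boundary violations
  expect_equal(filter_high_confidence(make_call(dp = 29, gq = 99,
                                                af = 45))$reasons, "DP")
  expect_equal(filter_high_confidence(make_call(gq = 29))$reasons, "GQ")
  # AF between the heterozygous and homozygous windows
  cases <- data.frame(af = c(32.9, 33, 50, 50.1, 60, 69.9, 70, 100),
                      kept = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                               TRUE, TRUE))
  for (i in seq_len(nrow(cases))) {
    v <- filter_high_confidence(make_call(af = cases$af[i]))
    expect_equal(v$kept, cases$kept[i], info = paste("af =", cases$af[i]))
    if (!cases$kept[i]) expect_equal(v$reasons, "AF")
  }
  # strand balance: rarer strand must carry >= 20% of alt observations
  expect_true(filter_high_confidence(make_call(saf = 2, sar = 8))$kept)
  expect_equal(filter_high_confidence(make_call(saf = 1, sar = 9))$reasons,
               "STRAND")
  expect_equal(filter_high_confidence(make_call(saf = 0, sar = 0))$reasons,
               "STRAND")  # af > 0 with no recorded alt observations
  # multiple failures listed in stable DP, GQ, AF, STRAND order
  v <- filter_high_confidence(make_call(dp = 10, gq = 10, af = 60,
                                        saf = 6, sar = 0))
  expect_equal(v$reasons, "DP,GQ,AF,STRAND")
  expect_error(filter_high_confidence(make_call(saf = 40, sar = 40,
                                                dp = 50)), "saf")
})

test_that("filtering is idempotent on the kept set", {
  tf <- tempfile(fileext = ".vcf")
  on.exit(unlink(tf))
  simulate_vcf(80, qc_fail_fraction = 0.3, seed = 4, path = tf)
  calls <- read_variant_calls(tf)
  once <- filter_high_confidence(calls)
  kept <- once[once$kept, names(calls)]
  twice <- filter_high_confidence(kept)
  expect_true(all(twice$kept))
  expect_equal(twice$reasons, rep("", nrow(kept)))
})

test_that("simulated VCF fixtures are filtered exactly as labelled", {
  tf <- tempfile(fileext = ".vcf")
  on.exit(unlink(tf))
  # no failures requested -> everything passes
  simulate_vcf(30, qc_fail_fraction = 0, seed = 2, path = tf)
  all_pass <- filter_high_confidence(read_variant_calls(tf))
  expect_true(all(all_pass$kept))
  # every rule violated at least once, each by exactly one rule
  simulate_vcf(40, qc_fail_fraction = 0.25, seed = 9, path = tf)
  calls <- read_variant_calls(tf)
  expected <- vcfR::extract.info(vcfR::read.vcfR(tf, verbose = FALSE),
                                 "EXPECT")
  f <- filter_high_confidence(calls)
  verdict <- ifelse(f$kept, "PASS", f$reasons)
  expect_identical(verdict, expected)
  expect_setequal(setdiff(unique(expected), "PASS"),
                  c("DP", "GQ", "AF", "STRAND"))
})

test_that("MAF classification partitions [0, 0.5] at the stated cut-offs", {
  expect_equal(classify_maf(0.009), "rare")
  expect_equal(classify_maf(0.01), "low_frequency")
  expect_equal(classify_maf(0.049), "low_frequency")
  expect_equal(classify_maf(0.05), "common")
  expect_equal(classify_maf(0), "rare")
  expect_equal(classify_maf(0.5), "common")
  expect_error(classify_maf(0.6), "minor")
  expect_error(classify_maf(-0.1), "minor")
  # exactly one class for every value on a fine grid
  grid <- seq(0, 0.5, by = 0.001)
  cls <- classify_maf(grid)
  expect_true(all(cls %in% c("rare", "low_frequency", "common")))
  expect_equal(length(cls), length(grid))
})

test_that("functional classification follows the annotation vocabulary", {
  expect_equal(classify_function("missense"), "functional")
  expect_equal(classify_function("nonsense"), "functional")
  expect_equal(classify_function("frameshift"), "functional")
  expect_equal(classify_function("splice-region"), "functional")
  expect_equal(classify_function("synonymous"), "non_functional")
  expect_equal(classify_function("intronic"), "non_functional")
  expect_equal(classify_function("other"), "non_functional")
  expect_error(classify_function("nonsynonymous"), "unknown annotation")
})

test_that("variant-class summaries reproduce a labelled screen composition", {
  ann <- screen_annotation()
  tf <- tempfile(fileext = ".vcf")
  on.exit(unlink(tf))
  simulate_vcf(168, qc_fail_fraction = 0, seed = 6, annotation = ann,
               path = tf)
  sm <- summarize_variant_classes(read_variant_calls(tf))
  expect_equal(sm$n, 168)
  expect_equal(sm$n_intronic, 100)
  expect_equal(sm$n_exonic, 68)
  expect_equal(unname(sm$by_annotation["missense"]), 43L)
  expect_equal(unname(sm$by_annotation["nonsense"]), 2L)
  expect_equal(unname(sm$by_annotation["frameshift"]), 2L)
  expect_equal(unname(sm$by_annotation["synonymous"]), 21L)
  expect_equal(sum(sm$cross), 168)
})

test_that("per-gene functional shares are reported as fractions", {
  genes <- c(rep("GCKR", 11), rep("NCAN", 16), rep("LYPLAL1", 7),
             rep("PPP1R3B", 4), rep("TM6SF2", 9))
  calls <- data.frame(annotation = rep("missense", 47), gene = genes,
                      maf = rep(0.001, 47))
  sm <- summarize_variant_classes(calls)
  expect_equal(sm$n_functional, 47)
  expect_equal(unname(sm$functional_gene_share["GCKR"]), 11 / 47,
               tolerance = 1e-12)
  expect_equal(unname(sm$functional_gene_share["NCAN"]), 16 / 47,
               tolerance = 1e-12)
  expect_lt(abs(sm$functional_gene_share[["GCKR"]] - 0.23), 0.01)
  expect_lt(abs(sm$functional_gene_share[["NCAN"]] - 0.34), 0.01)
})

test_that("an empty call set summarizes to zeros", {
  empty <- data.frame(annotation = character(0), gene = character(0),
                      maf = numeric(0))
  sm <- summarize_variant_classes(empty)
  expect_equal(sm$n, 0)
  expect_equal(sm$n_intronic, 0)
  expect_equal(sm$n_exonic, 0)
  expect_equal(sum(sm$by_annotation), 0)
})
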
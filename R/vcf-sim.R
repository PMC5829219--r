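.panel_genes <- c("GCKR", "PPP1R3B", "NCAN", "LYPLAL1", "TM6SF2")

.annotation_levels <- c("nonsense", "frameshift", "splice-region",
                        "missense", "synonymous", "intronic", "other")

.qc_rules <- c("DP", "GQ", "AF", "STRAND")

#' Simulate a VCF of candidate-gene variant calls
#'
#' Emits a syntactically valid VCF v4.2 with a single sample whose FORMAT
#' fields carry the read depth (DP), genotype quality (GQ), alternate
#' allele fraction in percent (AF), and the per-strand alternate
#' observation counts (SAF/SAR) that the post-caller quality filter
#' consumes.  A fraction of records is generated to violate exactly one
#' filter rule each, cycling through DP, GQ, AF and STRAND so that every
#' rule is exercised whenever at least four failing records are
#' requested; the intended verdict is recorded in the INFO key `EXPECT`
#' (`PASS` or the failed rule), which the filter itself never reads.
#' Each record also carries `GENE`, `ANN` (annotation class) and `MAF`
#' INFO keys used by the classification helpers.
#'
#' @param n_variants Number of records.
#' @param qc_fail_fraction Fraction of records built to fail QC, in
#'   \[0, 1\].
#' @param seed Integer seed.
#' @param annotation Optional character vector of length `n_variants`
#'   giving the annotation class per record (from
#'   `r paste(.annotation_levels, collapse = ", ")`); sampled if `NULL`.
#' @param genes Optional character vector of gene symbols per record;
#'   sampled from the five-gene panel if `NULL`.
#' @param path Optional file path; if supplied the VCF text is written
#'   there.
#' @return Invisibly, the VCF lines as a character vector.
#' @export
simulate_vcf <- function(n_variants, qc_fail_fraction = 0, seed = 1L,
                         annotation = NULL, genes = NULL, path = NULL) {
  stopifnot(n_variants >= 1)
  if (qc_fail_fraction < 0 || qc_fail_fraction > 1) {
    stop("qc_fail_fraction must lie in [0, 1]")
  }
  set.seed(seed)
  n <- as.integer(n_variants)
  if (is.null(annotation)) {
    annotation <- sample(.annotation_levels, n, replace = TRUE,
                         prob = c(0.01, 0.01, 0.02, 0.26, 0.12, 0.56, 0.02))
  }
  stopifnot(length(annotation) == n, all(annotation %in% .annotation_levels))
  if (is.null(genes)) genes <- sample(.panel_genes, n, replace = TRUE)
  stopifnot(length(genes) == n)

  n_fail <- round(n * qc_fail_fraction)
  fail_idx <- if (n_fail > 0) sort(sample.int(n, n_fail)) else integer(0)
  fail_rule <- rep("PASS", n)
  if (n_fail > 0) {
    fail_rule[fail_idx] <- rep_len(.qc_rules, n_fail)
  }

  bases <- c("A", "C", "G", "T")
  pos <- sort(sample.int(5e5, n)) + 1e6L
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  maf <- signif(stats::rbeta(n, 0.3, 4) * 0.5, 3)

  dp <- sample(40:200, n, replace = TRUE)
  gq <- sample(40:99, n, replace = TRUE)
  hom <- stats::runif(n) < 0.2
  af <- ifelse(hom, stats::runif(n, 90, 100), stats::runif(n, 38, 50))

  # single-rule violations
  dp[fail_rule == "DP"] <- sample(5:29, sum(fail_rule == "DP"), replace = TRUE)
  gq[fail_rule == "GQ"] <- sample(0:29, sum(fail_rule == "GQ"), replace = TRUE)
  af[fail_rule == "AF"] <- stats::runif(sum(fail_rule == "AF"), 51, 69)

  af <- round(af, 1)
  altn <- pmax(1L, pmin(dp, as.integer(round(dp * af / 100))))
  saf <- as.integer(round(altn * stats::runif(n, 0.4, 0.6)))
  saf <- pmax(pmin(saf, altn - 1L), 1L)
  saf[altn == 1L] <- 1L  # degenerate single-read alt stays one-sided
  sar <- altn - saf
  # STRAND violations: all alternate reads on one strand
  strand_bad <- fail_rule == "STRAND"
  saf[strand_bad] <- altn[strand_bad]
  sar[strand_bad] <- 0L

  gt <- ifelse(af > 50, "1/1", "0/1")
  info <- sprintf("GENE=%s;ANN=%s;MAF=%s;EXPECT=%s",
                  genes, annotation, format(maf, trim = TRUE), fail_rule)
  records <- sprintf(
    "chr1\t%d\t.\t%s\t%s\t%d\t.\t%s\tGT:DP:GQ:AF:SAF:SAR\t%s:%d:%d:%s:%d:%d",
    pos, ref, alt, gq, info, gt, dp, gq, format(af, trim = TRUE), saf, sar
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=candgene::simulate_vcf",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Annotation class\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Population minor allele frequency\">",
    "##INFO=<ID=EXPECT,Number=1,Type=String,Description=\"Intended QC verdict (generator label)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction, percent\">",
    "##FORMAT=<ID=SAF,Number=1,Type=Integer,Description=\"Alternate observations, forward strand\">",
    "##FORMAT=<ID=SAR,Number=1,Type=Integer,Description=\"Alternate observations, reverse strand\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE1"
  )
  lines <- c(header, records)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
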
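#' Default VCF field-name mapping for QC metrics
#'
#' Maps the QC metric roles (depth, genotype quality, alternate allele
#' fraction in percent, per-strand alternate observation counts) to the
#' VCF keys they are stored under.  Each metric is sought first among
#' the per-sample FORMAT fields and then in INFO, so the same mapping
#' covers both the Torrent dialect (SAF/SAR in INFO) and the generic
#' layout written by [simulate_vcf()].
#'
#' @return Named character vector with entries `dp`, `gq`, `af`, `saf`,
#'   `sar`.
#' @export
default_field_map <- function() {
  c(dp = "DP", gq = "GQ", af = "AF", saf = "SAF", sar = "SAR")
}

#' Read variant calls from a VCF file
#'
#' Parses a VCF v4.2 file and assembles one row per record with the QC
#' metrics and annotation fields used downstream.  Multi-sample files
#' use the first sample's FORMAT values.
#'
#' @param path VCF file path.
#' @param field_map Metric-to-key mapping, see [default_field_map()].
#' @return A data.frame of class `variant_calls` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `dp`, `gq`, `af` (percent), `saf`, `sar`,
#'   `gene`, `annotation`, `maf` (fraction, `NA` if unknown).
#' @export
read_variant_calls <- function(path, field_map = default_field_map()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  pull <- function(key) {
    val <- rep(NA_character_, n)
    gt_keys <- character(0)
    if (ncol(v@gt) >= 2L) {
      fmt <- strsplit(v@gt[, 1L], ":", fixed = TRUE)
      smp <- strsplit(v@gt[, 2L], ":", fixed = TRUE)
      val <- mapply(function(f, s) {
        i <- match(key, f)
        if (is.na(i) || i > length(s)) NA_character_ else s[i]
      }, fmt, smp, USE.NAMES = FALSE)
    }
    miss <- is.na(val)
    if (any(miss)) {
      inf <- vcfR::extract.info(v, element = key)
      if (!is.null(inf)) val[miss] <- inf[miss]
    }
    val
  }
  num <- function(key) suppressWarnings(as.numeric(pull(key)))
  gene <- vcfR::extract.info(v, element = "GENE")
  ann  <- vcfR::extract.info(v, element = "ANN")
  maf  <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "MAF")))
  out <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    dp = num(field_map[["dp"]]), gq = num(field_map[["gq"]]),
    af = num(field_map[["af"]]),
    saf = num(field_map[["saf"]]), sar = num(field_map[["sar"]]),
    gene = if (is.null(gene)) NA_character_ else gene,
    annotation = if (is.null(ann)) NA_character_ else ann,
    maf = maf,
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Post-caller high-confidence variant filter
#'
#' Applies the resequencing pipeline's quality rules to each call:
#' depth DP >= 30, genotype quality GQ >= 30, alternate allele fraction
#' (percent) within the heterozygous window \[33, 50\] or the homozygous
#' window \[70, 100\], and balanced strand support -- the rarer strand
#' must carry at least `strand_balance_min` of the alternate
#' observations.  All thresholds are inclusive.  A call with alternate
#' fraction above zero but no recorded alternate observations on either
#' strand fails the strand rule.
#'
#' @param calls A `variant_calls` data.frame (or any data.frame with
#'   numeric `dp`, `gq`, `af`, `saf`, `sar` columns).
#' @param strand_balance_min Minimum fraction of alternate observations
#'   on the rarer strand; default 0.2.
#' @return The input with two added columns: `kept` (logical) and
#'   `reasons` (character; failed rules from DP, GQ, AF, STRAND joined
#'   by `","`, empty when kept).
#' @export
filter_high_confidence <- function(calls, strand_balance_min = 0.2) {
  stopifnot(is.data.frame(calls),
            all(c("dp", "gq", "af", "saf", "sar") %in% names(calls)))
  if (strand_balance_min < 0 || strand_balance_min > 0.5) {
    stop("strand_balance_min must lie in [0, 0.5]")
  }
  dp <- calls$dp; gq <- calls$gq; af <- calls$af
  saf <- calls$saf; sar <- calls$sar
  if (any(saf + sar > dp, na.rm = TRUE)) {
    stop("invalid calls: saf + sar exceeds dp")
  }
  fail_dp <- !(dp >= 30)
  fail_gq <- !(gq >= 30)
  fail_af <- !((af >= 33 & af <= 50) | (af >= 70 & af <= 100))
  tot <- saf + sar
  balance <- ifelse(tot > 0, pmin(saf, sar) / tot, NA_real_)
  fail_strand <- ifelse(tot > 0, balance < strand_balance_min, af > 0)
  reasons <- character(nrow(calls))
  rule_fail <- cbind(DP = fail_dp, GQ = fail_gq, AF = fail_af,
                     STRAND = fail_strand)
  reasons <- apply(rule_fail, 1L, function(r) {
    paste(.qc_rules[which(r)], collapse = ",")
  })
  calls$kept <- reasons == ""
  calls$reasons <- reasons
  calls
}

#' Classify a population minor-allele frequency
#'
#' Partitions \[0, 0.5\] into `rare` (MAF < 0.01), `low_frequency`
#' (0.01 <= MAF < 0.05) and `common` (MAF >= 0.05).
#'
#' @param maf Numeric vector of minor-allele fractions in \[0, 0.5\].
#' @return Character vector of class labels.
#' @export
classify_maf <- function(maf) {
  if (any(!is.finite(maf)) || any(maf < 0) || any(maf > 0.5)) {
    stop("maf must lie in [0, 0.5] (minor allele)")
  }
  ifelse(maf < 0.01, "rare",
         ifelse(maf < 0.05, "low_frequency", "common"))
}

#' Classify an annotation as functional or not
#'
#' Functional classes are nonsense, frameshift, splice-region and
#' missense; synonymous, intronic and other variants are
#' non-functional.
#'
#' @param annotation Character vector over the closed vocabulary
#'   `r paste(.annotation_levels, collapse = ", ")`.
#' @return Character vector, `"functional"` or `"non_functional"`.
#' @export
classify_function <- function(annotation) {
  bad <- setdiff(unique(annotation), .annotation_levels)
  if (length(bad)) {
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "))
  }
  functional <- c("nonsense", "frameshift", "splice-region", "missense")
  ifelse(annotation %in% functional, "functional", "non_functional")
}

#' Summarize variant annotation and frequency classes
#'
#' Cross-tabulates calls by annotation class and MAF class and reports
#' the headline counts of a resequencing screen: intronic vs exonic
#' records (exonic = nonsense, frameshift, missense or synonymous),
#' functional variants, and the per-gene share of functional variants.
#'
#' @param calls A `variant_calls` data.frame with `annotation` and
#'   optionally `maf` and `gene` columns.
#' @return A list with `n`, `by_annotation`, `n_intronic`, `n_exonic`,
#'   `n_functional`, `functional_gene_share` (fractions), and `cross`
#'   (annotation x MAF-class table over calls with known MAF).
#' @export
summarize_variant_classes <- function(calls) {
  stopifnot(is.data.frame(calls), "annotation" %in% names(calls))
  ann <- factor(calls$annotation, levels = .annotation_levels)
  exonic_classes <- c("nonsense", "frameshift", "missense", "synonymous")
  by_ann <- table(ann)
  maf_known <- if ("maf" %in% names(calls)) !is.na(calls$maf) else
    rep(FALSE, nrow(calls))
  cross <- if (any(maf_known)) {
    table(annotation = ann[maf_known],
          maf_class = factor(classify_maf(calls$maf[maf_known]),
                             levels = c("rare", "low_frequency", "common")))
  } else {
    table(annotation = factor(character(0), levels = .annotation_levels),
          maf_class = factor(character(0),
                             levels = c("rare", "low_frequency", "common")))
  }
  functional <- classify_function(calls$annotation) == "functional"
  share <- NULL
  if ("gene" %in% names(calls) && any(functional)) {
    tab <- table(calls$gene[functional])
    share <- as.numeric(tab) / sum(functional)
    names(share) <- names(tab)
  }
  list(
    n = nrow(calls),
    by_annotation = by_ann,
    n_intronic = sum(ann == "intronic", na.rm = TRUE),
    n_exonic = sum(ann %in% exonic_classes, na.rm = TRUE),
    n_functional = sum(functional),
    functional_gene_share = share,
    cross = cross
  )
}
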
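#' Case/control genotype counts
#'
#' A 2 x 3 contingency structure of genotype counts, with genotypes
#' ordered `aa`, `aA`, `AA` where `A` is the risk (minor) allele.
#'
#' @param case,control Length-3 non-negative integer vectors
#'   `(aa, aA, AA)`.
#' @return Matrix of class `genotype_counts` (rows case/control).
#' @export
genotype_counts <- function(case, control) {
  stopifnot(length(case) == 3L, length(control) == 3L,
            all(case >= 0), all(control >= 0),
            sum(case) > 0, sum(control) > 0)
  m <- rbind(case = case, control = control)
  colnames(m) <- c("aa", "aA", "AA")
  structure(m, class = c("genotype_counts", "matrix"))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of observed genotype counts
#' against the counts expected under HWE at the sample allele
#' frequency.  A monomorphic sample is in trivial equilibrium
#' (statistic 0, p = 1).
#'
#' @param counts Length-3 vector `(aa, aA, AA)` for one group.
#' @return List with `statistic`, `df` (1), `p.value`, and the sample
#'   risk-allele frequency `allele_freq`.
#' @export
hwe_chi2 <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0), sum(counts) > 0)
  n <- sum(counts)
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(statistic = 0, df = 1L, p.value = 1, allele_freq = unname(p)))
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = unname(stat), df = 1L,
       p.value = stats::pchisq(stat, 1L, lower.tail = FALSE),
       allele_freq = unname(p))
}

#' Collapse genotype counts under a penetrance model
#'
#' Dominant: carriers of at least one risk allele are exposed
#' (`aA + AA`); recessive: only risk-allele homozygotes are exposed
#' (`AA`).
#'
#' @param counts A [genotype_counts()] object.
#' @param model `"dominant"` or `"recessive"`.
#' @return 2 x 2 matrix of class `table2x2`, rows case/control, columns
#'   exposed/unexposed.
#' @export
collapse_genotypes <- function(counts, model = c("dominant", "recessive")) {
  stopifnot(inherits(counts, "genotype_counts"))
  model <- match.arg(model)
  exposed <- if (model == "dominant") counts[, "aA"] + counts[, "AA"]
             else counts[, "AA"]
  m <- cbind(exposed = exposed, unexposed = rowSums(counts) - exposed)
  rownames(m) <- c("case", "control")
  structure(m, class = c("table2x2", "matrix"), model = model)
}

#' Uncorrected Pearson chi-square test
#'
#' Pearson's chi-square without continuity correction, on a 2 x 2 or
#' 2 x 3 contingency table; df = (rows - 1)(cols - 1).
#'
#' @param tab Matrix of counts with positive margins.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- unclass(as.matrix(tab))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: chi-square statistic undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value))
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' OR = ad/bc for the 2 x 2 table (a = exposed cases, b = unexposed
#' cases, c = exposed controls, d = unexposed controls), with the Woolf
#' log-scale interval exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#' A zero cell triggers the Haldane-Anscombe 0.5 correction and the
#' result is flagged both `corrected` and non-`estimable` (reported the
#' way published tables print a dash for such comparisons).
#'
#' @param tab A `table2x2` matrix (rows case/control, columns
#'   exposed/unexposed) or any 2 x 2 count matrix in that layout.
#' @param conf_z Normal quantile for the interval (default 1.96).
#' @return List with `or`, `ci_low`, `ci_high`, `corrected`,
#'   `estimable`.
#' @export
odds_ratio_woolf <- function(tab, conf_z = 1.96) {
  tab <- unclass(as.matrix(tab))
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - conf_z * se),
       ci_high = exp(log(or) + conf_z * se),
       corrected = corrected,
       estimable = !corrected)
}

#' Per-SNP association under a penetrance model
#'
#' For the genotypic model: uncorrected Pearson chi-square on the full
#' 2 x 3 table plus per-genotype odds ratios against the `aa` reference
#' (heterozygote and homozygote rows).  For dominant/recessive models:
#' the collapsed 2 x 2 chi-square and Woolf odds ratio.
#'
#' @param counts A [genotype_counts()] object.
#' @param model `"genotypic"`, `"dominant"` or `"recessive"`.
#' @return A list of class `assoc_result`: `model`, `statistic`, `df`,
#'   `p.value`, and either `or`/`ci_low`/`ci_high` (collapsed models)
#'   or `or_het`/`or_hom` sublists (genotypic model), plus the table
#'   tested.
#' @export
snp_association <- function(counts,
                            model = c("genotypic", "dominant",
                                      "recessive")) {
  stopifnot(inherits(counts, "genotype_counts"))
  model <- match.arg(model)
  if (model == "genotypic") {
    # a genotype unobserved in both groups carries no information:
    # drop the empty column rather than fail (df adjusts accordingly)
    tab <- unclass(counts)[, colSums(counts) > 0, drop = FALSE]
    ct <- if (ncol(tab) >= 2) pearson_chi2(tab) else
      list(statistic = NA_real_, df = 0L, p.value = NA_real_)
    het <- odds_ratio_woolf(counts[, c("aA", "aa")])
    hom <- odds_ratio_woolf(counts[, c("AA", "aa")])
    res <- list(model = model, statistic = ct$statistic, df = ct$df,
                p.value = ct$p.value, or_het = het, or_hom = hom,
                table = counts)
  } else {
    tab <- collapse_genotypes(counts, model)
    if (any(colSums(tab) == 0)) {
      # e.g. no risk-allele homozygote in either group under the
      # recessive model: the comparison is not estimable
      res <- list(model = model, statistic = NA_real_, df = 1L,
                  p.value = NA_real_, or = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, corrected = FALSE,
                  estimable = FALSE, table = tab)
    } else {
      ct <- pearson_chi2(tab)
      or <- odds_ratio_woolf(tab)
      res <- c(list(model = model, statistic = ct$statistic, df = ct$df,
                    p.value = ct$p.value), or, list(table = tab))
    }
  }
  structure(res, class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s model: chi2 = %.3f (df %d), p = %.4g\n",
              x$model, x$statistic, x$df, x$p.value))
  if (!is.null(x$or)) {
    cat(sprintf("  OR = %.2f (95%% CI %.2f-%.2f)%s\n", x$or, x$ci_low,
                x$ci_high,
                if (isTRUE(x$corrected)) " [0.5-corrected]" else ""))
  }
  if (!is.null(x$or_het)) {
    fmt <- function(o, lab) {
      if (o$estimable) {
        sprintf("  %s vs aa: OR = %.2f (%.2f-%.2f)\n", lab, o$or,
                o$ci_low, o$ci_high)
      } else sprintf("  %s vs aa: OR not estimable (zero cell)\n", lab)
    }
    cat(fmt(x$or_het, "aA"), fmt(x$or_hom, "AA"), sep = "")
  }
  invisible(x)
}

#' Carrier-burden enrichment for one gene
#'
#' Compares the fraction of subjects carrying at least one qualifying
#' (functional) variant in a gene between cases and controls: 2 x 2
#' Pearson chi-square and Woolf odds ratio.
#'
#' @param carrier Logical vector, one entry per subject.
#' @param status Character or factor vector aligned with `carrier`,
#'   values `"case"`/`"control"`.
#' @return A list of class `assoc_result` with the 2 x 2 table,
#'   chi-square and OR; flagged non-estimable when no subject carries a
#'   variant.
#' @export
carrier_burden <- function(carrier, status) {
  stopifnot(length(carrier) == length(status), is.logical(carrier))
  status <- factor(as.character(status), levels = c("case", "control"))
  if (any(is.na(status))) stop("status must be 'case' or 'control'")
  tab <- cbind(
    exposed = c(sum(carrier & status == "case"),
                sum(carrier & status == "control")),
    unexposed = c(sum(!carrier & status == "case"),
                  sum(!carrier & status == "control"))
  )
  rownames(tab) <- c("case", "control")
  tab <- structure(tab, class = c("table2x2", "matrix"))
  if (sum(tab[, "exposed"]) == 0) {
    return(structure(list(model = "carrier_burden", statistic = NA_real_,
                          df = 1L, p.value = NA_real_, or = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          corrected = FALSE, estimable = FALSE,
                          table = tab),
                     class = "assoc_result"))
  }
  ct <- pearson_chi2(tab)
  or <- odds_ratio_woolf(tab)
  structure(c(list(model = "carrier_burden", statistic = ct$statistic,
                   df = ct$df, p.value = ct$p.value), or,
              list(table = tab)),
            class = "assoc_result")
}

#' Steatosis severity classes from the Hamaguchi grade
#'
#' The ultrasound steatosis grade on the 0--6 Hamaguchi scale maps to
#' four classes (0 absent, 1--2 mild, 3--4 moderate, 5--6 severe) and a
#' binary severe flag (grade 5--6) used for severity association.
#'
#' @param grade Integer vector of grades in 0..6.
#' @return Data.frame with `grade`, `class4` (ordered factor
#'   absent/mild/moderate/severe) and `severe` (logical).
#' @export
severity_classes <- function(grade) {
  if (any(!is.finite(grade)) || any(grade != as.integer(grade)) ||
      any(grade < 0) || any(grade > 6)) {
    stop("grade must be an integer in 0..6")
  }
  class4 <- cut(grade, breaks = c(-0.5, 0.5, 2.5, 4.5, 6.5),
                labels = c("absent", "mild", "moderate", "severe"),
                ordered_result = TRUE)
  data.frame(grade = as.integer(grade), class4 = class4,
             severe = grade >= 5)
}
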
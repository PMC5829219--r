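#' Default 4-SNP genetic risk score weights
#'
#' Per-allele log-odds beta-coefficients for the four fatty-liver index
#' SNPs, taken as fixed external weights (Dallas Heart Study effect
#' sizes): rs738409 (PNPLA3, G) 0.2653, rs58542926 (TM6SF2, T) 0.2711,
#' rs1260326 (GCKR, T) 0.0649, rs641738 (MBOAT7, T) 0.0575.
#'
#' @return Data.frame with columns `snp_id`, `gene`, `risk_allele`,
#'   `beta`.
#' @export
default_grs_weights <- function() {
  data.frame(
    snp_id = c("rs738409", "rs58542926", "rs1260326", "rs641738"),
    gene = c("PNPLA3", "TM6SF2", "GCKR", "MBOAT7"),
    risk_allele = c("G", "T", "T", "T"),
    beta = c(0.2653, 0.2711, 0.0649, 0.0575),
    stringsAsFactors = FALSE
  )
}

#' Default weighted-GRS tertile boundaries
#'
#' The published cohort's tertile cut points for the weighted 4-SNP
#' score: T1 <= 0.1775 < T2 <= 0.3877 < T3.
#'
#' @return Numeric length-2 vector.
#' @export
default_tertile_boundaries <- function() c(0.1775, 0.3877)

.dosage_matrix <- function(dosages, snp_ids = NULL) {
  if (is.data.frame(dosages)) dosages <- as.matrix(dosages)
  if (is.null(dim(dosages))) dosages <- matrix(dosages, nrow = 1L,
                                               dimnames = list(NULL,
                                                               names(dosages)))
  if (!is.null(snp_ids)) {
    if (is.null(colnames(dosages)) && ncol(dosages) == length(snp_ids)) {
      colnames(dosages) <- snp_ids
    }
    missing <- setdiff(snp_ids, colnames(dosages))
    if (length(missing)) {
      stop("dosages missing SNP(s): ", paste(missing, collapse = ", "))
    }
    dosages <- dosages[, snp_ids, drop = FALSE]
  }
  storage.mode(dosages) <- "double"
  if (any(is.na(dosages))) {
    stop("missing dosage; subjects with incomplete genotypes must be ",
         "excluded (no imputation)")
  }
  if (any(!dosages %in% c(0, 1, 2))) stop("dosages must be 0, 1 or 2")
  dosages
}

#' Unweighted (count) genetic risk score
#'
#' Plain sum of risk-allele dosages across the panel SNPs; for the
#' 4-SNP panel the theoretical range is 0--8.
#'
#' @param dosages Numeric vector (one subject) or matrix/data.frame
#'   (subjects x SNPs) of risk-allele dosages 0/1/2.
#' @return Integer score(s).
#' @export
unweighted_grs <- function(dosages) {
  d <- .dosage_matrix(dosages)
  as.integer(rowSums(d))
}

#' Weighted genetic risk score
#'
#' Sum over SNPs of the per-allele beta-coefficient times the
#' risk-allele dosage.
#'
#' @param dosages As in [unweighted_grs()]; columns (or names) must
#'   match `weights$snp_id`.
#' @param weights Weights table, see [default_grs_weights()].
#' @return Numeric score(s).
#' @export
weighted_grs <- function(dosages, weights = default_grs_weights()) {
  stopifnot(is.data.frame(weights),
            all(c("snp_id", "beta") %in% names(weights)),
            all(is.finite(weights$beta)))
  d <- .dosage_matrix(dosages, weights$snp_id)
  as.numeric(d %*% weights$beta)
}

#' Assign weighted-GRS tertiles
#'
#' T1 for score <= b1, T2 for b1 < score <= b2, T3 above b2 (left
#' intervals closed on the right, matching the published boundaries).
#'
#' @param score Numeric vector of weighted scores.
#' @param boundaries Ascending length-2 cut points; default
#'   [default_tertile_boundaries()].
#' @return Factor with levels T1, T2, T3.
#' @export
assign_tertile <- function(score, boundaries = default_tertile_boundaries()) {
  stopifnot(length(boundaries) == 2L, boundaries[1] < boundaries[2])
  cut(score, breaks = c(-Inf, boundaries, Inf),
      labels = c("T1", "T2", "T3"), right = TRUE)
}

#' Empirical tertile boundaries of a score distribution
#'
#' 33.3 and 66.7 percentiles of the supplied scores.
#'
#' @param scores Numeric vector with at least 3 distinct values.
#' @return Numeric length-2 vector.
#' @export
recompute_tertile_boundaries <- function(scores) {
  if (length(unique(scores)) < 3L) {
    stop("degenerate score distribution: need at least 3 distinct values")
  }
  unname(stats::quantile(scores, probs = c(1, 2) / 3))
}

#' Tertile-by-status association of the weighted GRS
#'
#' Uncorrected Pearson chi-square over the 2 x 3 status-by-tertile
#' table, plus Woolf odds ratios of each upper tertile against T1.
#'
#' @param tertile Factor from [assign_tertile()].
#' @param status `"case"`/`"control"` vector aligned with `tertile`.
#' @return List of class `assoc_result` with `statistic`, `df`,
#'   `p.value`, `or_t2`, `or_t3` (each a Woolf OR list), `table`, and
#'   `complete` (FALSE when a tertile is empty).
#' @export
grs_trend_test <- function(tertile, status) {
  stopifnot(length(tertile) == length(status))
  tertile <- factor(tertile, levels = c("T1", "T2", "T3"))
  status <- factor(as.character(status), levels = c("case", "control"))
  tab <- table(status = status, tertile = tertile)
  complete <- all(colSums(tab) > 0)
  if (!complete) {
    warning("empty tertile: trend test not estimable")
    return(structure(list(model = "grs_trend", statistic = NA_real_,
                          df = 2L, p.value = NA_real_, table = tab,
                          complete = FALSE),
                     class = "assoc_result"))
  }
  ct <- pearson_chi2(tab)
  or_vs_t1 <- function(t) {
    odds_ratio_woolf(cbind(exposed = tab[, t], unexposed = tab[, "T1"]))
  }
  structure(
    list(model = "grs_trend", statistic = ct$statistic, df = ct$df,
         p.value = ct$p.value, or_t2 = or_vs_t1("T2"),
         or_t3 = or_vs_t1("T3"), table = tab, complete = TRUE),
    class = "assoc_result"
  )
}

#' Per-subject GRS profile table
#'
#' Computes unweighted and weighted scores and tertile labels for a
#' subject table.  Subjects missing any panel genotype are excluded
#' (logged via a message), matching the complete-case GRS policy.
#'
#' @param subjects Subject table with one dosage column per
#'   `weights$snp_id` and a `subject_id` column.
#' @param weights See [default_grs_weights()].
#' @param boundaries Tertile cut points, or `NULL` to recompute them
#'   empirically from the weighted scores.
#' @return Data.frame `subject_id`, `unweighted`, `weighted`,
#'   `tertile`; the boundaries used are attached as attribute
#'   `boundaries`.
#' @export
grs_profile <- function(subjects, weights = default_grs_weights(),
                        boundaries = default_tertile_boundaries()) {
  stopifnot(all(weights$snp_id %in% names(subjects)))
  d <- as.matrix(subjects[, weights$snp_id, drop = FALSE])
  complete <- stats::complete.cases(d)
  if (any(!complete)) {
    message(sum(!complete), " subject(s) excluded from GRS: missing genotype")
  }
  d <- d[complete, , drop = FALSE]
  w <- weighted_grs(d, weights)
  if (is.null(boundaries)) boundaries <- recompute_tertile_boundaries(w)
  out <- data.frame(
    subject_id = subjects$subject_id[complete],
    unweighted = unweighted_grs(d),
    weighted = w,
    tertile = assign_tertile(w, boundaries),
    stringsAsFactors = FALSE
  )
  attr(out, "boundaries") <- boundaries
  out
}
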
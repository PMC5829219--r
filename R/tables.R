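#' Reference genotype counts for the 4-SNP NAFLD panel
#'
#' Case/control genotype counts at the four index SNPs from a published
#' ultrasound-defined NAFLD case-control cohort (218 cases, 227
#' controls), used as worked-example inputs for the contingency
#' machinery.  Genotypes are ordered by risk-allele dosage (aa, aA, AA
#' with A the risk allele).  Note on TM6SF2 rs58542926: the published
#' genotype table prints 161 wild-type cases, but the group total, the
#' per-genotype odds ratios and the dominant-model statistics are only
#' mutually consistent with the 193 wild-type carriers stated in the
#' accompanying text; 193 is used here.  No case was homozygous for the
#' TM6SF2 risk allele.
#'
#' @return Named list of [genotype_counts()] objects
#'   (`rs738409`, `rs1260326`, `rs58542926`, `rs641738`) with a
#'   `risk_allele` attribute each.
#' @examples
#' counts <- nafld_genotype_counts()
#' snp_association(counts$rs738409, "dominant")
#' @export
nafld_genotype_counts <- function() {
  mk <- function(case, control, risk) {
    g <- genotype_counts(case, control)
    attr(g, "risk_allele") <- risk
    g
  }
  list(
    rs738409   = mk(c(92, 91, 35),  c(123, 56, 48),  "G"),  # PNPLA3
    rs1260326  = mk(c(43, 90, 85),  c(49, 123, 55),  "T"),  # GCKR
    rs58542926 = mk(c(193, 25, 0),  c(214, 11, 2),   "T"),  # TM6SF2
    rs641738   = mk(c(61, 105, 52), c(78, 111, 38),  "T")   # MBOAT7
  )
}
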
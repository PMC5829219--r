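#' Design for analytic case-control association power
#'
#' Describes a one-stage case-control genetic association design in
#' terms of prevalence, risk-allele frequency and the per-allele
#' genotype relative risk under an additive or multiplicative disease
#' model, for the analytic power calculation of [analytic_power()]
#' (the GAS-calculator family of computations).
#'
#' @param n_cases,n_controls Group sizes.
#' @param prevalence Population disease prevalence K in (0, 1).
#' @param freq Risk-allele frequency p in (0, 1).
#' @param rr Per-allele genotype relative risk (> 0).
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @param model `"additive"` (relative risks 1, r, 2r - 1) or
#'   `"multiplicative"` (1, r, r^2).
#' @return Object of class `power_design`.
#' @export
power_design <- function(n_cases, n_controls, prevalence, freq, rr,
                         alpha = 0.05,
                         model = c("additive", "multiplicative")) {
  model <- match.arg(model)
  stopifnot(n_cases > 0, n_controls > 0, rr > 0)
  for (v in c(prevalence = prevalence, freq = freq, alpha = alpha)) {
    if (v <= 0 || v >= 1) stop("prevalence, freq and alpha must lie in (0,1)")
  }
  if (model == "additive" && 2 * rr - 1 <= 0) {
    stop("additive model needs rr > 0.5 (homozygote relative risk 2r - 1)")
  }
  structure(
    list(n_cases = n_cases, n_controls = n_controls,
         prevalence = prevalence, freq = freq, rr = rr, alpha = alpha,
         model = model),
    class = "power_design"
  )
}

.hwe_probs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

.rr_vector <- function(design) {
  if (design$model == "additive") c(1, design$rr, 2 * design$rr - 1)
  else c(1, design$rr, design$rr^2)
}

#' Genotype penetrances implied by a power design
#'
#' Solves the baseline penetrance f0 from
#' K = sum_g P(g | HWE) f_g with genotype relative risks (1, r, 2r - 1)
#' for the additive model or (1, r, r^2) for the multiplicative model,
#' and returns the three penetrances (f0, f1, f2).
#'
#' @param design A [power_design()].
#' @return Numeric length-3 vector of penetrances, all in (0, 1).
#' @export
genotype_penetrances <- function(design) {
  stopifnot(inherits(design, "power_design"))
  P <- .hwe_probs(design$freq)
  rrv <- .rr_vector(design)
  f0 <- design$prevalence / sum(P * rrv)
  f <- f0 * rrv
  if (any(f >= 1) || any(f <= 0)) {
    stop("inconsistent design: implied penetrance outside (0, 1)")
  }
  stats::setNames(f, c("f0", "f1", "f2"))
}

#' Genotype distributions among cases and controls
#'
#' Bayes ascertainment of the retrospective design:
#' P(g | case) = P(g) f_g / K and P(g | control) = P(g)(1 - f_g)/(1 - K).
#'
#' @param design A [power_design()].
#' @return List with numeric length-3 vectors `case` and `control`
#'   (ordered aa, aA, AA; each sums to 1) and the implied risk-allele
#'   frequencies `p_case`, `p_control`.
#' @export
case_control_genotype_freqs <- function(design) {
  f <- genotype_penetrances(design)
  P <- .hwe_probs(design$freq)
  K <- design$prevalence
  case <- P * f / K
  control <- P * (1 - f) / (1 - K)
  list(case = unname(case), control = unname(control),
       p_case = unname((case[2] + 2 * case[3]) / 2),
       p_control = unname((control[2] + 2 * control[3]) / 2))
}

#' Analytic power of the allelic case-control test
#'
#' Normal-approximation power of the two-sided 1-df allelic (2N-allele)
#' two-proportion comparison between cases and controls: the critical
#' value uses the pooled null variance and the non-centrality uses the
#' unpooled variances at the design's case/control allele frequencies.
#'
#' @param design A [power_design()].
#' @return Power as a fraction in (0, 1).
#' @examples
#' d <- power_design(218, 227, prevalence = 0.30, freq = 0.03, rr = 2.0)
#' analytic_power(d)  # ~ 0.87
#' @export
analytic_power <- function(design) {
  g <- case_control_genotype_freqs(design)
  m1 <- 2 * design$n_cases
  m0 <- 2 * design$n_controls
  p1 <- g$p_case
  p0 <- g$p_control
  diff <- p1 - p0
  v1 <- p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0
  pbar <- (m1 * p1 + m0 * p0) / (m1 + m0)
  v0 <- pbar * (1 - pbar) * (1 / m1 + 1 / m0)
  z <- stats::qnorm(1 - design$alpha / 2)
  stats::pnorm((diff - z * sqrt(v0)) / sqrt(v1)) +
    stats::pnorm((-diff - z * sqrt(v0)) / sqrt(v1))
}

.allelic_chi2_p <- function(a1, n1, a0, n0) {
  # Pearson chi-square on the 2x2 allele-count table (vectorized)
  b1 <- n1 - a1; b0 <- n0 - a0
  n <- n1 + n0
  stat <- n * (a1 * b0 - b1 * a0)^2 /
    ((a1 + b1) * (a0 + b0) * (a1 + a0) * (b1 + b0))
  stats::pchisq(stat, 1L, lower.tail = FALSE)
}

.trend_chi2_p <- function(cases3, controls3) {
  # Cochran-Armitage trend test with scores 0,1,2 on genotype counts
  x <- c(0, 1, 2)
  n1 <- sum(cases3); n0 <- sum(controls3); n <- n1 + n0
  tot <- cases3 + controls3
  num <- sum(x * (n0 * cases3 - n1 * controls3)) / n
  xbar <- sum(x * tot) / n
  varhat <- n1 * n0 / n * (sum(x^2 * tot) / n - xbar^2)
  stat <- num^2 / varhat
  stats::pchisq(stat, 1L, lower.tail = FALSE)
}

#' Empirical power by Monte-Carlo simulation
#'
#' Simulates `reps` retrospective cohorts by drawing case and control
#' genotype counts from the ascertained distributions of
#' [case_control_genotype_freqs()], runs the chosen 1-df test on each,
#' and returns the rejection fraction at the design alpha with its
#' Monte-Carlo standard error.
#'
#' @param design A [power_design()].
#' @param reps Number of simulated cohorts (>= 200, default 1000).
#' @param seed Integer seed.
#' @param statistic `"allelic"` (default, matching [analytic_power()])
#'   or `"trend"` (Cochran-Armitage).
#' @return List with `power`, `se`, `reps`, `statistic`.
#' @export
empirical_power <- function(design, reps = 1000L, seed = 1L,
                            statistic = c("allelic", "trend")) {
  stopifnot(inherits(design, "power_design"), reps >= 200L)
  statistic <- match.arg(statistic)
  set.seed(seed)
  g <- case_control_genotype_freqs(design)
  ca <- stats::rmultinom(reps, design$n_cases, g$case)
  co <- stats::rmultinom(reps, design$n_controls, g$control)
  if (statistic == "allelic") {
    a1 <- ca[2, ] + 2 * ca[3, ]
    a0 <- co[2, ] + 2 * co[3, ]
    pv <- .allelic_chi2_p(a1, 2 * design$n_cases, a0, 2 * design$n_controls)
  } else {
    pv <- vapply(seq_len(reps), function(i) {
      .trend_chi2_p(ca[, i], co[, i])
    }, numeric(1))
  }
  phat <- mean(pv < design$alpha)
  list(power = phat, se = sqrt(phat * (1 - phat) / reps), reps = reps,
       statistic = statistic)
}

#' Smallest per-allele relative risk detectable at a target power
#'
#' Inverts [analytic_power()] in the relative risk (for rr > 1) by
#' root finding.  The search is bracketed below the largest relative
#' risk consistent with the design (the homozygote penetrance must stay
#' below 1, which caps the feasible relative risk when the prevalence
#' is high).
#'
#' @param design A [power_design()]; its `rr` entry is ignored.
#' @param target_power Desired power (default 0.80).
#' @return The per-allele relative risk achieving the target power.
#' @export
min_detectable_rr <- function(design, target_power = 0.80) {
  stopifnot(inherits(design, "power_design"),
            target_power > design$alpha, target_power < 1)
  pow <- function(r) {
    d <- design; d$rr <- r
    analytic_power(d)
  }
  feasible <- function(r) {
    d <- design; d$rr <- r
    !inherits(tryCatch(genotype_penetrances(d), error = identity),
              "error")
  }
  hi <- 50
  while (hi > 1.01 && !feasible(hi)) hi <- 0.98 * hi
  if (hi <= 1.01) stop("no feasible relative risk above 1 for this design")
  if (pow(hi) < target_power) {
    stop("target power unreachable within the feasible relative-risk range")
  }
  stats::uniroot(function(r) pow(r) - target_power,
                 interval = c(1.0001, hi), tol = 1e-8)$root
}
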
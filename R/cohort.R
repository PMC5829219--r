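#' Specify a biallelic SNP for simulation
#'
#' Describes one index SNP by its risk-allele frequency in the source
#' population and its per-allele odds ratio on disease.  Risk-allele
#' effects act additively on the log-odds scale, the conventional coding
#' for logistic association analyses.
#'
#' @param id SNP identifier (e.g. `"rs738409"`).
#' @param risk_allele_freq Population frequency of the risk allele,
#'   strictly between 0 and 1.
#' @param per_allele_or Odds ratio per copy of the risk allele (> 0);
#'   1 means no effect.
#' @param risk_allele Risk allele base, e.g. `"G"`.
#' @return An object of class `snp_spec`.
#' @examples
#' snp_spec("rs738409", 0.335, 1.6, "G")
#' @export
snp_spec <- function(id, risk_allele_freq, per_allele_or, risk_allele = "A") {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.numeric(risk_allele_freq) || risk_allele_freq <= 0 ||
      risk_allele_freq >= 1) {
    stop("risk_allele_freq must lie strictly in (0, 1)")
  }
  if (!is.numeric(per_allele_or) || per_allele_or <= 0) {
    stop("per_allele_or must be a positive real")
  }
  structure(
    list(id = id, risk_allele_freq = risk_allele_freq,
         per_allele_or = per_allele_or, risk_allele = risk_allele),
    class = "snp_spec"
  )
}

#' Default 4-SNP panel for NAFLD simulation
#'
#' The four index SNPs of the fatty-liver candidate-gene panel with
#' risk-allele frequencies matching the control genotype distributions of
#' the reference cohort (see [nafld_genotype_counts()]) and per-allele
#' odds ratios in the 1.2--2.5 range reported for these loci: PNPLA3
#' rs738409 (G), TM6SF2 rs58542926 (T, low-frequency), GCKR rs1260326 (T)
#' and MBOAT7 rs641738 (T).
#'
#' @return A list of [snp_spec()] objects.
#' @export
default_snp_panel <- function() {
  list(
    snp_spec("rs738409",   0.335, 1.6,  "G"),
    snp_spec("rs58542926", 0.07,  2.5,  "T"),
    snp_spec("rs1260326",  0.42,  1.4,  "T"),
    snp_spec("rs641738",   0.41,  1.25, "T")
  )
}

#' Default covariate distribution parameters
#'
#' Location/scale descriptors for the metabolic covariates of a simulated
#' source population: age and BMI normal; fasting glucose, fasting insulin
#' and triglycerides log-normal (these variables are right-skewed and are
#' log-transformed before entering regressions).  Values are centred
#' between the case and control medians of the reference cohort.
#'
#' @return Named list of parameter lists.
#' @export
default_covariate_params <- function() {
  list(
    age         = list(mean = 52,        sd = 10),
    sex_male    = list(prob = 0.66),
    bmi         = list(mean = 27,        sd = 3.5),
    log_glucose = list(mean = log(88),   sd = 0.12),
    log_insulin = list(mean = log(8.0),  sd = 0.50),
    log_tg      = list(mean = log(105),  sd = 0.45)
  )
}

#' Default covariate effects on the disease log-odds
#'
#' Log-odds coefficients for the covariate terms of the generative
#' disease model, applied to centred covariates: age per year, male sex,
#' BMI per kg/m2, and log-HOMA-IR / log-TG per log unit.  Magnitudes are
#' chosen so that simulated cases show the direction and rough size of
#' the case--control covariate differences seen in metabolic cohorts.
#'
#' @return Named numeric vector.
#' @export
default_covariate_betas <- function() {
  c(age = 0.03, sex_male = 0.30, bmi = 0.15, log_homa = 0.90, log_tg = 0.70)
}

#' Specify a case-control cohort to simulate
#'
#' @param n_cases,n_controls Target group sizes (default 218 / 227, the
#'   reference study design).
#' @param snps List of [snp_spec()] objects; default [default_snp_panel()].
#' @param covariate_params See [default_covariate_params()].
#' @param baseline_prevalence Population disease prevalence at reference
#'   covariate values and zero risk alleles balanced out; default 0.30.
#' @param covariate_betas See [default_covariate_betas()].
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 218, n_controls = 227,
                        snps = default_snp_panel(),
                        covariate_params = default_covariate_params(),
                        baseline_prevalence = 0.30,
                        covariate_betas = default_covariate_betas(),
                        seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0)
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1) {
    stop("baseline_prevalence must lie in (0, 1)")
  }
  if (!length(snps) || !all(vapply(snps, inherits, logical(1), "snp_spec"))) {
    stop("snps must be a non-empty list of snp_spec objects")
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         snps = snps, covariate_params = covariate_params,
         baseline_prevalence = baseline_prevalence,
         covariate_betas = covariate_betas, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Homeostasis model assessment of insulin resistance
#'
#' HOMA-IR = fasting plasma glucose (mg/dL) x fasting insulin (U/L) / 405.
#'
#' @param glucose Fasting plasma glucose in mg/dL (> 0).
#' @param insulin Fasting insulin in U/L (> 0).
#' @return Numeric HOMA-IR index.
#' @examples
#' compute_homa_ir(405, 1)    # 1
#' compute_homa_ir(95, 12.7)  # ~ 2.98
#' @export
compute_homa_ir <- function(glucose, insulin) {
  if (any(!is.finite(glucose)) || any(!is.finite(insulin)) ||
      any(glucose <= 0) || any(insulin <= 0)) {
    stop("glucose and insulin must be positive")
  }
  glucose * insulin / 405
}

# Hamaguchi grade distribution for simulated cases: ~76% moderate-severe
# (grade >= 3) of which ~33% severe (grade 5-6), split evenly within pairs.
.case_grade_probs <- c(
  `1` = 0.1185, `2` = 0.1185, `3` = 0.2185, `4` = 0.2185,
  `5` = 0.163,  `6` = 0.163
)

#' Simulate a retrospective case-control cohort
#'
#' Draws subjects from a source population: genotypes at each SNP under
#' Hardy-Weinberg equilibrium, covariates from the distributions in the
#' spec, and disease status from a logistic model whose log-odds are
#' `logit(baseline_prevalence)` plus additive per-allele log-OR terms
#' (centred at their population expectation) plus centred covariate
#' terms.  Sampling continues (rejection sampling) until the requested
#' numbers of cases and controls are collected; it aborts if quotas are
#' not met within `1000 * (n_cases + n_controls)` population draws.
#' Cases receive an ultrasound steatosis grade on the Hamaguchi 0--6
#' scale with about 76% at grade 3 or higher; controls are grade 0.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame of class `subject_table` with one row per
#'   subject: `subject_id`, `status` (`"case"`/`"control"`), one
#'   risk-allele dosage column (0/1/2) per SNP id, `age`, `sex`
#'   (`"M"`/`"F"`), `bmi`, `glucose`, `insulin`, `homa_ir`, `tg`,
#'   `steatosis_grade`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_target <- spec$n_cases + spec$n_controls
  max_draws <- 1000L * n_target
  cp <- spec$covariate_params
  cb <- spec$covariate_betas
  freqs <- vapply(spec$snps, `[[`, numeric(1), "risk_allele_freq")
  logors <- log(vapply(spec$snps, `[[`, numeric(1), "per_allele_or"))
  snp_ids <- vapply(spec$snps, `[[`, character(1), "id")
  # centres of the linear-predictor terms so the marginal prevalence
  # stays near baseline_prevalence
  mu_log_homa <- cp$log_glucose$mean + cp$log_insulin$mean - log(405)
  b0 <- stats::qlogis(spec$baseline_prevalence)

  cases <- list(); controls <- list()
  n_cases_have <- 0L; n_controls_have <- 0L; drawn <- 0L
  batch <- max(2000L, 2L * n_target)

  while ((n_cases_have < spec$n_cases || n_controls_have < spec$n_controls) &&
         drawn < max_draws) {
    m <- min(batch, max_draws - drawn)
    drawn <- drawn + m
    G <- vapply(freqs, function(p) stats::rbinom(m, 2L, p), integer(m))
    if (m == 1L) G <- matrix(G, nrow = 1L)
    colnames(G) <- snp_ids
    age      <- stats::rnorm(m, cp$age$mean, cp$age$sd)
    sex_male <- stats::rbinom(m, 1L, cp$sex_male$prob)
    bmi      <- stats::rnorm(m, cp$bmi$mean, cp$bmi$sd)
    glucose  <- exp(stats::rnorm(m, cp$log_glucose$mean, cp$log_glucose$sd))
    insulin  <- exp(stats::rnorm(m, cp$log_insulin$mean, cp$log_insulin$sd))
    tg       <- exp(stats::rnorm(m, cp$log_tg$mean, cp$log_tg$sd))
    homa     <- compute_homa_ir(glucose, insulin)
    eta <- b0 +
      as.vector(sweep(G, 2L, 2 * freqs) %*% logors) +
      cb[["age"]]      * (age - cp$age$mean) +
      cb[["sex_male"]] * (sex_male - cp$sex_male$prob) +
      cb[["bmi"]]      * (bmi - cp$bmi$mean) +
      cb[["log_homa"]] * (log(homa) - mu_log_homa) +
      cb[["log_tg"]]   * (log(tg) - cp$log_tg$mean)
    y <- stats::rbinom(m, 1L, stats::plogis(eta))
    df <- data.frame(G, age = age,
                     sex = ifelse(sex_male == 1L, "M", "F"),
                     bmi = bmi, glucose = glucose, insulin = insulin,
                     homa_ir = homa, tg = tg,
                     check.names = FALSE, stringsAsFactors = FALSE)
    need_ca <- spec$n_cases - n_cases_have
    if (need_ca > 0L) {
      idx <- which(y == 1L)
      if (length(idx)) {
        idx <- idx[seq_len(min(need_ca, length(idx)))]
        cases[[length(cases) + 1L]] <- df[idx, , drop = FALSE]
        n_cases_have <- n_cases_have + length(idx)
      }
    }
    need_co <- spec$n_controls - n_controls_have
    if (need_co > 0L) {
      idx <- which(y == 0L)
      if (length(idx)) {
        idx <- idx[seq_len(min(need_co, length(idx)))]
        controls[[length(controls) + 1L]] <- df[idx, , drop = FALSE]
        n_controls_have <- n_controls_have + length(idx)
      }
    }
  }
  if (n_cases_have < spec$n_cases || n_controls_have < spec$n_controls) {
    stop("cohort sampling did not converge within ", max_draws,
         " draws; prevalence too extreme for the requested group sizes")
  }
  out <- rbind(do.call(rbind, cases), do.call(rbind, controls))
  status <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  grade <- integer(nrow(out))
  grade[status == "case"] <- sample(
    1:6, spec$n_cases, replace = TRUE, prob = .case_grade_probs
  )
  out <- cbind(
    data.frame(subject_id = sprintf("S%05d", seq_len(nrow(out))),
               status = status, stringsAsFactors = FALSE),
    out,
    data.frame(steatosis_grade = grade)
  )
  rownames(out) <- NULL
  class(out) <- c("subject_table", "data.frame")
  attr(out, "cohort_spec") <- spec
  out
}

#' Write / read a subject table as TSV
#'
#' The on-disk format is a plain tab-separated table with a header row
#' carrying the column names of [simulate_cohort()] output.
#'
#' @param subjects A subject table data.frame.
#' @param path File path.
#' @return `write_subject_tsv` returns `path` invisibly;
#'   `read_subject_tsv` returns the subject table.
#' @export
write_subject_tsv <- function(subjects, path) {
  utils::write.table(as.data.frame(subjects), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_tsv
#' @export
read_subject_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("subject_table", "data.frame")
  out
}
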
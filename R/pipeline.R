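#' Build a study run configuration
#'
#' Assembles and validates the configuration consumed by
#' [run_study()].  Unknown fields are rejected (fail fast).
#'
#' @param subjects Subject table data.frame, or path to a subject TSV
#'   (see [read_subject_tsv()]).
#' @param vcf Optional path to a VCF of variant calls for the QC stage.
#' @param predictions Optional data.frame or TSV path of per-variant
#'   predictor verdicts for the consensus stage.
#' @param weights GRS weights table (default [default_grs_weights()]).
#' @param covariates Adjustment covariate column names used by the
#'   regression stages; defaults to age, male sex, BMI and the
#'   log-transformed HOMA-IR and triglycerides (skewed covariates enter
#'   on the log scale).
#' @param snp_models Named character vector mapping SNP id to its fixed
#'   penetrance coding (`"dominant"`/`"recessive"`) for the regression
#'   stages; default: dominant for rs738409 and rs58542926, recessive
#'   for rs1260326 and rs641738.
#' @param entry_p,removal_p Stepwise thresholds (defaults 0.05 / 0.10).
#' @param strand_balance_min QC strand-balance threshold (default 0.2).
#' @param grs_boundaries Tertile cut points, or `NULL` for empirical.
#' @param bootstrap_B Bootstrap replicates for the final model (0
#'   disables the bootstrap stage).
#' @param power_designs List of [power_design()] objects to report, or
#'   `NULL` for the study's two reference designs (common freq 0.30 and
#'   low-frequency 0.03, per-allele RR 2.0, prevalence 0.30).
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Optional output directory for the report bundle.
#' @return Object of class `run_config`.
#' @export
run_config <- function(subjects, vcf = NULL, predictions = NULL,
                       weights = default_grs_weights(),
                       covariates = c("age", "sex_male", "bmi",
                                      "log_homa", "log_tg"),
                       snp_models = c(rs738409 = "dominant",
                                      rs58542926 = "dominant",
                                      rs1260326 = "recessive",
                                      rs641738 = "recessive"),
                       entry_p = 0.05, removal_p = 0.10,
                       strand_balance_min = 0.2,
                       grs_boundaries = default_tertile_boundaries(),
                       bootstrap_B = 0L,
                       power_designs = NULL,
                       seed = 1L, out_dir = NULL) {
  if (is.character(subjects)) {
    if (!file.exists(subjects)) stop("subjects file not found: ", subjects)
    subjects <- read_subject_tsv(subjects)
  }
  stopifnot(is.data.frame(subjects))
  if (!is.null(vcf) && !file.exists(vcf)) stop("vcf not found: ", vcf)
  if (is.character(predictions)) {
    if (!file.exists(predictions)) stop("predictions file not found: ",
                                        predictions)
  }
  stopifnot(all(snp_models %in% c("dominant", "recessive")))
  if (entry_p <= 0 || entry_p > 1 || removal_p <= 0 || removal_p > 1) {
    stop("entry_p and removal_p must lie in (0, 1]")
  }
  if (is.null(power_designs)) {
    n1 <- sum(subjects$status == "case")
    n0 <- sum(subjects$status == "control")
    power_designs <- list(
      common = power_design(n1, n0, prevalence = 0.30, freq = 0.30,
                            rr = 2.0),
      low_frequency = power_design(n1, n0, prevalence = 0.30, freq = 0.03,
                                   rr = 2.0)
    )
  }
  structure(
    list(subjects = subjects, vcf = vcf, predictions = predictions,
         weights = weights, covariates = covariates,
         snp_models = snp_models, entry_p = entry_p,
         removal_p = removal_p, strand_balance_min = strand_balance_min,
         grs_boundaries = grs_boundaries,
         bootstrap_B = as.integer(bootstrap_B),
         power_designs = power_designs, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

.derive_columns <- function(subjects) {
  s <- as.data.frame(subjects)
  s$status_bin <- as.integer(s$status == "case")
  if (!"sex_male" %in% names(s) && "sex" %in% names(s)) {
    s$sex_male <- as.integer(s$sex == "M")
  }
  if (!"log_homa" %in% names(s) && "homa_ir" %in% names(s)) {
    s$log_homa <- log(s$homa_ir)
  }
  if (!"log_tg" %in% names(s) && "tg" %in% names(s)) {
    s$log_tg <- log(s$tg)
  }
  s
}

.counts_from_dosages <- function(dosage, status) {
  count3 <- function(d) c(sum(d == 0), sum(d == 1), sum(d == 2))
  genotype_counts(count3(dosage[status == "case"]),
                  count3(dosage[status == "control"]))
}

#' Run the end-to-end study replica
#'
#' Sequences the study pipeline under one configuration: (1) VCF
#' quality filtering and variant-class summary, (2) per-gene
#' carrier-burden enrichment (when the subject table carries
#' `carrier_<GENE>` columns), (3) per-SNP association under genotypic,
#' dominant and recessive models with covariate-adjusted logistic fits,
#' (4) forward-Wald stepwise selection over the coded SNP terms and
#' covariates with Hosmer-Lemeshow, Nagelkerke R2 and optional
#' bootstrap adjustment, (5) GRS profiles and tertile association,
#' (6) analytic power for the configured designs.  Any stage failure
#' aborts with the stage name; partial outputs are removed.  The
#' report is a pure function of (inputs, configuration, seed).
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `study_report` with one element per stage
#'   plus `meta` (seed, config hash, group sizes).
#' @export
run_study <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  written <- character(0)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  subjects <- .derive_columns(config$subjects)
  snp_ids <- names(config$snp_models)
  snp_ids <- snp_ids[snp_ids %in% names(subjects)]
  report <- list()

  # -- QC stage -------------------------------------------------------
  if (!is.null(config$vcf)) {
    report$qc <- stage("qc", {
      calls <- read_variant_calls(config$vcf)
      filtered <- filter_high_confidence(calls, config$strand_balance_min)
      kept <- filtered[filtered$kept, , drop = FALSE]
      say("qc", "%d calls in, %d kept, %d rejected", nrow(filtered),
          nrow(kept), sum(!filtered$kept))
      list(calls = filtered, n_in = nrow(filtered), n_kept = nrow(kept),
           classes = summarize_variant_classes(kept))
    })
  }

  # -- consensus stage ------------------------------------------------
  if (!is.null(config$predictions)) {
    report$consensus <- stage("consensus", {
      preds <- if (is.character(config$predictions)) {
        read_predictions_tsv(config$predictions)
      } else {
        aggregate_predictions(config$predictions)
      }
      say("consensus", "%d variants scored, %d damaging", nrow(preds),
          sum(preds$damaging))
      preds
    })
  }

  # -- burden stage ---------------------------------------------------
  carrier_cols <- grep("^carrier_", names(subjects), value = TRUE)
  if (length(carrier_cols)) {
    report$burden <- stage("burden", {
      res <- lapply(carrier_cols, function(cc) {
        carrier_burden(as.logical(subjects[[cc]]), subjects$status)
      })
      names(res) <- sub("^carrier_", "", carrier_cols)
      pvals <- vapply(res, `[[`, numeric(1), "p.value")
      say("burden", "%d genes tested", length(res))
      list(results = res,
           p_adjusted = stats::p.adjust(pvals, method = "bonferroni"))
    })
  }

  # -- association stage ----------------------------------------------
  report$association <- stage("association", {
    rows <- list()
    for (snp in snp_ids) {
      counts <- .counts_from_dosages(subjects[[snp]], subjects$status)
      hwe <- hwe_chi2(counts["control", ])
      for (model in c("genotypic", "dominant", "recessive")) {
        res <- snp_association(counts, model)
        coding <- config$snp_models[[snp]]
        adj <- NULL
        if (model == coding) {
          term <- paste0(snp, "_", substr(coding, 1, 3))
          subjects[[term]] <- if (coding == "dominant") {
            as.integer(subjects[[snp]] >= 1)
          } else as.integer(subjects[[snp]] == 2)
          fit <- logistic_fit(
            stats::reformulate(c(term, config$covariates), "status_bin"),
            subjects)
          adj <- fit$coefficients[fit$coefficients$term == term, ]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          snp = snp, model = model, chi2 = res$statistic, df = res$df,
          p = res$p.value,
          or = if (!is.null(res$or)) res$or else NA_real_,
          ci_low = if (!is.null(res$ci_low)) res$ci_low else NA_real_,
          ci_high = if (!is.null(res$ci_high)) res$ci_high else NA_real_,
          hwe_control_p = hwe$p.value,
          adj_or = if (!is.null(adj)) adj$or else NA_real_,
          adj_p = if (!is.null(adj)) adj$p.value else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
    say("association", "%d SNPs x 3 models", length(snp_ids))
    do.call(rbind, rows)
  })

  # -- stepwise stage -------------------------------------------------
  report$stepwise <- stage("stepwise", {
    terms <- character(0)
    for (snp in snp_ids) {
      coding <- config$snp_models[[snp]]
      term <- paste0(snp, "_", substr(coding, 1, 3))
      subjects[[term]] <- if (coding == "dominant") {
        as.integer(subjects[[snp]] >= 1)
      } else as.integer(subjects[[snp]] == 2)
      terms <- c(terms, term)
    }
    sw <- stepwise_forward_wald(subjects, "status_bin",
                                candidates = c(terms, config$covariates),
                                entry_p = config$entry_p,
                                removal_p = config$removal_p)
    hl <- hosmer_lemeshow(sw$model)
    out <- list(selected = sw$selected, trace = sw$trace,
                model = sw$model, hosmer_lemeshow = hl,
                nagelkerke_r2 = nagelkerke_r2(sw$model))
    if (config$bootstrap_B > 0L && length(sw$selected)) {
      out$bootstrap <- bootstrap_adjust(
        sw$model$formula, subjects, B = config$bootstrap_B,
        seed = config$seed)
    }
    say("stepwise", "selected: %s",
        if (length(sw$selected)) paste(sw$selected, collapse = ", ")
        else "(none)")
    out
  })

  # -- GRS stage ------------------------------------------------------
  if (all(config$weights$snp_id %in% names(subjects))) {
    report$grs <- stage("grs", {
      prof <- grs_profile(subjects, config$weights,
                          config$grs_boundaries)
      keep <- match(prof$subject_id, subjects$subject_id)
      trend <- grs_trend_test(prof$tertile, subjects$status[keep])
      say("grs", "%d subjects scored", nrow(prof))
      list(profile = prof, trend = trend,
           boundaries = attr(prof, "boundaries"))
    })
  }

  # -- power stage ----------------------------------------------------
  report$power <- stage("power", {
    out <- lapply(config$power_designs, function(d) {
      list(design = d, power = analytic_power(d))
    })
    say("power", "%d designs", length(out))
    out
  })

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(deparse(cfg_for_hash), tmp)
  report$meta <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(tmp)),
    n_cases = sum(subjects$status == "case"),
    n_controls = sum(subjects$status == "control")
  )
  class(report) <- "study_report"

  if (!is.null(config$out_dir)) {
    stage("write", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      wrt <- function(df, name) {
        path <- file.path(config$out_dir, name)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <<- c(written, path)
      }
      wrt(report$association, "association.tsv")
      wrt(report$stepwise$trace, "stepwise_trace.tsv")
      if (!is.null(report$grs)) wrt(report$grs$profile, "grs_profile.tsv")
      meta_path <- file.path(config$out_dir, "meta.json")
      jsonlite::write_json(report$meta, meta_path, auto_unbox = TRUE)
      written <<- c(written, meta_path)
    })
  }
  report
}
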
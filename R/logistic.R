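#' Covariate-adjusted logistic model fit
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()] with
#' a log-likelihood convergence tolerance of 1e-8 and at most 100
#' iterations), reporting per-term coefficients, standard errors, Wald
#' chi-square statistics, p-values and odds ratios with Woolf-type
#' normal intervals.  Aliased (rank-deficient) columns are an error:
#' the design must be full rank after the caller drops redundant terms.
#' Separation is flagged: a fit that fails to converge or produces a
#' diverging coefficient is returned with `converged = FALSE` and a
#' warning rather than silently.
#'
#' @param formula Model formula with a binary (0/1 or two-level factor)
#'   outcome.
#' @param data Data.frame.
#' @return An object of class `logistic_model`: `coefficients`
#'   (data.frame term/beta/se/wald_chi2/p.value/or/ci_low/ci_high),
#'   `ll_fitted`, `ll_null`, `n`, `converged`, `formula` and the
#'   underlying `fit`.
#' @export
logistic_fit <- function(formula, data) {
  fit <- stats::glm(formula, family = stats::binomial(), data = data,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (any(is.na(stats::coef(fit)))) {
    stop("aliased terms in design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  beta <- sm[, 1]; se <- sm[, 2]
  # diverging fit: boundary fitted values with an exploding standard error
  separated <- any(se > 100) &&
    any(stats::fitted(fit) < 1e-8 | stats::fitted(fit) > 1 - 1e-8)
  converged <- fit$converged && !separated
  if (!converged) {
    warning("logistic fit did not converge (possible separation); ",
            "estimates are unreliable")
  }
  wald <- (beta / se)^2
  coefs <- data.frame(
    term = rownames(sm), beta = beta, se = se, wald_chi2 = wald,
    p.value = stats::pchisq(wald, 1L, lower.tail = FALSE),
    or = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    row.names = NULL, stringsAsFactors = FALSE
  )
  null_fit <- stats::update(fit, . ~ 1)
  structure(
    list(coefficients = coefs,
         ll_fitted = as.numeric(stats::logLik(fit)),
         ll_null = as.numeric(stats::logLik(null_fit)),
         n = stats::nobs(fit), converged = converged,
         formula = formula, fit = fit),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("Logistic model, n = %d%s\n", x$n,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  df <- x$coefficients
  df[-1] <- lapply(df[-1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  cat(sprintf("Nagelkerke R2 = %.3f\n", nagelkerke_r2(x)))
  invisible(x)
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell R2 = 1 - exp(2 (llnull - llfit)/n), rescaled by its
#' attainable maximum 1 - exp(2 llnull / n) so that a saturated model
#' reaches 1.
#'
#' @param model A `logistic_model`.
#' @return Fraction in \[0, 1\].
#' @export
nagelkerke_r2 <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  r2_cs <- 1 - exp(2 * (model$ll_null - model$ll_fitted) / model$n)
  r2_max <- 1 - exp(2 * model$ll_null / model$n)
  r2_cs / r2_max
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups subjects into deciles of fitted risk (default 10 groups) and
#' compares observed with expected event counts; the statistic is
#' referred to chi-square with (groups - 2) degrees of freedom.  Tied
#' fitted values can make some quantile cut points coincide; such
#' groups are merged and the merge is noted in the output.  With fewer
#' than three surviving groups the test is non-informative (df < 1) and
#' flagged.
#'
#' @param model A `logistic_model`.
#' @param groups Number of risk groups (>= 2, default 10).
#' @return List with `statistic`, `df`, `p.value`, `groups_used`,
#'   `merged`, `informative` and the per-group observed/expected table.
#' @export
hosmer_lemeshow <- function(model, groups = 10L) {
  stopifnot(inherits(model, "logistic_model"), groups >= 2L)
  phat <- stats::fitted(model$fit)
  y <- model$fit$y
  breaks <- unique(stats::quantile(phat, probs = seq(0, 1,
                                                     length.out = groups + 1)))
  merged <- length(breaks) < groups + 1L
  if (length(breaks) < 3L) breaks <- c(-Inf, breaks)  # degenerate risk
  grp <- cut(phat, breaks = breaks, include.lowest = TRUE)
  obs1 <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  exp1 <- tapply(phat, grp, sum)
  keep <- !is.na(n_g) & n_g > 0
  obs1 <- obs1[keep]; n_g <- n_g[keep]; exp1 <- exp1[keep]
  g <- length(n_g)
  stat <- sum((obs1 - exp1)^2 / exp1 +
              ((n_g - obs1) - (n_g - exp1))^2 / (n_g - exp1))
  df <- g - 2L
  informative <- df >= 1L
  list(
    statistic = unname(stat), df = df,
    p.value = if (informative)
      stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_,
    groups_used = g, merged = merged, informative = informative,
    table = data.frame(group = names(n_g), n = as.integer(n_g),
                       observed = as.integer(obs1),
                       expected = as.numeric(exp1), row.names = NULL)
  )
}

#' Forward-Wald stepwise logistic model selection
#'
#' Iteratively builds a logistic model: at each step the candidate term
#' with the smallest score-test (Rao) p-value below `entry_p` enters;
#' after every entry, candidate terms already in the model whose Wald
#' p-value exceeds `removal_p` are removed (worst first).  Forced
#' (`include`) terms are never removed.  Stops when no entry or removal
#' changes the model, with a full trace of the steps.
#'
#' @param data Data.frame.
#' @param outcome Name of the binary outcome column.
#' @param candidates Character vector of candidate term names
#'   (single-column numeric or two-level terms).
#' @param include Terms always kept in the model (default none).
#' @param entry_p Score-test entry threshold (default 0.05).
#' @param removal_p Wald removal threshold (default 0.10).
#' @param max_steps Safety cap on selection iterations.
#' @return List with `model` (a `logistic_model`), `selected` (character
#'   vector in entry order) and `trace` (data.frame step/action/term/p).
#' @export
stepwise_forward_wald <- function(data, outcome, candidates,
                                  include = character(0),
                                  entry_p = 0.05, removal_p = 0.10,
                                  max_steps = 50L) {
  stopifnot(all(c(outcome, candidates, include) %in% names(data)))
  selected <- character(0)
  trace <- list()
  step <- 0L
  fit_terms <- function(terms) {
    rhs <- if (length(terms)) terms else "1"
    stats::glm(stats::reformulate(rhs, response = outcome),
               family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  }
  fit <- fit_terms(include)
  repeat {
    step <- step + 1L
    if (step > max_steps) break
    changed <- FALSE
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      sc <- stats::add1(fit,
                        scope = stats::reformulate(c(include, selected,
                                                     remaining)),
                        test = "Rao")
      pv <- sc[remaining, "Pr(>Chi)"]
      names(pv) <- remaining
      pv <- pv[!is.na(pv)]
      if (length(pv) && min(pv) < entry_p) {
        term <- names(pv)[which.min(pv)]
        selected <- c(selected, term)
        fit <- fit_terms(c(include, selected))
        trace[[length(trace) + 1L]] <-
          data.frame(step = step, action = "add", term = term,
                     p = unname(min(pv)))
        changed <- TRUE
      }
    }
    # backward sweep on entered candidates
    repeat {
      if (!length(selected)) break
      sm <- summary(fit)$coefficients
      idx <- match(selected, rownames(sm))
      wp <- sm[idx, 4]
      names(wp) <- selected
      wp <- wp[!is.na(wp)]
      if (!length(wp) || max(wp) <= removal_p) break
      term <- names(wp)[which.max(wp)]
      selected <- setdiff(selected, term)
      fit <- fit_terms(c(include, selected))
      trace[[length(trace) + 1L]] <-
        data.frame(step = step, action = "remove", term = term,
                   p = unname(max(wp)))
      changed <- TRUE
    }
    if (!changed) break
  }
  model <- logistic_fit(stats::reformulate(
    if (length(c(include, selected))) c(include, selected) else "1",
    response = outcome), data)
  list(model = model, selected = selected,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(0), action = character(0),
                    term = character(0), p = numeric(0)))
}

#' Bootstrap adjustment of logistic model p-values
#'
#' Refits the model on `B` resamples of subjects drawn with
#' replacement.  Per term it reports the percentile bootstrap 95%
#' confidence interval and an adjusted two-sided p-value from the
#' position of zero in the bootstrap coefficient distribution,
#' `2 * min(Pr(beta* <= 0), Pr(beta* >= 0))` with add-one smoothing.
#' Aborts if more than 10% of replicates fail to converge.  Fully
#' reproducible for a given seed.
#'
#' @param formula Model formula (binary outcome).
#' @param data Data.frame.
#' @param B Number of bootstrap resamples (>= 100, default 1000).
#' @param seed Integer seed.
#' @return Data.frame term/beta/p_raw/p_boot/ci_low/ci_high with
#'   attributes `B`, `seed`, `n_nonconverged`.
#' @export
bootstrap_adjust <- function(formula, data, B = 1000L, seed = 1L) {
  stopifnot(B >= 100L)
  set.seed(seed)
  base <- logistic_fit(formula, data)
  terms <- base$coefficients$term
  boot <- matrix(NA_real_, nrow = B, ncol = length(terms),
                 dimnames = list(NULL, terms))
  bad <- 0L
  n <- nrow(data)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(
      stats::glm(formula, family = stats::binomial(), data = data[idx, ],
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      error = function(e) NULL)
    if (is.null(fb) || !fb$converged || any(is.na(stats::coef(fb)))) {
      bad <- bad + 1L
      next
    }
    cb <- stats::coef(fb)
    boot[b, names(cb)] <- cb
  }
  if (bad > 0.10 * B) {
    stop(sprintf("bootstrap aborted: %d of %d replicates failed to converge",
                 bad, B))
  }
  ok <- colSums(!is.na(boot))
  p_boot <- vapply(terms, function(t) {
    bb <- boot[, t]; bb <- bb[!is.na(bb)]
    m <- length(bb)
    pl <- (1 + sum(bb <= 0)) / (m + 1)
    pr <- (1 + sum(bb >= 0)) / (m + 1)
    min(1, 2 * min(pl, pr))
  }, numeric(1))
  ci <- t(apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE))
  out <- data.frame(
    term = terms, beta = base$coefficients$beta,
    p_raw = base$coefficients$p.value, p_boot = unname(p_boot),
    ci_low = ci[, 1], ci_high = ci[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "n_nonconverged") <- bad
  out
}

#' Wald test for a SNP-by-covariate interaction
#'
#' Fits a logistic model with both main effects, the product term and
#' any additional adjustment covariates, and reports the Wald test and
#' odds ratio for the product coefficient.  An aliased design (e.g. a
#' binary term interacted with itself) is an error.
#'
#' @param data Data.frame.
#' @param outcome Binary outcome column name.
#' @param term1,term2 Names of the two interacting columns.
#' @param covariates Additional adjustment columns (default none).
#' @return List of class `assoc_result` with `term`, `beta`, `se`,
#'   `statistic` (Wald chi-square), `p.value`, `or`, `ci_low`,
#'   `ci_high`, and the fitted `model`.
#' @export
interaction_test <- function(data, outcome, term1, term2,
                             covariates = character(0)) {
  stopifnot(all(c(outcome, term1, term2, covariates) %in% names(data)))
  rhs <- c(term1, term2, paste0(term1, ":", term2), covariates)
  fit <- stats::glm(stats::reformulate(rhs, response = outcome),
                    family = stats::binomial(), data = data,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (any(is.na(stats::coef(fit)))) {
    stop("interaction design is rank-deficient (aliased term)")
  }
  model <- logistic_fit(stats::reformulate(rhs, response = outcome), data)
  cf <- model$coefficients
  prod_name <- paste0(term1, ":", term2)
  row <- cf[grepl(prod_name, cf$term, fixed = TRUE), , drop = FALSE]
  if (nrow(row) != 1L) stop("could not locate the product term")
  structure(
    list(model = "interaction", term = row$term, beta = row$beta,
         se = row$se, statistic = row$wald_chi2, df = 1L,
         p.value = row$p.value, or = row$or, ci_low = row$ci_low,
         ci_high = row$ci_high, fit = model),
    class = "assoc_result"
  )
}
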
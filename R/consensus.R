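#' @name consensus
#' @title Consensus deleteriousness scoring across five predictors
#' @description
#' Missense variants are scored by aggregating the categorical verdicts
#' of five in-silico deleteriousness predictors (SIFT, PolyPhen-2,
#' PROVEAN, SNPs&GO, MutationTaster roles).  Each verdict contributes 0
#' (neutral / benign / polymorphism), 1 (possibly damaging, a PolyPhen-2
#' category) or 2 (damaging / disease causing / probably damaging) to a
#' collective score on 0--10, and a variant is called damaging when at
#' least three of the five tools report a full damaging verdict.
NULL

.prediction_tools <- c("sift", "polyphen2", "provean", "snp_go",
                       "mutation_taster")

.verdict_levels <- c("neutral", "possibly_damaging", "damaging")

.verdict_scores <- c(neutral = 0L, possibly_damaging = 1L, damaging = 2L)

#' Build a five-tool prediction set
#'
#' @param sift,polyphen2,provean,snp_go,mutation_taster One verdict per
#'   tool, each `"neutral"`, `"possibly_damaging"` or `"damaging"`.
#'   The intermediate `possibly_damaging` category belongs to the
#'   PolyPhen-2 vocabulary only and is rejected for the other tools.
#' @return An object of class `prediction_set` (named character vector).
#' @examples
#' prediction_set("damaging", "possibly_damaging", "damaging",
#'                "neutral", "damaging")
#' @export
prediction_set <- function(sift, polyphen2, provean, snp_go,
                           mutation_taster) {
  v <- c(sift = sift, polyphen2 = polyphen2, provean = provean,
         snp_go = snp_go, mutation_taster = mutation_taster)
  if (any(is.na(v))) stop("missing verdict; no imputation is performed")
  bad <- setdiff(v, .verdict_levels)
  if (length(bad)) {
    stop("unknown verdict(s): ", paste(bad, collapse = ", "),
         "; use normalize_verdict() for tool-native labels")
  }
  off <- setdiff(names(v)[v == "possibly_damaging"], "polyphen2")
  if (length(off)) {
    stop("possibly_damaging is a PolyPhen-2 category; found for: ",
         paste(off, collapse = ", "))
  }
  structure(v, class = "prediction_set")
}

#' Default tool-vocabulary normalization table
#'
#' Maps the native labels of the five predictors (case-insensitive) to
#' the canonical verdicts.  Extend or override entries to accommodate
#' other tool versions.
#'
#' @return Named character vector: native label -> canonical verdict.
#' @export
default_verdict_map <- function() {
  c(
    "tolerated"                 = "neutral",
    "benign"                    = "neutral",
    "polymorphism"              = "neutral",
    "polymorphism automatic"    = "neutral",
    "neutral"                   = "neutral",
    "possibly damaging"         = "possibly_damaging",
    "possibly_damaging"         = "possibly_damaging",
    "probably damaging"         = "damaging",
    "probably_damaging"         = "damaging",
    "deleterious"               = "damaging",
    "damaging"                  = "damaging",
    "disease"                   = "damaging",
    "disease causing"           = "damaging",
    "disease_causing"           = "damaging",
    "disease causing automatic" = "damaging"
  )
}

#' Normalize tool-native verdict labels
#'
#' @param labels Character vector of tool-native labels.
#' @param map Normalization table, see [default_verdict_map()].
#' @return Character vector of canonical verdicts.
#' @export
normalize_verdict <- function(labels, map = default_verdict_map()) {
  key <- tolower(trimws(labels))
  out <- unname(map[key])
  if (any(is.na(out) & !is.na(labels))) {
    stop("unmapped verdict label(s): ",
         paste(unique(labels[is.na(out)]), collapse = ", "))
  }
  out
}

#' Collective deleteriousness score (0--10)
#'
#' Sum over the five tools of 0 for neutral, 1 for possibly damaging
#' and 2 for damaging.
#'
#' @param preds A [prediction_set()].
#' @return Integer in 0..10.
#' @export
collective_score <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  sum(.verdict_scores[unclass(preds)])
}

#' Consensus damaging call (>= 3 of 5 tools)
#'
#' A variant is damaging when at least three of the five tools give a
#' full damaging verdict; the intermediate possibly-damaging category
#' does not count towards the consensus.
#'
#' @param preds A [prediction_set()].
#' @return Logical flag.
#' @export
is_damaging <- function(preds) {
  stopifnot(inherits(preds, "prediction_set"))
  sum(unclass(preds) == "damaging") >= 3L
}

#' Aggregate a table of per-variant predictions
#'
#' @param df Data.frame with a variant identifier column plus one column
#'   per tool (`r paste(.prediction_tools, collapse = ", ")`), holding
#'   canonical or tool-native labels.
#' @param id_col Name of the identifier column (default first column).
#' @param normalize Normalize tool-native labels first (default TRUE).
#' @return The identifier column plus `collective_score` and `damaging`.
#' @export
aggregate_predictions <- function(df, id_col = names(df)[1],
                                  normalize = TRUE) {
  stopifnot(all(.prediction_tools %in% names(df)))
  rows <- lapply(seq_len(nrow(df)), function(i) {
    v <- vapply(.prediction_tools, function(t) as.character(df[[t]][i]),
                character(1))
    if (normalize) v <- normalize_verdict(v)
    ps <- prediction_set(v[1], v[2], v[3], v[4], v[5])
    data.frame(collective_score = collective_score(ps),
               damaging = is_damaging(ps))
  })
  cbind(df[, id_col, drop = FALSE], do.call(rbind, rows))
}

#' Read a variant-by-tool verdict TSV
#'
#' @param path TSV path with header: identifier column then the five
#'   tool columns.
#' @param ... Passed to [aggregate_predictions()].
#' @return See [aggregate_predictions()].
#' @export
read_predictions_tsv <- function(path, ...) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  aggregate_predictions(df, ...)
}
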
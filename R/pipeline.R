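#' Run the discovery pipeline end to end
#'
#' Pairing -> encoding -> reversal testing -> LASSO Cox selection ->
#' unpenalized Cox refit -> risk scoring -> survival evaluation, on
#' one discovery cohort. Stages match the standalone functions
#' exactly, so any stage can be re-run from saved intermediates.
#'
#' @param expression Expression tibble (or a `cohort`, in which case
#'   `clinical` is taken from it).
#' @param clinical Clinical tibble.
#' @param regulators Regulator tibble (default [load_regulators()];
#'   for synthetic cohorts pass the generator's regulator symbols).
#' @param r_min,p_max Pair-catalog thresholds (defaults 0.5, 0.01).
#' @param log10_fisher_threshold Reversal selection cutoff on the
#'   two-sided log10 p (default -70).
#' @param group1,group2 Grade labels for the reversal test.
#' @param folds CV folds for the LASSO stage (default 10).
#' @param seed Integer seed (required; drives CV fold assignment).
#' @param horizons Evaluation horizons in months.
#' @param out_dir Optional directory; when given, the signature
#'   (JSON), risk scores (TSV), reversal-test table (TSV), metrics
#'   (JSON) and a run manifest (JSON: config, seed, package version)
#'   are written there.
#' @return List with `catalog`, `indicators`, `reversal`,
#'   `candidates`, `selected`, `signature`, `scores`, `metrics`,
#'   `manifest`.
#' @export
run_discovery <- function(expression, clinical = NULL,
                          regulators = load_regulators(),
                          r_min = 0.5, p_max = 0.01,
                          log10_fisher_threshold = -70,
                          group1 = "LGG", group2 = "GBM",
                          folds = 10, seed, horizons = c(12, 36, 60),
                          out_dir = NULL) {
  if (missing(seed)) stop("seed is required")
  if (inherits(expression, "cohort")) {
    clinical <- expression$clinical
    expression <- expression$expression
  }
  if (is.null(clinical)) stop("clinical table is required")
  clinical <- validate_clinical(clinical)

  catalog <- build_pair_catalog(expression, regulators, r_min, p_max)
  if (nrow(catalog) == 0) stop("stage pairing: empty pair catalog")
  indicators <- encode_pairs(expression, catalog)
  reversal <- reversal_test(indicators, clinical, group1, group2,
                            log10_fisher_threshold)
  candidates <- select_reversed_pairs(reversal, log10_fisher_threshold)
  if (nrow(candidates) < 2)
    stop("stage reversal: fewer than 2 candidate pairs at log10 p < ",
         log10_fisher_threshold)
  cand_ind <- indicators[match(candidates$pair, indicators$pair), , drop = FALSE]
  # pairs with identical indicator vectors are one feature: keep the
  # lowest-p representative so the refit design has full rank
  dup <- duplicated(as.data.frame(ind_values(cand_ind)))
  if (any(dup)) cand_ind <- cand_ind[!dup, , drop = FALSE]
  selected <- lasso_cox_select(cand_ind, clinical, folds = folds, seed = seed)
  if (nrow(selected) == 0) stop("stage lasso: empty selection")
  signature <- cox_refit(selected, indicators, clinical)
  scores <- risk_score(signature, indicators)
  metrics <- evaluate_scores(scores, clinical, horizons)

  manifest <- list(
    config = list(r_min = r_min, p_max = p_max,
                  log10_fisher_threshold = log10_fisher_threshold,
                  group1 = group1, group2 = group2, folds = folds,
                  seed = seed, horizons = horizons),
    n_samples = nrow(clinical), n_pairs_catalog = nrow(catalog),
    n_candidates = nrow(candidates), n_selected = nrow(selected),
    package_version = as.character(utils::packageVersion("pairsig"))
  )
  res <- list(catalog = catalog, indicators = indicators,
              reversal = reversal, candidates = candidates,
              selected = selected, signature = signature,
              scores = scores, metrics = metrics, manifest = manifest)
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_signature(res$signature, file.path(out_dir, "signature.json"))
  readr::write_tsv(res$scores, file.path(out_dir, "scores.tsv"))
  readr::write_tsv(res$reversal, file.path(out_dir, "reversal_test.tsv"))
  jsonlite::write_json(
    list(auc = res$metrics$auc, c_index = res$metrics$c_index,
         logrank_p = res$metrics$logrank$p),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Validate a fixed signature on an external cohort
#'
#' Encodes the signature's pairs on the new cohort, scores with the
#' fixed coefficients (Eq.-style linear combination of +/-1
#' indicators), stratifies by the cohort's median score, and runs the
#' evaluation suite. Any signature gene missing from the cohort is a
#' hard error — the score is undefined without all its terms.
#'
#' @param signature A `pair_signature` (e.g. [published_mrgps()]) or
#'   a path to a signature JSON.
#' @param expression Expression tibble of the validation cohort (or
#'   a `cohort`).
#' @param clinical Clinical tibble.
#' @param horizons Months (default 12, 36, 60).
#' @return List with `scores`, `metrics` (km / logrank / auc /
#'   c_index).
#' @export
run_validate <- function(signature, expression, clinical = NULL,
                         horizons = c(12, 36, 60)) {
  if (is.character(signature)) signature <- read_signature(signature)
  stopifnot(inherits(signature, "pair_signature"))
  if (inherits(expression, "cohort")) {
    clinical <- expression$clinical
    expression <- expression$expression
  }
  clinical <- validate_clinical(clinical)
  genes <- unique(c(signature$entries$regulator, signature$entries$target))
  missing <- setdiff(genes, expression$gene)
  if (length(missing))
    stop("validation cohort lacks signature gene(s): ",
         paste(missing, collapse = ", "))
  indicators <- encode_pairs(expression, signature$entries)
  scores <- risk_score(signature, indicators)
  list(scores = scores,
       metrics = evaluate_scores(scores, clinical, horizons))
}
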
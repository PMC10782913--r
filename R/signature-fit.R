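new_pair_signature <- function(entries, provenance, fit = NULL) {
  stopifnot(all(c("regulator", "target", "coefficient") %in% names(entries)),
            !anyDuplicated(paste(entries$regulator, entries$target)),
            all(is.finite(entries$coefficient)))
  structure(list(entries = tibble::as_tibble(entries),
                 provenance = provenance, fit = fit),
            class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("<pair_signature> %d pairs (%s)\n", nrow(x$entries), x$provenance))
  print(x$entries, ...)
  invisible(x)
}

#' The published five-pair glioma risk signature
#'
#' The MrGPS model: risk score =
#' -0.204 I(EIF3A|AK2) - 0.266 I(EIF3A|EMP3) - 0.439 I(YTHDC1|IGFBP2)
#' - 0.140 I(YTHDC1|TUBA1C) + 0.647 I(IGF2BP3|CYP17A1),
#' where each I is the within-sample +1/-1 ordering indicator.
#' Coefficients are stored to three decimals exactly as published.
#'
#' @return A `pair_signature` with `provenance = "published"`.
#' @export
#' @examples
#' published_mrgps()
published_mrgps <- function() {
  new_pair_signature(
    tibble::tribble(
      ~regulator, ~target,   ~coefficient,
      "EIF3A",    "AK2",     -0.204,
      "EIF3A",    "EMP3",    -0.266,
      "YTHDC1",   "IGFBP2",  -0.439,
      "YTHDC1",   "TUBA1C",  -0.140,
      "IGF2BP3",  "CYP17A1",  0.647
    ),
    provenance = "published"
  )
}

# align indicator matrix (pairs x samples) with clinical; returns list
# with x (samples x pairs), time, event, clinical rows in x's order
align_surv <- function(indicators, clinical) {
  m <- ind_values(indicators)
  samp <- intersect(colnames(m), clinical$sample_id)
  if (length(samp) < 2) stop("fewer than 2 samples shared between indicators and clinical")
  cl <- clinical[match(samp, clinical$sample_id), , drop = FALSE]
  list(x = t(m[, samp, drop = FALSE]), clinical = cl,
       time = cl$time_months, event = cl$event)
}

#' LASSO Cox selection of candidate pairs
#'
#' L1-penalized Cox partial likelihood over a penalty path; lambda is
#' chosen by k-fold cross-validated partial-likelihood deviance
#' (minimum rule). Indicator features are not standardized — they are
#' already symmetric +/-1, and rescaling by column SD would only blur
#' interpretability. Deterministic given `seed` (fold assignment is
#' the only randomness).
#'
#' @param indicators Indicator tibble restricted to candidate pairs.
#' @param clinical Clinical tibble with `time_months`, `event`.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment (required).
#' @return Tibble of pairs with nonzero coefficients at lambda.min:
#'   columns `pair`, `regulator`, `target`, `lasso_coefficient`;
#'   attribute `lambda` holds the chosen penalty.
#' @export
lasso_cox_select <- function(indicators, clinical, folds = 10, seed) {
  if (missing(seed)) stop("seed is required for cross-validation")
  al <- align_surv(indicators, clinical)
  if (sum(al$event) == 0) stop("no events in clinical data")
  if (ncol(al$x) < 2) stop("need >=2 candidate pairs")
  sds <- apply(al$x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant pair column(s): ",
            paste(colnames(al$x)[sds == 0], collapse = ", "))
    al$x <- al$x[, sds > 0, drop = FALSE]
    if (ncol(al$x) < 2) stop("fewer than 2 non-constant candidate pairs")
  }
  y <- survival::Surv(al$time, al$event)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), nrow(al$x)))
  cvfit <- glmnet::cv.glmnet(al$x, y, family = "cox", foldid = foldid,
                             standardize = FALSE)
  co <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  keep <- rownames(co)[co[, 1] != 0]
  sel <- tibble::tibble(pair = keep,
                        lasso_coefficient = co[keep, 1])
  parts <- strsplit(sel$pair, "|", fixed = TRUE)
  sel$regulator <- vapply(parts, `[`, "", 1)
  sel$target <- vapply(parts, `[`, "", 2)
  sel <- sel[, c("pair", "regulator", "target", "lasso_coefficient")]
  attr(sel, "lambda") <- cvfit$lambda.min
  sel
}

#' Unpenalized multivariate Cox refit of selected pairs
#'
#' Fits a plain Cox proportional-hazards model on the selected pair
#' indicators and packages the coefficients as a `pair_signature`
#' with per-pair hazard ratios, Wald confidence intervals and the
#' global likelihood-ratio p-value.
#'
#' @param selected Data frame with columns `regulator`, `target`
#'   (e.g. from [lasso_cox_select()]).
#' @param indicators Indicator tibble containing the selected pairs.
#' @param clinical Clinical tibble.
#' @return A `pair_signature` with `provenance = "fitted"`; the
#'   `survival::coxph` fit is kept in `$fit`.
#' @export
cox_refit <- function(selected, indicators, clinical) {
  stopifnot(nrow(selected) >= 1)
  keys <- paste(selected$regulator, selected$target, sep = "|")
  idx <- match(keys, indicators$pair)
  if (anyNA(idx)) stop("selected pair(s) missing from indicators: ",
                       paste(keys[is.na(idx)], collapse = ", "))
  al <- align_surv(indicators[idx, , drop = FALSE], clinical)
  x <- al$x
  qx <- qr(cbind(x))
  if (qx$rank < ncol(x)) {
    dep <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("perfectly collinear pair columns: ", paste(dep, collapse = ", "))
  }
  df <- data.frame(time = al$time, event = al$event, x, check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  if (any(!is.finite(stats::coef(fit))))
    stop("Cox refit failed to converge (non-finite coefficients)")
  sfit <- summary(fit)
  entries <- tibble::tibble(
    regulator = selected$regulator,
    target = selected$target,
    coefficient = unname(stats::coef(fit)),
    hr = unname(exp(stats::coef(fit))),
    hr_low = unname(sfit$conf.int[, "lower .95"]),
    hr_high = unname(sfit$conf.int[, "upper .95"]),
    wald_p = unname(sfit$coefficients[, "Pr(>|z|)"])
  )
  sig <- new_pair_signature(entries, provenance = "fitted", fit = fit)
  sig$global_p <- unname(sfit$logtest["pvalue"])
  sig
}

#' Risk scores from a pair signature
#'
#' score(sample) = sum_i coefficient_i * I_i(sample); samples are
#' stratified by the median score (higher = higher risk; median ties
#' go to the low-risk group, the reference in survival comparisons).
#' Every signature pair must be present in the indicator matrix —
#' missing pairs are a hard error, never silently dropped, because
#' the score is only defined with all its terms.
#'
#' @param signature A `pair_signature`.
#' @param indicators Indicator tibble from [encode_pairs()].
#' @return Tibble with columns `sample_id`, `score`, `group`
#'   ("high"/"low").
#' @export
risk_score <- function(signature, indicators) {
  stopifnot(inherits(signature, "pair_signature"))
  keys <- paste(signature$entries$regulator, signature$entries$target, sep = "|")
  idx <- match(keys, indicators$pair)
  if (anyNA(idx))
    stop("signature pair(s) absent from indicator matrix: ",
         paste(keys[is.na(idx)], collapse = ", "))
  m <- ind_values(indicators[idx, , drop = FALSE])
  score <- as.vector(crossprod(m, signature$entries$coefficient))
  med <- stats::median(score)
  tibble::tibble(sample_id = colnames(m), score = score,
                 group = ifelse(score > med, "high", "low"))
}

#' Cox model combining pair indicators with clinical covariates
#'
#' Multivariate Cox over the signature's pair indicators plus named
#' clinical covariates (default age and radiotherapy), yielding a
#' combined prognostic index per sample.
#'
#' @param signature A `pair_signature`.
#' @param indicators Indicator tibble.
#' @param clinical Clinical tibble carrying the covariate columns.
#' @param covariates Character vector of clinical column names
#'   (default `c("age", "radiotherapy")`). With `character(0)` the
#'   model reduces to the pairs-only Cox fit.
#' @return List with `fit` (coxph), `terms` (tibble of coefficient,
#'   HR, CI, p per term) and `index` (tibble sample_id, linear
#'   predictor).
#' @export
combine_clinical <- function(signature, indicators, clinical,
                             covariates = c("age", "radiotherapy")) {
  stopifnot(inherits(signature, "pair_signature"))
  keys <- paste(signature$entries$regulator, signature$entries$target, sep = "|")
  idx <- match(keys, indicators$pair)
  if (anyNA(idx)) stop("signature pair(s) absent from indicators")
  al <- align_surv(indicators[idx, , drop = FALSE], clinical)
  x <- as.data.frame(al$x, check.names = FALSE)
  for (cv in covariates) {
    if (!cv %in% names(al$clinical)) stop("covariate not in clinical table: ", cv)
    v <- al$clinical[[cv]]
    if (is.character(v)) v <- as.factor(v)
    if (length(unique(v)) < 2) stop("constant covariate: ", cv)
    x[[cv]] <- v
  }
  mm <- stats::model.matrix(~ ., data = x)[, -1, drop = FALSE]
  if (qr(mm)$rank < ncol(mm))
    stop("collinear columns in combined design (pair indicators vs covariates)")
  df <- data.frame(time = al$time, event = al$event, x, check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", names(x)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df)
  sfit <- summary(fit)
  terms <- tibble::tibble(
    term = gsub("`", "", rownames(sfit$coefficients)),
    coefficient = unname(sfit$coefficients[, "coef"]),
    hr = unname(sfit$conf.int[, "exp(coef)"]),
    hr_low = unname(sfit$conf.int[, "lower .95"]),
    hr_high = unname(sfit$conf.int[, "upper .95"]),
    wald_p = unname(sfit$coefficients[, "Pr(>|z|)"])
  )
  list(fit = fit, terms = terms,
       index = tibble::tibble(sample_id = al$clinical$sample_id,
                              score = unname(fit$linear.predictors)))
}

#' Single-gene LASSO Cox baseline signature
#'
#' The classical alternative to pair encoding: LASSO Cox on
#' standardized continuous gene expressions, penalty tuned by the
#' same cross-validated deviance rule, returning the selected genes
#' and continuous risk scores for head-to-head comparison with the
#' pair model.
#'
#' @param expr Expression tibble.
#' @param clinical Clinical tibble.
#' @param n_target Upper bound on signature size; if lambda.min
#'   selects more genes, the largest lambda on the path with at most
#'   `n_target` nonzero coefficients is used instead (default 20).
#' @param folds CV folds (default 10).
#' @param seed Integer seed (required).
#' @return List with `genes` (tibble gene, coefficient), `scores`
#'   (tibble sample_id, score, group by median split) and `lambda`.
#' @export
baseline_gene_signature <- function(expr, clinical, n_target = 20,
                                    folds = 10, seed) {
  if (missing(seed)) stop("seed is required for cross-validation")
  expr <- validate_expression(expr)
  m <- expr_values(expr)
  samp <- intersect(colnames(m), clinical$sample_id)
  cl <- clinical[match(samp, clinical$sample_id), ]
  if (sum(cl$event) == 0) stop("no events in clinical data")
  x <- t(m[, samp, drop = FALSE])
  x <- x[, apply(x, 2, stats::sd) > 0, drop = FALSE]
  y <- survival::Surv(cl$time_months, cl$event)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), nrow(x)))
  cvfit <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                             standardize = TRUE)
  lam <- cvfit$lambda.min
  nz <- cvfit$nzero[cvfit$lambda == lam]
  if (nz > n_target) {
    ok <- cvfit$lambda[cvfit$nzero <= n_target]
    lam <- min(ok)  # most permissive lambda still within the size budget
  }
  co <- as.matrix(stats::coef(cvfit, s = lam))
  keep <- rownames(co)[co[, 1] != 0]
  genes <- tibble::tibble(gene = keep, coefficient = co[keep, 1])
  score <- as.vector(x[, keep, drop = FALSE] %*% genes$coefficient)
  med <- stats::median(score)
  list(genes = genes,
       scores = tibble::tibble(sample_id = samp, score = score,
                               group = ifelse(score > med, "high", "low")),
       lambda = lam)
}

#' Serialize / deserialize a pair signature as JSON
#'
#' @param signature A `pair_signature`.
#' @param path Output (input) file path.
#' @return `path` invisibly (`read_signature` returns the signature).
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "pair_signature"))
  obj <- list(pairs = purrr::map2(signature$entries$regulator,
                                  signature$entries$target, c),
              coefficients = signature$entries$coefficient,
              provenance = signature$provenance)
  if (!is.null(signature$global_p)) obj$global_p <- signature$global_p
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- tibble::tibble(
    regulator = vapply(obj$pairs, function(p) p[[1]], ""),
    target = vapply(obj$pairs, function(p) p[[2]], ""),
    coefficient = vapply(obj$coefficients, as.numeric, numeric(1))
  )
  sig <- new_pair_signature(entries, provenance = obj$provenance %||% "fitted")
  if (!is.null(obj$global_p)) sig$global_p <- obj$global_p
  sig
}

#' @importFrom rlang %||% .data
NULL

#' Tidy a pair signature into a per-pair tibble
#'
#' @param x A `pair_signature`.
#' @param ... Unused.
#' @return The entries tibble (pair, coefficient, and, for fitted
#'   signatures, hazard ratios with CIs and Wald p-values).
#' @export
tidy.pair_signature <- function(x, ...) {
  dplyr::mutate(x$entries,
                pair = paste(.data$regulator, .data$target, sep = "|"),
                .before = 1)
}

#' One-row summary of a pair signature
#'
#' @param x A `pair_signature`.
#' @param ... Unused.
#' @return Tibble with `n_pairs`, `provenance`, `coef_sum` and, when
#'   available, the global likelihood-ratio p-value.
#' @export
glance.pair_signature <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$entries),
                 provenance = x$provenance,
                 coef_sum = sum(x$entries$coefficient),
                 global_p = if (is.null(x$global_p)) NA_real_ else x$global_p)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
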
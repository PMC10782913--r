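#' Encode gene pairs as within-sample ordering indicators
#'
#' For each pair (M, G) and sample s the indicator is +1 when
#' E(M) >= E(G) in that sample and -1 otherwise (ties take the ">="
#' branch, i.e. +1). Because only the within-sample ordering of the
#' two genes matters, the encoding is invariant to any strictly
#' increasing per-sample transform of the expression values — the
#' property that lets cohorts be combined without normalization.
#'
#' @param expr Expression tibble.
#' @param catalog A `pair_catalog`, or any data frame with columns
#'   `regulator` and `target`.
#' @return Tibble with columns `regulator`, `target`, `pair`
#'   (`"REG|TARGET"`) and one integer (+1/-1) column per sample.
#' @export
encode_pairs <- function(expr, catalog) {
  expr <- validate_expression(expr)
  stopifnot(all(c("regulator", "target") %in% names(catalog)))
  m <- expr_values(expr)
  missing <- setdiff(unique(c(catalog$regulator, catalog$target)), rownames(m))
  if (length(missing)) {
    hit <- catalog$regulator %in% missing | catalog$target %in% missing
    stop(sprintf("gene(s) %s absent from expression matrix (first pair affected: %s|%s)",
                 paste(missing, collapse = ", "),
                 catalog$regulator[hit][1], catalog$target[hit][1]))
  }
  ind <- ifelse(m[catalog$regulator, , drop = FALSE] >=
                  m[catalog$target, , drop = FALSE], 1L, -1L)
  out <- tibble::as_tibble(as.data.frame(ind, check.names = FALSE))
  dplyr::bind_cols(
    tibble::tibble(regulator = catalog$regulator, target = catalog$target,
                   pair = paste(catalog$regulator, catalog$target, sep = "|")),
    out
  )
}

ind_values <- function(indicators) {
  m <- as.matrix(indicators[, !(names(indicators) %in%
                                  c("regulator", "target", "pair")), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- indicators$pair
  m
}

#' Per-pair 2x2 contingency counts between two diagnosis groups
#'
#' Counts a = group-1 samples with indicator +1, b = group-1 with -1,
#' c = group-2 with +1, d = group-2 with -1, so a+b is the group-1
#' size and c+d the group-2 size.
#'
#' @param indicators Indicator tibble from [encode_pairs()].
#' @param clinical Clinical tibble; its `grade` column labels samples.
#' @param group1,group2 Grade labels (default LGG, GBM).
#' @return Tibble with columns `pair`, `regulator`, `target`, `a`,
#'   `b`, `c`, `d`.
#' @export
contingency_counts <- function(indicators, clinical,
                               group1 = "LGG", group2 = "GBM") {
  m <- ind_values(indicators)
  lab <- stats::setNames(clinical$grade, clinical$sample_id)
  samp <- colnames(m)
  unknown <- samp[!lab[samp] %in% c(group1, group2) | is.na(lab[samp])]
  if (length(unknown))
    stop("samples with neither group label: ", paste(utils::head(unknown, 5), collapse = ", "))
  g1 <- samp[lab[samp] == group1]
  g2 <- samp[lab[samp] == group2]
  pos1 <- rowSums(m[, g1, drop = FALSE] == 1L)
  pos2 <- rowSums(m[, g2, drop = FALSE] == 1L)
  tibble::tibble(
    pair = indicators$pair,
    regulator = indicators$regulator,
    target = indicators$target,
    a = as.integer(pos1), b = length(g1) - as.integer(pos1),
    c = as.integer(pos2), d = length(g2) - as.integer(pos2)
  )
}

# log10 factorial via lgamma; never raw factorials
lfact10 <- function(k) lgamma(k + 1) / log(10)

#' Hypergeometric point probability of a 2x2 table, in log10
#'
#' log10 of (a+b)! (c+d)! (a+c)! (b+d)! / (a! b! c! d! n!), the exact
#' probability of one table with fixed margins. Computed via
#' log-gamma so tables far beyond double-precision underflow (p well
#' below 1e-300) remain exact in log space.
#'
#' @param a,b,c,d Non-negative integer counts (vectorized).
#' @return log10 point probability (<= 0).
#' @export
fisher_point_log10 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative count")
  n <- a + b + c + d
  if (any(n == 0)) stop("empty table")
  lfact10(a + b) + lfact10(c + d) + lfact10(a + c) + lfact10(b + d) -
    lfact10(a) - lfact10(b) - lfact10(c) - lfact10(d) - lfact10(n)
}

# stable log10(sum(10^x))
logsumexp10 <- function(x) {
  m <- max(x)
  m + log10(sum(10^(x - m)))
}

#' Two-sided Fisher exact p-value of a 2x2 table, in log10
#'
#' Sums, over all tables with the observed margins, the point
#' probabilities that do not exceed the observed one (the standard
#' two-sided convention), entirely in log space. A relative guard of
#' 1e-7 on log-probabilities absorbs floating-point ties. This keeps
#' selection thresholds such as p < 1e-70 meaningful, which naive
#' probability arithmetic cannot represent reliably.
#'
#' @inheritParams fisher_point_log10
#' @return log10 two-sided p (<= 0; always >= the point log10 p).
#' @export
fisher_two_sided_log10 <- function(a, b, c, d) {
  if (length(a) > 1) {
    return(vapply(seq_along(a),
                  function(i) fisher_two_sided_log10(a[i], b[i], c[i], d[i]),
                  numeric(1)))
  }
  if (any(c(a, b, c, d) < 0)) stop("negative count")
  r1 <- a + b; ac <- a + c; n <- a + b + c + d
  if (n == 0) stop("empty table")
  lo <- max(0, ac - (n - r1)); hi <- min(r1, ac)
  aa <- lo:hi
  lp <- fisher_point_log10(aa, r1 - aa, ac - aa, n - r1 - ac + aa)
  obs <- lp[aa == a]
  keep <- lp <= obs + 1e-7 * abs(obs) + 1e-12
  min(logsumexp10(lp[keep]), 0)
}

#' Test every pair for ordering reversal between two groups
#'
#' Runs the exact Fisher test on each pair's 2x2 table of within-
#' sample orderings (group x indicator sign) and reports both the
#' point probability of the observed table and the two-sided p, in
#' log10 space.
#'
#' @inheritParams contingency_counts
#' @param log10_threshold Selection cutoff on the two-sided log10 p
#'   (default -70).
#' @return Tibble with columns `pair`, `regulator`, `target`, `a`,
#'   `b`, `c`, `d`, `log10_p_point`, `log10_p_two_sided`, `selected`.
#' @export
reversal_test <- function(indicators, clinical, group1 = "LGG", group2 = "GBM",
                          log10_threshold = -70) {
  counts <- contingency_counts(indicators, clinical, group1, group2)
  counts$log10_p_point <- fisher_point_log10(counts$a, counts$b, counts$c, counts$d)
  counts$log10_p_two_sided <- fisher_two_sided_log10(counts$a, counts$b,
                                                     counts$c, counts$d)
  counts$selected <- counts$log10_p_two_sided < log10_threshold
  counts
}

#' Select significantly reversed pairs
#'
#' @param results Tibble from [reversal_test()].
#' @param log10_threshold Cutoff on `log10_p_two_sided` (strict `<`,
#'   default -70, i.e. p < 1e-70).
#' @return The selected rows sorted by ascending p.
#' @export
select_reversed_pairs <- function(results, log10_threshold = -70) {
  out <- dplyr::filter(results, .data$log10_p_two_sided < log10_threshold)
  dplyr::arrange(out, .data$log10_p_two_sided)
}

#' Per-group proportion of regulator-above-target samples
#'
#' For each pair and each group label, the fraction of samples whose
#' indicator is +1 (regulator expressed at or above its target). In
#' glioma this proportion decreases from normal brain through LGG to
#' GBM for reversal-selected pairs.
#'
#' @param indicators Indicator tibble from [encode_pairs()].
#' @param clinical Clinical tibble with `grade` labels.
#' @param groups Ordered character vector of group labels, e.g.
#'   `c("normal", "LGG", "GBM")`.
#' @return Tibble with columns `pair`, `group` (factor, given order)
#'   and `proportion`.
#' @export
reversal_proportion <- function(indicators, clinical,
                                groups = c("normal", "LGG", "GBM")) {
  m <- ind_values(indicators)
  lab <- stats::setNames(clinical$grade, clinical$sample_id)
  purrr::map_dfr(groups, function(g) {
    samp <- intersect(colnames(m), names(lab)[lab == g])
    if (length(samp) == 0) stop("empty group: ", g)
    tibble::tibble(pair = rownames(m), group = g,
                   proportion = unname(rowMeans(m[, samp, drop = FALSE] == 1L)))
  }) |>
    dplyr::mutate(group = factor(.data$group, levels = groups))
}
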
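# m6A regulators named in the primary literature: 8 writers, 2 erasers,
# 15 readers (25 total). Users can append further regulators via a TSV.
.default_regulators <- function() {
  tibble::tribble(
    ~symbol,   ~class,
    "METTL3",  "writer",
    "METTL5",  "writer",
    "METTL14", "writer",
    "METTL16", "writer",
    "VIRMA",   "writer",
    "WTAP",    "writer",
    "ZC3H13",  "writer",
    "ZCCHC4",  "writer",
    "ALKBH5",  "eraser",
    "FTO",     "eraser",
    "YTHDF1",  "reader",
    "YTHDF2",  "reader",
    "YTHDF3",  "reader",
    "YTHDC1",  "reader",
    "YTHDC2",  "reader",
    "HNRNPC",  "reader",
    "IGF2BP1", "reader",
    "IGF2BP2", "reader",
    "IGF2BP3", "reader",
    "ELAVL1",  "reader",
    "G3BP1",   "reader",
    "RBMX",    "reader",
    "FMR1",    "reader",
    "EIF3A",   "reader",
    "PRRC2A",  "reader"
  )
}

#' The m6A regulator set
#'
#' Returns the packaged default list of 25 m6A writers, erasers and
#' readers, optionally extended with user-supplied entries.
#'
#' @param extra_path Optional TSV with columns `symbol`, `class`
#'   (writer/eraser/reader) appended to the default list. Duplicated
#'   symbols are dropped (first occurrence wins).
#' @return Tibble with columns `symbol` (unique, upper case) and
#'   `class`.
#' @export
#' @examples
#' nrow(load_regulators())  # 25
load_regulators <- function(extra_path = NULL) {
  regs <- .default_regulators()
  if (!is.null(extra_path)) {
    extra <- utils::read.delim(extra_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    if (!all(c("symbol", "class") %in% names(extra)))
      stop("extra regulator file needs columns symbol, class")
    bad <- setdiff(unique(extra$class), c("writer", "eraser", "reader"))
    if (length(bad))
      stop("unknown regulator class: ", paste(bad, collapse = ", "))
    regs <- dplyr::bind_rows(regs, tibble::as_tibble(extra))
  }
  regs$symbol <- toupper(regs$symbol)
  dplyr::distinct(regs, .data$symbol, .keep_all = TRUE)
}

#' Pearson correlation with t-based p-value
#'
#' r is the plain product-moment coefficient; the two-sided p-value
#' comes from t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom,
#' exact under bivariate normality.
#'
#' @param x,y Numeric vectors of equal length n >= 3, non-constant.
#' @return A list with elements `r` and `p`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Build the regulator-target pair catalog
#'
#' Every regulator present in the matrix is tested against every
#' non-regulator gene; a pair enters the catalog when |r| > `r_min`
#' and p < `p_max` (strict inequalities). A gene is an m6A target if
#' it pairs with at least one regulator.
#'
#' @param expr Expression tibble.
#' @param regulators Regulator tibble from [load_regulators()].
#' @param r_min Minimum absolute Pearson correlation (default 0.5).
#' @param p_max Maximum p-value (default 0.01).
#' @return A `pair_catalog`: tibble with columns `regulator`,
#'   `target`, `r`, `p`, plus attributes `thresholds` and `targets`
#'   (the unique target-gene set).
#' @export
build_pair_catalog <- function(expr, regulators = load_regulators(),
                               r_min = 0.5, p_max = 0.01) {
  expr <- validate_expression(expr)
  m <- expr_values(expr)
  reg_syms <- intersect(regulators$symbol, rownames(m))
  if (length(reg_syms) == 0) stop("no regulator present in expression matrix")
  tgt_syms <- setdiff(rownames(m), regulators$symbol)
  if (length(tgt_syms) == 0) stop("no non-regulator gene in expression matrix")

  n <- ncol(m)
  reg_m <- m[reg_syms, , drop = FALSE]
  tgt_m <- m[tgt_syms, , drop = FALSE]
  # vectorized correlation of every regulator against every target
  r_mat <- stats::cor(t(reg_m), t(tgt_m))
  r_clip <- pmin(pmax(r_mat, -1 + 1e-15), 1 - 1e-15)
  t_stat <- r_clip * sqrt((n - 2) / (1 - r_clip^2))
  p_mat <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)

  cat_tbl <- tibble::tibble(
    regulator = rep(reg_syms, times = length(tgt_syms)),
    target = rep(tgt_syms, each = length(reg_syms)),
    r = as.vector(r_mat),
    p = as.vector(p_mat)
  )
  cat_tbl <- dplyr::filter(cat_tbl, is.finite(.data$r),
                           abs(.data$r) > r_min, .data$p < p_max)
  cat_tbl <- dplyr::arrange(cat_tbl, .data$p, dplyr::desc(abs(.data$r)),
                            .data$regulator, .data$target)
  structure(cat_tbl,
            class = c("pair_catalog", class(cat_tbl)),
            thresholds = c(r_min = r_min, p_max = p_max),
            targets = sort(unique(cat_tbl$target)))
}

#' Hypergeometric enrichment of a verified pair set
#'
#' Upper-tail probability of observing at least the realized overlap
#' between a pair catalog and an externally verified pair set (e.g.
#' CLIP-supported pairs), drawing |catalog| pairs from the universe.
#' Returned in log10 space so extreme enrichment does not underflow.
#'
#' @param catalog_pairs,verified_pairs,universe_pairs Character
#'   vectors of pair keys (e.g. "REG|TARGET"); catalog and verified
#'   must be subsets of the universe.
#' @return log10 of P(overlap >= observed).
#' @export
hypergeometric_overlap <- function(catalog_pairs, verified_pairs, universe_pairs) {
  universe_pairs <- unique(universe_pairs)
  catalog_pairs <- unique(catalog_pairs)
  verified_pairs <- unique(verified_pairs)
  if (length(universe_pairs) == 0) stop("empty universe")
  if (length(setdiff(catalog_pairs, universe_pairs)) ||
      length(setdiff(verified_pairs, universe_pairs)))
    stop("catalog and verified sets must be subsets of the universe")
  N <- length(universe_pairs)
  K <- length(verified_pairs)
  k <- length(catalog_pairs)
  q <- length(intersect(catalog_pairs, verified_pairs))
  if (q == 0) return(0)  # P(X >= 0) = 1
  stats::phyper(q - 1, K, N - K, k, lower.tail = FALSE, log.p = TRUE) / log(10)
}
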
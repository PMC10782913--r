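#' Read a gene expression matrix from TSV
#'
#' Expression values must be on a within-sample comparable scale (one
#' monotone transform applied to every gene of a sample, e.g. log2(x+1)
#' of TPM). The pair encoding downstream is invariant to per-sample
#' monotone transforms, so no cross-cohort normalization is performed
#' or needed.
#'
#' @param path Path to a UTF-8 tab-separated file. First column holds
#'   gene symbols (header `gene`), remaining column headers are sample
#'   identifiers.
#' @param transpose_hint If `TRUE`, the file is samples x genes and is
#'   transposed after reading.
#' @return A tibble with column `gene` (unique, upper-cased symbols)
#'   and one numeric column per sample. Duplicate gene rows are
#'   collapsed by arithmetic mean.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tS1\tS2", "TP53\t1.5\t2.5", "EGFR\t3\t4"), tf)
#' read_expression(tf)
read_expression <- function(path, transpose_hint = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file needs a gene column and >=1 sample column")
  if (transpose_hint) {
    ids <- as.character(raw[[1]])
    mat <- t(as.matrix(raw[, -1, drop = FALSE]))
    raw <- data.frame(gene = colnames(raw)[-1], mat,
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(raw) <- c("gene", ids)
  }
  names(raw)[1] <- "gene"
  genes <- toupper(as.character(raw[[1]]))
  samples <- names(raw)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))

  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d (gene %s), column '%s': '%s'",
                     bad[1], genes[bad[1]], samples[j], v[bad[1]]))
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  if (anyNA(m) || any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/non-finite value at gene %s, sample '%s'",
                 genes[idx[1]], samples[idx[2]]))
  }
  if (anyDuplicated(genes)) {
    m <- rowsum(m, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(gene = genes), out)
  validate_expression(out)
}

#' Write an expression tibble to TSV
#'
#' Round-trips bit-exactly with [read_expression()] for finite values
#' (full precision, 17 significant digits).
#'
#' @param expr Expression tibble as returned by [read_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- validate_expression(expr)
  df <- as.data.frame(expr, check.names = FALSE)
  for (j in 2:ncol(df)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

validate_expression <- function(expr) {
  stopifnot(is.data.frame(expr), "gene" %in% names(expr)[1])
  if (nrow(expr) < 2 || ncol(expr) < 3)
    stop("expression matrix must have >=2 genes and >=2 samples")
  if (anyDuplicated(expr$gene))
    stop("duplicate gene ids after collapse")
  m <- expr_values(expr)
  if (any(!is.finite(m))) stop("non-finite expression values")
  tibble::as_tibble(expr)
}

# numeric matrix view, genes x samples, rownames = gene
expr_values <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene
  m
}

expr_samples <- function(expr) names(expr)[-1]

#' Read a clinical table from TSV
#'
#' @param path TSV with required columns `sample_id`, `time_months`
#'   (or `time_days` with `days_to_months = TRUE`), `event` (0 =
#'   censored, 1 = death) and `grade` (LGG/GBM, or normal for
#'   reference tissue). Optional columns (`age`, `gender`,
#'   `radiotherapy`, ...) are preserved as covariates.
#' @param days_to_months If `TRUE`, survival times are read from a
#'   `time_days` column and divided by 30.44.
#' @return A validated tibble, one row per sample.
#' @export
read_clinical <- function(path, days_to_months = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (days_to_months) {
    if (!"time_days" %in% names(df)) stop("days_to_months=TRUE requires column 'time_days'")
    df$time_months <- as.numeric(df$time_days) / 30.44
    df$time_days <- NULL
  }
  validate_clinical(tibble::as_tibble(df))
}

validate_clinical <- function(clinical) {
  req <- c("sample_id", "time_months", "event", "grade")
  miss <- setdiff(req, names(clinical))
  if (length(miss)) stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  clinical$sample_id <- as.character(clinical$sample_id)
  clinical$time_months <- as.numeric(clinical$time_months)
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample ids in clinical table")
  bad_t <- which(!is.finite(clinical$time_months) | clinical$time_months <= 0)
  bad_e <- which(!clinical$event %in% c(0, 1))
  if (length(bad_t) || length(bad_e))
    stop("invalid clinical rows (time must be > 0, event in {0,1}): rows ",
         paste(sort(unique(c(bad_t, bad_e))), collapse = ", "))
  tibble::as_tibble(clinical)
}

#' Bundle an expression matrix with its clinical table
#'
#' @param expression Expression tibble ([read_expression()] layout).
#' @param clinical Clinical tibble ([read_clinical()] layout).
#' @param name Cohort label.
#' @return A `cohort` object (list with `expression`, `clinical`,
#'   `name`); clinical rows are restricted to samples present in the
#'   expression matrix, and every clinical sample must be found there.
#' @export
cohort <- function(expression, clinical, name = "cohort") {
  expression <- validate_expression(expression)
  clinical <- validate_clinical(clinical)
  missing <- setdiff(clinical$sample_id, expr_samples(expression))
  if (length(missing))
    stop("clinical samples absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  structure(list(expression = expression, clinical = clinical, name = name),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s'> %d genes x %d samples, %d clinical records (%d events)\n",
              x$name, nrow(x$expression), ncol(x$expression) - 1L,
              nrow(x$clinical), sum(x$clinical$event)))
  invisible(x)
}

#' Restrict cohorts to their common gene set
#'
#' Mirrors the cross-platform step of keeping genes commonly detected
#' across cohorts: every returned expression matrix contains exactly
#' the gene intersection, in a shared order. Samples are untouched.
#' Idempotent.
#'
#' @param cohorts A list of `cohort` objects (a single `cohort` is
#'   also accepted and returned unchanged in a length-1 list).
#' @return List of harmonized `cohort` objects.
#' @export
harmonize <- function(cohorts) {
  if (inherits(cohorts, "cohort")) cohorts <- list(cohorts)
  stopifnot(length(cohorts) >= 1)
  common <- Reduce(intersect, lapply(cohorts, function(co) co$expression$gene))
  if (length(common) == 0) stop("empty gene intersection across cohorts")
  lapply(cohorts, function(co) {
    co$expression <- co$expression[match(common, co$expression$gene), , drop = FALSE]
    co
  })
}
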
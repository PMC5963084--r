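# Composite normal reference and robust Z-scoring of tumor expression.

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expected layout: first column `gene`, remaining columns one per sample.
#' Values are normalized expression on a positive, unitless scale (e.g.
#' RSEM-style); blanks become `NA`. Duplicate gene symbols or sample IDs are
#' an error.
#'
#' @param path path to the TSV file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "gene")
    stop("expression TSV must have a leading 'gene' column", call. = FALSE)
  if (anyDuplicated(df$gene))
    stop("duplicate gene symbols in ", path, call. = FALSE)
  if (anyDuplicated(names(df)[-1]))
    stop("duplicate sample IDs in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  m
}

#' Write an expression matrix as TSV
#' @param m numeric matrix with gene rownames.
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the composite normal-tissue reference
#'
#' Normal samples from all cancer types are pooled into a single composite
#' reference: for each gene the location is the median over normal samples
#' and the scale is the median absolute difference of those samples from the
#' median. Pooling across tissues deliberately widens the per-gene reference
#' range, giving a conservative definition of aberrant expression that is
#' applicable to every cancer type.
#'
#' The scale is the raw median absolute deviation, with no normal-consistency
#' factor; `scale_factor` (default 1) rescales it for anyone wanting the
#' 1.4826-adjusted convention. Genes with zero scale or fewer than
#' `min_samples` non-missing normals are flagged uncallable rather than
#' producing infinite Z-scores.
#'
#' @param normals numeric matrix of normal-tissue expression (genes x samples).
#' @param min_samples minimum non-missing normal samples per gene (default 3).
#' @param scale_factor multiplier applied to the per-gene scale (default 1).
#' @return A `normal_reference`: data frame with columns `gene`, `m`
#'   (location), `s` (scale), `n_used`, `callable`, and attribute
#'   `n_normals`.
#' @export
build_reference <- function(normals, min_samples = 3L, scale_factor = 1) {
  stopifnot(is.matrix(normals), scale_factor > 0)
  if (ncol(normals) == 0L) stop("no normal samples", call. = FALSE)
  if (nrow(normals) == 0L) stop("no genes in normal matrix", call. = FALSE)
  m <- apply(normals, 1L, stats::median, na.rm = TRUE)
  s <- vapply(seq_len(nrow(normals)), function(i) {
    v <- normals[i, ]
    stats::median(abs(v - m[i]), na.rm = TRUE)
  }, numeric(1)) * scale_factor
  n_used <- rowSums(!is.na(normals))
  ref <- data.frame(
    gene = rownames(normals), m = unname(m), s = unname(s),
    n_used = unname(n_used),
    callable = unname(is.finite(s) & s > 0 & n_used >= min_samples),
    stringsAsFactors = FALSE)
  rownames(ref) <- NULL
  attr(ref, "n_normals") <- ncol(normals)
  class(ref) <- c("normal_reference", "data.frame")
  ref
}

#' Robust Z-scores of tumor expression against a normal reference
#'
#' `Z[g, t] = (x[g, t] - m[g]) / s[g]` for callable genes. Uncallable genes
#' (zero scale or too few normals) yield missing Z-scores, never infinities;
#' tumor genes absent from the reference are dropped with a warning.
#'
#' @param tumors numeric matrix of tumor expression (genes x samples).
#' @param ref a `normal_reference` from [build_reference()].
#' @return Numeric matrix of Z-scores (genes x samples) with `NA` where
#'   uncallable or missing.
#' @export
zscore <- function(tumors, ref) {
  stopifnot(is.matrix(tumors), inherits(ref, "normal_reference"))
  common <- intersect(rownames(tumors), ref$gene)
  if (length(common) == 0L)
    stop("no genes shared between tumors and reference", call. = FALSE)
  dropped <- setdiff(rownames(tumors), common)
  if (length(dropped))
    warning(sprintf("%d tumor gene(s) absent from reference dropped (e.g. %s)",
                    length(dropped), dropped[1]), call. = FALSE)
  idx <- match(common, ref$gene)
  x <- tumors[common, , drop = FALSE]
  z <- (x - ref$m[idx]) / ref$s[idx]
  z[!ref$callable[idx], ] <- NA_real_
  z
}

#' Call expression level from a Z-score
#'
#' Thresholds are inclusive: `z >= thr_high` is `"high"`, `z <= thr_low` is
#' `"low"`, otherwise `"normal"`. A missing Z (uncallable gene or missing
#' input) is called `"normal"`; use [expression_calls()] to keep the
#' uncallable flag alongside.
#'
#' @param z numeric vector of Z-scores.
#' @param thr_high high threshold, must be positive (default 2).
#' @param thr_low low threshold, must be negative (default -2).
#' @return Character vector in `c("low", "normal", "high")`.
#' @export
call_level <- function(z, thr_high = 2, thr_low = -2) {
  stopifnot(thr_high > 0, thr_low < 0)
  out <- rep("normal", length(z))
  out[!is.na(z) & z >= thr_high] <- "high"
  out[!is.na(z) & z <= thr_low] <- "low"
  out
}

#' Long-format expression calls for a Z-score matrix
#'
#' @param z Z-score matrix from [zscore()].
#' @inheritParams call_level
#' @return Data frame with columns `sample`, `gene`, `z`, `level`,
#'   `callable`.
#' @export
expression_calls <- function(z, thr_high = 2, thr_low = -2) {
  stopifnot(is.matrix(z))
  out <- data.frame(
    sample = rep(colnames(z), each = nrow(z)),
    gene = rep(rownames(z), times = ncol(z)),
    z = as.vector(z),
    stringsAsFactors = FALSE)
  out$level <- call_level(out$z, thr_high, thr_low)
  out$callable <- !is.na(out$z)
  out
}

#' @export
print.normal_reference <- function(x, ...) {
  cat(sprintf("Composite normal reference: %d genes from %d normal samples (%d callable)\n",
              nrow(x), attr(x, "n_normals"), sum(x$callable)))
  invisible(x)
}
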
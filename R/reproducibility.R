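#' Common subset of expressed genes between two libraries
#'
#' Genes present in both expression tables with RPKM at or above the
#' threshold in both (the boundary is inclusive: a gene at exactly the
#' threshold is kept). Restricting replicate correlations to moderately to
#' highly expressed genes (RPKM >= 10) avoids the count noise that
#' dominates lowly expressed genes.
#'
#' @param a,b gene expression tables from [gene_expression_table()].
#' @param threshold RPKM cutoff (default 10).
#' @return character vector of gene ids.
#' @export
common_expressed_subset <- function(a, b, threshold = 10) {
  common <- intersect(a$gene_id, b$gene_id)
  ra <- a$rpkm[match(common, a$gene_id)]
  rb <- b$rpkm[match(common, b$gene_id)]
  common[ra >= threshold & rb >= threshold]
}

#' Pearson and Spearman correlation
#'
#' Thin named wrappers over [stats::cor()]: `pearson_cor` is the sample
#' product-moment coefficient; `spearman_cor` is Pearson on mid-ranks
#' (ties receive average ranks). Degenerate inputs (zero variance, or
#' all-tied vectors for Spearman) return `NA` with a warning rather than
#' erroring, so replicate reports can flag the pair.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation coefficient in `[-1, 1]`, or `NA` when undefined.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

#' @rdname pearson_cor
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("all-tied vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Replicate reproducibility report
#'
#' For every unordered pair of libraries, computes Pearson and Spearman
#' correlations of RPKM over the pair's common expressed subset
#' ([common_expressed_subset()], resolved per pair). Pairs whose subset
#' holds fewer than 3 genes are reported with `NA` coefficients.
#'
#' Coefficients are computed on raw RPKM by default; `log10 = TRUE`
#' correlates `log10(RPKM)` instead (Spearman is unaffected by the
#' monotone transform). The choice is recorded in the `log10` attribute.
#'
#' @param tables named list (>= 2) of gene expression tables; names label
#'   the libraries.
#' @param threshold RPKM cutoff (default 10).
#' @param log10 correlate log10 RPKM instead of raw RPKM.
#' @return data.frame with one row per pair: `library_a`, `library_b`,
#'   `n_genes`, `pearson`, `spearman`, `threshold`.
#' @export
replicate_report <- function(tables, threshold = 10, log10 = FALSE) {
  stopifnot(length(tables) >= 2L)
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("lib", seq_along(tables))
  pairs <- utils::combn(names(tables), 2L)
  rows <- apply(pairs, 2L, function(pr) {
    a <- tables[[pr[1]]]; b <- tables[[pr[2]]]
    genes <- common_expressed_subset(a, b, threshold)
    x <- a$rpkm[match(genes, a$gene_id)]
    y <- b$rpkm[match(genes, b$gene_id)]
    if (log10) { x <- log10(x); y <- log10(y) }
    if (length(genes) < 3L) {
      pe <- NA_real_; sp <- NA_real_
    } else {
      pe <- pearson_cor(x, y)
      sp <- spearman_cor(x, y)
    }
    data.frame(library_a = pr[1], library_b = pr[2],
               n_genes = length(genes), pearson = pe, spearman = sp,
               threshold = threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "log10") <- log10
  out
}
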
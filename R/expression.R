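#' Per-cell-type expression percentiles
#'
#' For each cell type, computes every gene's mean expression across that
#' type's cells and its fractional rank among all genes, scaled to `[0, 1]`
#' as `(rank - 1) / (n_genes - 1)` with average ranks for ties, so the
#' top-ranked gene scores 1, the bottom gene 0, and a fully tied cell type
#' gives every gene 0.5. The
#' percentile is invariant to any monotone transformation of the per-type
#' means. Cell types without cells are excluded with a warning.
#'
#' @param expr Non-negative expression matrix, genes x cells, with rownames
#'   (gene symbols) and colnames (cell ids); dense or `Matrix` sparse.
#' @param cell_types Character/factor vector of cell-type labels, one per
#'   column of `expr` (optionally named by cell id).
#' @return A `data.frame` with columns `gene`, `cell_type`,
#'   `mean_expression`, `percentile`.
#' @export
celltype_percentiles <- function(expr, cell_types) {
  stopifnot(nrow(expr) >= 2, !is.null(rownames(expr)))
  if (length(cell_types) != ncol(expr))
    stop("one cell-type label per expression column is required")
  if (!is.null(names(cell_types)) && !is.null(colnames(expr)))
    cell_types <- cell_types[colnames(expr)]
  cell_types <- as.character(cell_types)
  types <- unique(cell_types)
  empty <- types[!types %in% cell_types]
  if (length(empty)) warning("cell type(s) without cells excluded")
  n_genes <- nrow(expr)
  rows <- lapply(types, function(ct) {
    cols <- which(cell_types == ct)
    m <- Matrix::rowMeans(expr[, cols, drop = FALSE])
    data.frame(gene = rownames(expr), cell_type = ct,
               mean_expression = as.numeric(m),
               percentile = (rank(m, ties.method = "average") - 1) /
                 (n_genes - 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare expression percentiles of a prioritized set against a baseline
#'
#' Per cell type, a two-sided Wilcoxon rank-sum test comparing the
#' expression-percentile distribution of the prioritized genes against that
#' of the baseline genes (typically all genes carrying at least one cohort
#' variant), with Benjamini-Hochberg adjustment across cell types. Reports
#' the median percentile difference (prioritized minus baseline) and a
#' significance tier (`***` FDR < 0.001, `**` < 0.01, `*` < 0.05, `ns`).
#' Sets with fewer than 3 genes present in the percentile table yield `NA`
#' with a warning.
#'
#' @param percentiles Output of [celltype_percentiles()].
#' @param prioritized Character vector of prioritized genes.
#' @param baseline Character vector of baseline genes.
#' @return A `data.frame` with one row per cell type: `cell_type`,
#'   `n_prioritized`, `n_baseline`, `median_diff`, `p`, `p_adj`, `tier`.
#' @export
compare_gene_sets <- function(percentiles, prioritized, baseline) {
  prioritized <- unique(as.character(prioritized))
  baseline <- unique(as.character(baseline))
  types <- unique(percentiles$cell_type)
  rows <- lapply(types, function(ct) {
    d <- percentiles[percentiles$cell_type == ct, , drop = FALSE]
    x <- d$percentile[d$gene %in% prioritized]
    y <- d$percentile[d$gene %in% baseline]
    if (length(x) < 3 || length(y) < 3) {
      warning("cell type '", ct, "': gene set smaller than 3; test skipped")
      return(data.frame(cell_type = ct, n_prioritized = length(x),
                        n_baseline = length(y), median_diff = NA_real_,
                        p = NA_real_))
    }
    p <- stats::wilcox.test(x, y, alternative = "two.sided",
                            exact = FALSE)$p.value
    data.frame(cell_type = ct, n_prioritized = length(x),
               n_baseline = length(y),
               median_diff = stats::median(x) - stats::median(y), p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$tier <- cut(out$p_adj, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                  labels = c("***", "**", "*", "ns"))
  out$tier <- as.character(out$tier)
  rownames(out) <- NULL
  out
}

#' Relative average expression per cell type
#'
#' Per-gene min-max scaling of cell-type mean expression to `[0, 1]` (the
#' heatmap normalization): 1 marks a gene's highest-expressing cell type.
#' Genes constant across types are set to 0.
#'
#' @inheritParams celltype_percentiles
#' @return A genes x cell-types numeric matrix in `[0, 1]`.
#' @export
relative_expression <- function(expr, cell_types) {
  pct <- celltype_percentiles(expr, cell_types)
  m <- tapply(pct$mean_expression, list(pct$gene, pct$cell_type), mean)
  m <- m[rownames(expr), , drop = FALSE]
  rng <- apply(m, 1L, range)
  span <- rng[2L, ] - rng[1L, ]
  out <- (m - rng[1L, ]) / ifelse(span > 0, span, 1)
  out[span == 0, ] <- 0
  out
}

#' Read an expression matrix with cell-type labels
#'
#' Accepts either a MatrixMarket triplet file (`.mtx`) with companion
#' row-name (genes) and column-name (cells) files, or a dense TSV with gene
#' rownames in the first column.
#'
#' @param path Matrix path (`.mtx` or TSV).
#' @param genes_path,cells_path Row/column name files (one id per line),
#'   required for `.mtx` input.
#' @return A genes x cells matrix with dimnames.
#' @export
read_expression <- function(path, genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(genes_path) || is.null(cells_path))
      stop("MTX input requires genes_path and cells_path")
    m <- Matrix::readMM(path)
    dimnames(m) <- list(readLines(genes_path), readLines(cells_path))
    m
  } else {
    d <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
    as.matrix(d)
  }
}

#' @rdname read_expression
#' @param labels_path Two-column TSV (cell id, cell type), with header.
#' @return `read_cell_labels()` returns a named character vector of cell
#'   types.
#' @export
read_cell_labels <- function(labels_path) {
  d <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  stats::setNames(as.character(d[[2L]]), as.character(d[[1L]]))
}
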
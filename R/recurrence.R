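#' Per-gene UFV recurrence
#'
#' Aggregates unusually frequent variants by gene: the number of distinct
#' UFVs (`n_ufv`, counting variants, not allele occurrences) and the number
#' of distinct cohort samples carrying at least one UFV in the gene
#' (`n_samples`, the union of carrier sets). Variants without a gene symbol
#' are skipped with a warning. Rows are sorted by `n_ufv` then `n_samples`
#' descending, ties broken lexicographically by symbol.
#'
#' @param ufvs UFV variant table (see [ufv_filter()]).
#' @return A `data.frame` with columns `gene`, `n_ufv`, `n_samples`.
#' @export
gene_recurrence <- function(ufvs) {
  gene <- as.character(ufvs$gene)
  ok <- !is.na(gene) & nzchar(gene)
  if (any(!ok))
    warning(sum(!ok), " variant(s) without a gene symbol skipped")
  ufvs <- ufvs[ok, , drop = FALSE]
  if (nrow(ufvs) == 0L)
    return(data.frame(gene = character(), n_ufv = integer(),
                      n_samples = integer()))
  carriers <- parse_carriers(ufvs$carriers)
  by_gene <- split(seq_len(nrow(ufvs)), ufvs$gene)
  rec <- data.frame(
    gene = names(by_gene),
    n_ufv = vapply(by_gene, function(i)
      length(unique(ufvs$variant_id[i])), integer(1)),
    n_samples = vapply(by_gene, function(i)
      length(unique(unlist(carriers[i]))), integer(1)),
    row.names = NULL
  )
  rec[order(-rec$n_ufv, -rec$n_samples, rec$gene), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Highly recurrent gene set
#'
#' Genes with at least `recur_min` distinct UFVs.
#'
#' @param recurrence Output of [gene_recurrence()].
#' @param recur_min Minimum number of distinct UFVs; default 4.
#' @return Character vector of gene symbols.
#' @export
recurrent_gene_set <- function(recurrence, recur_min = 4) {
  stopifnot(is.numeric(recur_min), recur_min >= 1)
  recurrence$gene[recurrence$n_ufv >= recur_min]
}

#' Rank genes for panel evaluation
#'
#' Genes ordered by recurrence (`n_ufv` descending), ties broken by
#' `n_samples` descending then symbol, optionally restricted to a candidate
#' gene set.
#'
#' @inheritParams recurrent_gene_set
#' @param genes Optional gene subset to rank (e.g. a prioritized set).
#' @return Ordered character vector of gene symbols.
#' @export
rank_genes_by_recurrence <- function(recurrence, genes = NULL) {
  if (!is.null(genes))
    recurrence <- recurrence[recurrence$gene %in% genes, , drop = FALSE]
  recurrence <- recurrence[order(-recurrence$n_ufv, -recurrence$n_samples,
                                 recurrence$gene), , drop = FALSE]
  recurrence$gene
}
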
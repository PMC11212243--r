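#' Fit the recurrence + network gene-prioritization model
#'
#' The core estimator: reduces an annotated cohort variant table to
#' unusually frequent variants (UFVs), aggregates per-gene recurrence,
#' propagates UFV seed weights over a confidence-weighted interaction
#' network, calibrates the propagation scores against an empirical null
#' ensemble that preserves each patient's mutation count while reassigning
#' mutations uniformly over network genes, and derives three prioritized
#' gene sets: recurrence-only (`n_ufv >= recur_min`), network-only
#' (`z > z_min`), and their intersection.
#'
#' Genes carrying UFVs but absent from the network receive no z-score; they
#' can enter prioritization only through recurrence and are reported in
#' the `nonnetwork_genes` element.
#'
#' @param variants Annotated cohort variant table (see [read_variants()] for
#'   the dialect).
#' @param network An [interaction_network()].
#' @param n_samples Number of diploid individuals in the cohort.
#' @param filter A [filter_config()].
#' @param recur_min Recurrence threshold (distinct UFVs per gene). Default 4.
#' @param z_min Propagation z-score threshold. Default 3.
#' @param alpha Propagation smoothing parameter in (0, 1). Default 0.5.
#' @param tol,max_iter Propagation convergence controls.
#' @param n_null Null-ensemble replicates. Default 10000.
#' @param rng_seed Integer seed driving the null ensemble.
#' @param seed_mode `"count"` (seed weight = UFV occurrences per gene,
#'   default) or `"binary"`.
#' @param normalization Network operator normalization, `"symmetric"`
#'   (default) or `"row"`.
#' @return An object of class `"netrecur"` with elements `filter_summary`,
#'   `ufv` (UFV table), `recurrence`, `scores` (gene, score, null moments,
#'   z), `sets` (the three prioritized gene sets), `nonnetwork_genes`, and
#'   the configuration used.
#' @seealso [prioritize()], [enrich_collection()], [panel_report()],
#'   [compare_gene_sets()]
#' @examples
#' sim <- simulate_study(sim_config(n_samples = 60, n_genes = 80,
#'                                  n_disease_genes = 8, rng_seed = 7))
#' fit <- netrecur(sim$variants, sim$network, n_samples = 60,
#'                 n_null = 50, rng_seed = 7)
#' print(fit)
#' head(coef(fit))
#' @export
netrecur <- function(variants, network, n_samples,
                     filter = filter_config(), recur_min = 4, z_min = 3,
                     alpha = 0.5, tol = 1e-6, max_iter = 1000,
                     n_null = 10000, rng_seed = 1,
                     seed_mode = c("count", "binary"),
                     normalization = c("symmetric", "row")) {
  cl <- match.call()
  seed_mode <- match.arg(seed_mode)
  normalization <- match.arg(normalization)
  stopifnot(inherits(network, "interaction_network"))
  variants <- validate_variants(variants)
  rare_damaging <- filter_rare_damaging(variants, filter)
  ufv <- ufv_filter(rare_damaging, n_samples, filter)
  fsum <- summarize_filtering(variants, rare_damaging, ufv)
  recurrence <- gene_recurrence(ufv)
  profiles <- mutation_profiles(ufv)
  wnorm <- normalize_network(network, normalization)
  seeds <- seed_vector(profiles, seed_mode)
  observed <- suppressWarnings(
    propagate(seeds, wnorm, alpha = alpha, tol = tol, max_iter = max_iter))
  null <- null_ensemble(profiles, wnorm, n_null = n_null,
                        rng_seed = rng_seed, alpha = alpha, tol = tol,
                        max_iter = max_iter)
  scores <- zscore_genes(observed, null)
  sets <- prioritize(recurrence, scores, recur_min = recur_min, z_min = z_min)
  structure(
    list(call = cl, n_samples = n_samples,
         config = list(filter = filter, recur_min = recur_min, z_min = z_min,
                       alpha = alpha, tol = tol, max_iter = max_iter,
                       n_null = n_null, rng_seed = rng_seed,
                       seed_mode = seed_mode, normalization = normalization),
         filter_summary = fsum, ufv = ufv, recurrence = recurrence,
         scores = scores, sets = sets,
         nonnetwork_genes = setdiff(recurrence$gene, network$nodes)),
    class = "netrecur"
  )
}

#' Prioritized gene sets from recurrence and network scores
#'
#' Combines the recurrence table and the z-scored propagation table into the
#' three candidate sets: `recurrence` (`n_ufv >= recur_min`), `network`
#' (`z > z_min`), and `intersection` (both).
#'
#' @param recurrence Output of [gene_recurrence()].
#' @param scores Output of [zscore_genes()].
#' @param recur_min Recurrence threshold. Default 4.
#' @param z_min z-score threshold (strict). Default 3.
#' @return A named list of three character vectors.
#' @export
prioritize <- function(recurrence, scores, recur_min = 4, z_min = 3) {
  stopifnot(recur_min > 0, z_min > 0)
  rec_set <- recurrent_gene_set(recurrence, recur_min)
  net_set <- scores$gene[!is.na(scores$z) & scores$z > z_min]
  list(recurrence = rec_set, network = net_set,
       intersection = intersect(rec_set, net_set))
}

#' @method print netrecur
#' @export
print.netrecur <- function(x, ...) {
  s <- x$filter_summary
  cat("Recurrence + network gene prioritization\n")
  cat(sprintf("  cohort: %d samples, %d input variants\n",
              x$n_samples, s$n_input))
  cat(sprintf("  rare damaging: %d; UFVs: %d (%.1f%%) in %d genes\n",
              s$n_after_rare_damaging, s$n_ufv, s$pct_ufv,
              nrow(x$recurrence)))
  cat(sprintf("  null ensemble: %d replicates (seed %d, alpha %.2f)\n",
              x$config$n_null, x$config$rng_seed, x$config$alpha))
  cat(sprintf("  gene sets: recurrence (n_ufv >= %d) %d | network (z > %g) %d | intersection %d\n",
              x$config$recur_min, length(x$sets$recurrence),
              x$config$z_min, length(x$sets$network),
              length(x$sets$intersection)))
  if (length(x$nonnetwork_genes))
    cat(sprintf("  %d mutated gene(s) absent from the network (no z-score)\n",
                length(x$nonnetwork_genes)))
  invisible(x)
}

#' @method summary netrecur
#' @export
summary.netrecur <- function(object, n_top = 10, ...) {
  sc <- object$scores
  top <- merge(sc, object$recurrence, by = "gene", all.x = TRUE)
  top$n_ufv[is.na(top$n_ufv)] <- 0L
  top <- top[order(-top$z, na.last = TRUE), , drop = FALSE]
  structure(list(fit = object, top = utils::head(top, n_top)),
            class = "summary.netrecur")
}

#' @method print summary.netrecur
#' @export
print.summary.netrecur <- function(x, ...) {
  print(x$fit)
  cat("\nTop genes by propagation z-score:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn netrecur Named vector of gene propagation z-scores.
#' @param object,x A fitted `"netrecur"` object.
#' @param ... Unused.
#' @export
coef.netrecur <- function(object, ...) {
  stats::setNames(object$scores$z, object$scores$gene)
}

#' @describeIn netrecur Raw (`type = "raw"`: score minus null mean) or
#'   standardized (`type = "standardized"`: z) departures from the null.
#' @param type Residual type.
#' @export
residuals.netrecur <- function(object,
                               type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  sc <- object$scores
  r <- if (type == "raw") sc$score - sc$null_mean else sc$z
  stats::setNames(r, sc$gene)
}

#' @describeIn netrecur Per-gene prediction table (recurrence, z, and set
#'   membership) for `genes` (default: all scored genes).
#' @param genes Optional character vector of genes to report.
#' @export
predict.netrecur <- function(object, genes = NULL, ...) {
  out <- merge(object$scores, object$recurrence, by = "gene", all = TRUE)
  out$n_ufv[is.na(out$n_ufv)] <- 0L
  out$n_samples[is.na(out$n_samples)] <- 0L
  if (!is.null(genes)) {
    out <- out[match(genes, out$gene), , drop = FALSE]
    out$gene <- genes
  }
  out$in_recurrence <- out$gene %in% object$sets$recurrence
  out$in_network <- out$gene %in% object$sets$network
  out$in_intersection <- out$gene %in% object$sets$intersection
  rownames(out) <- NULL
  out
}

#' @describeIn netrecur Scatter of per-gene recurrence against propagation
#'   z-score with the prioritization thresholds.
#' @export
plot.netrecur <- function(x, ...) {
  d <- predict(x)
  col <- ifelse(d$in_intersection, "firebrick",
                ifelse(d$in_recurrence | d$in_network, "steelblue", "grey60"))
  graphics::plot(d$n_ufv, d$z, pch = 16, col = col,
                 xlab = "distinct UFVs per gene",
                 ylab = "propagation z-score", ...)
  graphics::abline(h = x$config$z_min, v = x$config$recur_min - 0.5,
                   lty = 2, col = "grey40")
  graphics::legend("topleft", bty = "n", pch = 16,
                   col = c("firebrick", "steelblue", "grey60"),
                   legend = c("intersection", "one criterion", "background"))
  invisible(d)
}
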
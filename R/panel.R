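#' Cumulative cohort recovery of a ranked gene panel
#'
#' Entry `k` is the fraction of cohort samples carrying at least one UFV in
#' any of the top-`k` ranked genes (union of carrier sets). Genes in the
#' ranking without any UFV contribute nothing.
#'
#' @param ranked_genes Ordered character vector of panel genes (ranking
#'   fixed before evaluation; see [rank_genes_by_recurrence()]).
#' @param ufvs UFV variant table.
#' @param cohort_samples Character vector of all cohort sample ids.
#' @return Numeric vector of length `length(ranked_genes)`, named by gene;
#'   monotone non-decreasing in `k`.
#' @export
cohort_recovery_curve <- function(ranked_genes, ufvs, cohort_samples) {
  n <- length(unique(cohort_samples))
  if (n == 0L) stop("empty cohort")
  carriers <- parse_carriers(ufvs$carriers)
  by_gene <- split(carriers, as.character(ufvs$gene))
  missing <- setdiff(ranked_genes, names(by_gene))
  if (length(missing))
    message(length(missing), " ranked gene(s) without UFVs contribute nothing")
  covered <- character(0)
  out <- numeric(length(ranked_genes))
  for (k in seq_along(ranked_genes)) {
    g <- ranked_genes[k]
    if (g %in% names(by_gene))
      covered <- union(covered, unlist(by_gene[[g]], use.names = FALSE))
    out[k] <- length(covered) / n
  }
  stats::setNames(out, ranked_genes)
}

#' Expected control-cohort recovery under Hardy-Weinberg
#'
#' Probability that a general-population individual carries at least one of
#' the panel's variants, assuming independent variants in Hardy-Weinberg
#' equilibrium at their reference allele frequencies:
#' `1 - prod over variants v in the top-k genes of (1 - q_v)^2`. Novel
#' variants (no reference frequency) contribute `q = 0`, making the
#' estimate conservative.
#'
#' @inheritParams cohort_recovery_curve
#' @return Numeric vector per `k`, named by gene; monotone non-decreasing
#'   and invariant to gene order within the same top-`k` set.
#' @export
expected_control_curve <- function(ranked_genes, ufvs) {
  q <- ufvs$ref_af
  q[is.na(q)] <- 0
  if (any(q < 0 | q > 1)) stop("ref_af outside [0, 1]")
  # log survival contribution per gene: sum over its variants of 2*log(1-q)
  contrib <- 2 * log1p(-q)
  by_gene <- tapply(contrib, as.character(ufvs$gene), sum)
  gene_contrib <- ifelse(ranked_genes %in% names(by_gene),
                         by_gene[ranked_genes], 0)
  gene_contrib[is.na(gene_contrib)] <- 0
  stats::setNames(1 - exp(cumsum(gene_contrib)), ranked_genes)
}

#' @rdname expected_control_curve
#' @param k Panel size at which to evaluate the expected recovery.
#' @export
expected_control_recovery <- function(ranked_genes, ufvs, k) {
  stopifnot(k >= 1, k <= length(ranked_genes))
  unname(expected_control_curve(ranked_genes, ufvs)[k])
}

#' Compare candidate panels: cohort vs expected control recovery
#'
#' For each candidate ranked panel, tabulates per `k` the cumulative cohort
#' recovery, the Hardy-Weinberg expected control recovery, and their
#' difference, and flags the smallest `k` reaching a recovery target.
#'
#' @param panels Named list of ordered gene vectors.
#' @param ufvs UFV variant table.
#' @param cohort_samples Character vector of cohort sample ids.
#' @param recovery_target Cohort-recovery fraction used for the
#'   smallest-`k` flag. Default 0.5.
#' @return An object of class `"panel_report"`: a long `data.frame`
#'   (`panel`, `k`, `gene`, `cum_cohort_frac`, `expected_control_frac`,
#'   `difference`) with a `targets` attribute giving the smallest `k` per
#'   panel (NA when unreached).
#' @export
panel_report <- function(panels, ufvs, cohort_samples,
                         recovery_target = 0.5) {
  stopifnot(is.list(panels), length(panels) >= 1,
            length(names(panels)) == length(panels))
  rows <- lapply(names(panels), function(pn) {
    genes <- panels[[pn]]
    obs <- cohort_recovery_curve(genes, ufvs, cohort_samples)
    exp_ <- expected_control_curve(genes, ufvs)
    data.frame(panel = pn, k = seq_along(genes), gene = genes,
               cum_cohort_frac = as.numeric(obs),
               expected_control_frac = as.numeric(exp_),
               difference = as.numeric(obs - exp_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  targets <- vapply(names(panels), function(pn) {
    d <- out[out$panel == pn, , drop = FALSE]
    hit <- which(d$cum_cohort_frac >= recovery_target)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  structure(out, targets = targets, recovery_target = recovery_target,
            class = c("panel_report", "data.frame"))
}

#' @method print panel_report
#' @export
print.panel_report <- function(x, ...) {
  tg <- attr(x, "targets")
  cat("Panel evaluation (cohort recovery vs Hardy-Weinberg control expectation)\n")
  for (pn in names(tg)) {
    d <- x[x$panel == pn, , drop = FALSE]
    kmax <- nrow(d)
    cat(sprintf("  %s: %d genes; recovery %.1f%% (control %.1f%%) at k=%d",
                pn, kmax, 100 * d$cum_cohort_frac[kmax],
                100 * d$expected_control_frac[kmax], kmax))
    if (!is.na(tg[pn]))
      cat(sprintf("; reaches %.0f%% at k=%d", 100 * attr(x, "recovery_target"),
                  tg[pn]))
    cat("\n")
  }
  invisible(x)
}

#' @method plot panel_report
#' @export
plot.panel_report <- function(x, ...) {
  panels <- unique(x$panel)
  cols <- grDevices::hcl.colors(max(2L, length(panels)), "Dark 2")
  graphics::plot(NA, xlim = c(0, max(x$k)), ylim = c(0, 1),
                 xlab = "top-k ranked genes", ylab = "fraction recovered", ...)
  for (i in seq_along(panels)) {
    d <- x[x$panel == panels[i], , drop = FALSE]
    graphics::lines(c(0, d$k), c(0, d$cum_cohort_frac), col = cols[i], lwd = 2)
    graphics::lines(c(0, d$k), c(0, d$expected_control_frac), col = cols[i],
                    lty = 2)
  }
  graphics::legend("bottomright", bty = "n", lwd = 2, col = cols[seq_along(panels)],
                   legend = panels)
  graphics::legend("topleft", bty = "n", lty = c(1, 2),
                   legend = c("cohort", "expected control"))
  invisible(x)
}
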
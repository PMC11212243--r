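#' Gene-set collection
#'
#' A named list of gene sets restricted to a common universe (GMT-style),
#' used as the annotation side of over-representation tests.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of gene symbols; every set is
#'   intersected with it.
#' @param name Collection label.
#' @return An object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, universe, name = "collection") {
  stopifnot(is.list(sets), length(names(sets)) == length(sets),
            length(universe) > 0)
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  structure(list(name = name, sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @method print gene_set_collection
#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection '%s': %d sets over %d universe genes\n",
              x$name, length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' GMT: one set per line, tab-separated: set name, description, then member
#' gene symbols.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of one query in one annotation set
#'
#' Upper-tail probability of the observed overlap when `|query|` genes are
#' drawn without replacement from a universe containing `|annotation|`
#' annotated genes. Also reports the expected overlap
#' `n_query * n_set / n_universe`, the log observed/expected ratio, and the
#' log odds ratio of the 2x2 table (Haldane 0.5 correction when any cell is
#' zero). An optional bootstrap over the query set yields an SD and lower
#' bound for `log_obs_exp`.
#'
#' @param query Character vector of query genes.
#' @param annotation Character vector of annotated genes.
#' @param universe Character vector; query and annotation are restricted to
#'   it.
#' @param query_name,set_name Labels carried into the result row.
#' @param n_boot Bootstrap resamples of the query set for the
#'   `log_obs_exp` dispersion (0 = off).
#' @param rng_seed Seed for the bootstrap.
#' @return A one-row `data.frame` with fields `query_name`, `set_name`,
#'   `n_universe`, `n_query`, `n_set`, `n_overlap`, `expected_overlap`,
#'   `log_obs_exp`, `log_odds_ratio`, `p` (and `log_obs_exp_sd`,
#'   `log_obs_exp_lower` when `n_boot > 0`).
#' @export
hypergeom_enrich <- function(query, annotation, universe,
                             query_name = "query", set_name = "set",
                             n_boot = 0, rng_seed = 1) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- intersect(unique(as.character(query)), universe)
  annotation <- intersect(unique(as.character(annotation)), universe)
  if (length(query) == 0L) stop("empty query after universe restriction")
  n_u <- length(universe); n_q <- length(query); n_s <- length(annotation)
  ov <- length(intersect(query, annotation))
  expected <- n_q * n_s / n_u
  p <- stats::phyper(ov - 1, n_s, n_u - n_s, n_q, lower.tail = FALSE)
  log_oe <- if (expected > 0) log(ov / expected) else NA_real_
  a <- ov; b <- n_q - ov; c <- n_s - ov; d <- n_u - n_q - n_s + ov
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  out <- data.frame(query_name = query_name, set_name = set_name,
                    n_universe = n_u, n_query = n_q, n_set = n_s,
                    n_overlap = ov, expected_overlap = expected,
                    log_obs_exp = log_oe,
                    log_odds_ratio = log(a * d / (b * c)), p = p)
  if (n_boot > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(rng_seed)
    in_set <- query %in% annotation
    boots <- vapply(seq_len(n_boot), function(i) {
      ov_b <- sum(sample(in_set, n_q, replace = TRUE))
      if (ov_b == 0) NA_real_ else log(ov_b / expected)
    }, numeric(1))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    out$log_obs_exp_sd <- stats::sd(boots, na.rm = TRUE)
    out$log_obs_exp_lower <- out$log_obs_exp - out$log_obs_exp_sd
  }
  out
}

#' Enrichment of several queries against a collection
#'
#' One hypergeometric test per (query, set) pair, with Benjamini-Hochberg
#' adjustment applied within each query across the collection's sets.
#' Query genes outside the collection universe are dropped with a message.
#' Queries left empty after restriction yield rows with `n_query = 0` and
#' `p = NA`.
#'
#' @param queries Named list of character vectors.
#' @param collection A [gene_set_collection()].
#' @param n_boot,rng_seed Passed to [hypergeom_enrich()].
#' @return A `data.frame` of [hypergeom_enrich()] rows plus `p_adj`.
#' @export
enrich_collection <- function(queries, collection, n_boot = 0, rng_seed = 1) {
  stopifnot(inherits(collection, "gene_set_collection"),
            is.list(queries), length(names(queries)) == length(queries))
  rows <- list()
  for (qn in names(queries)) {
    q_raw <- unique(as.character(queries[[qn]]))
    q <- intersect(q_raw, collection$universe)
    if (length(q) < length(q_raw))
      message(length(q_raw) - length(q), " gene(s) of query '", qn,
              "' outside the collection universe dropped")
    q_rows <- lapply(names(collection$sets), function(sn) {
      if (length(q) == 0L)
        return(data.frame(query_name = qn, set_name = sn,
                          n_universe = length(collection$universe),
                          n_query = 0L, n_set = length(collection$sets[[sn]]),
                          n_overlap = 0L, expected_overlap = 0,
                          log_obs_exp = NA_real_, log_odds_ratio = NA_real_,
                          p = NA_real_))
      hypergeom_enrich(q, collection$sets[[sn]], collection$universe,
                       query_name = qn, set_name = sn, n_boot = n_boot,
                       rng_seed = rng_seed)
    })
    q_df <- do.call(rbind, q_rows)
    q_df$p_adj <- stats::p.adjust(q_df$p, method = "BH")
    rows[[qn]] <- q_df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Threshold sensitivity of prioritized-set enrichment
#'
#' Re-derives the three prioritized gene sets over a grid of UFV fold
#' thresholds (`ratio_grid`), recurrence thresholds (`recur_grid`) and
#' z-score thresholds (`z_grid`), and records the enrichment of each set
#' against the collection at every grid point. Propagation scores are held
#' fixed: `z_grid` varies the cut applied to the supplied `scores`, while
#' `ratio_grid` re-runs the UFV filter and recurrence on the rare/damaging
#' variant table. Grid points that empty a gene set are retained with
#' `n_query = 0` and `p = NA`.
#'
#' @param variants_rare_damaging Rare/damaging variant table (pre-UFV).
#' @param n_samples Cohort size.
#' @param scores Fixed z-score table from [zscore_genes()].
#' @param collection A [gene_set_collection()].
#' @param ratio_grid,recur_grid,z_grid Numeric grids; defaults are the
#'   single default thresholds.
#' @param filter Base [filter_config()] whose `ratio_min` is swept.
#' @return Long-format `data.frame`: grid coordinates + enrichment fields.
#' @export
threshold_sensitivity <- function(variants_rare_damaging, n_samples, scores,
                                  collection, ratio_grid = 1.3,
                                  recur_grid = 4, z_grid = 3,
                                  filter = filter_config()) {
  stopifnot(length(ratio_grid) > 0, length(recur_grid) > 0,
            length(z_grid) > 0)
  out <- list()
  for (r in ratio_grid) {
    cfg <- filter
    cfg$ratio_min <- r
    ufv <- suppressWarnings(ufv_filter(variants_rare_damaging, n_samples, cfg))
    rec <- suppressWarnings(gene_recurrence(ufv))
    for (rm in recur_grid) for (zm in z_grid) {
      sets <- prioritize(rec, scores, recur_min = rm, z_min = zm)
      enr <- enrich_collection(sets, collection)
      enr$ratio_min <- r
      enr$recur_min <- rm
      enr$z_min <- zm
      out[[length(out) + 1L]] <- enr
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
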
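#' Run the full prioritization pipeline from a single configuration
#'
#' Orchestrates filtering, recurrence, network propagation, prioritization,
#' enrichment, panel evaluation and (when expression inputs are supplied)
#' cell-type expression comparison, writing every intermediate artifact
#' plus a JSON run manifest to the output directory. Any stage failure
#' aborts with the stage name after writing a partial manifest.
#'
#' @param config A named list, or a path to a YAML file with the same keys:
#'   \describe{
#'     \item{variants}{Path to the variant TSV, or a `data.frame`.}
#'     \item{network}{Path to an edge list, or an [interaction_network()].}
#'     \item{n_samples}{Cohort size (required).}
#'     \item{outdir}{Output directory (required; created if absent).}
#'     \item{gene_sets}{Optional GMT path or [gene_set_collection()].}
#'     \item{expression, cell_labels}{Optional expression matrix (TSV/MTX
#'       path or matrix) and cell-type labels (TSV path or named vector).}
#'     \item{common_af_max, ratio_min, recur_min, z_min, alpha, n_null,
#'       rng_seed, recovery_target, panel_size}{Stage parameters with the
#'       package defaults.}
#'   }
#' @return The run manifest (invisibly also written as `manifest.json`):
#'   configuration hash, seed, per-stage row counts and package version.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$outdir),
            !is.null(config$n_samples))
  defaults <- list(common_af_max = 0.05, ratio_min = 1.3, recur_min = 4,
                   z_min = 3, alpha = 0.5, n_null = 10000, rng_seed = 1,
                   recovery_target = 0.5, panel_size = 50)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    package = "netrecur",
    version = as.character(utils::packageVersion("netrecur")),
    rng_seed = config$rng_seed,
    config_hash = hash_config(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      flush_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  variants <- stage("load", {
    if (is.character(config$variants)) read_variants(config$variants)
    else validate_variants(config$variants)
  })
  network <- stage("load", {
    if (is.character(config$network)) read_network(config$network)
    else config$network
  })
  manifest$stages$load <- list(status = "ok", n_variants = nrow(variants),
                               n_network_nodes = length(network$nodes),
                               n_network_edges = nrow(network$edges))

  fcfg <- filter_config(common_af_max = config$common_af_max,
                        ratio_min = config$ratio_min)
  fit <- stage("prioritize", netrecur(
    variants, network, n_samples = config$n_samples, filter = fcfg,
    recur_min = config$recur_min, z_min = config$z_min,
    alpha = config$alpha, n_null = config$n_null,
    rng_seed = config$rng_seed))
  write_variants(fit$ufv, file.path(outdir, "ufv.tsv"))
  jsonlite::write_json(unclass(fit$filter_summary),
                       file.path(outdir, "filter_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(fit$recurrence, file.path(outdir, "recurrence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$scores, file.path(outdir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sn in names(fit$sets))
    writeLines(fit$sets[[sn]], file.path(outdir, paste0("genes_", sn, ".txt")))
  if (length(fit$nonnetwork_genes))
    writeLines(fit$nonnetwork_genes, file.path(outdir, "genes_off_network.txt"))
  manifest$stages$filter <- list(status = "ok",
                                 n_input = fit$filter_summary$n_input,
                                 n_rare_damaging = fit$filter_summary$n_after_rare_damaging,
                                 n_ufv = fit$filter_summary$n_ufv)
  manifest$stages$prioritize <- list(
    status = "ok", n_null = config$n_null,
    n_recurrence = length(fit$sets$recurrence),
    n_network = length(fit$sets$network),
    n_intersection = length(fit$sets$intersection))

  if (!is.null(config$gene_sets)) {
    enr <- stage("enrich", {
      collection <- if (is.character(config$gene_sets)) {
        sets <- read_gmt(config$gene_sets)
        universe <- union(unique(variants$gene), unlist(sets))
        gene_set_collection(sets, universe)
      } else config$gene_sets
      suppressMessages(enrich_collection(fit$sets, collection))
    })
    utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$enrich <- list(status = "ok", n_tests = nrow(enr))
  } else {
    manifest$stages$enrich <- list(status = "skipped")
  }

  panel <- stage("panel", {
    cohort <- sort(unique(unlist(parse_carriers(variants$carriers))))
    ranked <- rank_genes_by_recurrence(fit$recurrence,
                                       genes = fit$sets$intersection)
    ranked <- utils::head(ranked, config$panel_size)
    if (length(ranked) == 0L) NULL else
      panel_report(list(intersection = ranked), fit$ufv, cohort,
                   recovery_target = config$recovery_target)
  })
  if (!is.null(panel)) {
    utils::write.table(as.data.frame(panel), file.path(outdir, "panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$panel <- list(status = "ok", n_rows = nrow(panel),
                                  k_at_target = unname(attr(panel, "targets")))
  } else {
    manifest$stages$panel <- list(status = "skipped")
  }

  if (!is.null(config$expression)) {
    cmp <- stage("expression", {
      expr <- if (is.character(config$expression))
        read_expression(config$expression, config$expression_genes,
                        config$expression_cells)
      else config$expression
      labels <- if (is.character(config$cell_labels))
        read_cell_labels(config$cell_labels) else config$cell_labels
      pct <- celltype_percentiles(expr, labels)
      baseline <- unique(variants$gene)
      compare_gene_sets(pct, fit$sets$intersection, baseline)
    })
    utils::write.table(cmp, file.path(outdir, "expression_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$expression <- list(status = "ok", n_cell_types = nrow(cmp))
  } else {
    manifest$stages$expression <- list(status = "skipped")
  }

  flush_manifest()
  invisible(manifest)
}

# Stable hash of the configuration: canonical JSON of the scalar entries
# (file-path and parameter values), md5 via tools::md5sum on a temp file.
hash_config <- function(config) {
  scalars <- Filter(function(x) is.atomic(x) && length(x) == 1L, config)
  scalars <- scalars[order(names(scalars))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(scalars, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
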
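#' Confidence-weighted gene interaction network
#'
#' Constructs an undirected interaction network from an edge list with
#' confidence weights. Self-loops are dropped, duplicate pairs collapsed to
#' their maximum weight, and STRING-style integer confidences (0-1000) are
#' rescaled to (0, 1] when detected (maximum weight above 1).
#'
#' @param edges A `data.frame` whose first three columns are gene A, gene B
#'   and the confidence weight.
#' @param nodes Optional character vector of node names; defaults to the
#'   genes appearing in `edges`. Extra nodes are retained as isolated nodes.
#' @return An object of class `"interaction_network"` with elements `nodes`
#'   (character) and `edges` (`data.frame` with `gene_a`, `gene_b`, `weight`).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 3L)
  edges <- data.frame(gene_a = as.character(edges[[1L]]),
                      gene_b = as.character(edges[[2L]]),
                      weight = as.numeric(edges[[3L]]))
  if (any(is.na(edges$weight)) || any(edges$weight <= 0))
    stop("edge weights must be positive")
  if (nrow(edges) && max(edges$weight) > 1) {
    message("edge weights exceed 1; assuming STRING 0-1000 confidence scale")
    edges$weight <- edges$weight / 1000
    if (any(edges$weight > 1))
      stop("edge weights exceed 1000; unrecognized confidence scale")
  }
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) removed")
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical unordered pair, keep max weight among duplicates
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste0(a, "\r", b)
  if (anyDuplicated(key)) {
    w <- tapply(edges$weight, key, max)
    ab <- strsplit(names(w), "\r", fixed = TRUE)
    edges <- data.frame(gene_a = vapply(ab, `[`, "", 1L),
                        gene_b = vapply(ab, `[`, "", 2L),
                        weight = as.numeric(w), row.names = NULL)
  } else {
    edges <- data.frame(gene_a = a, gene_b = b, weight = edges$weight)
  }
  all_nodes <- sort(unique(c(nodes, edges$gene_a, edges$gene_b)))
  if (length(all_nodes) == 0L) stop("network has no nodes")
  structure(list(nodes = all_nodes, edges = edges),
            class = "interaction_network")
}

#' @method print interaction_network
#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes, %d weighted edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(sprintf("  confidence range: [%.3g, %.3g]\n",
                min(x$edges$weight), max(x$edges$weight)))
  invisible(x)
}

#' Read / write an edge-list network file
#'
#' Three-column whitespace- or tab-separated edge list (gene A, gene B,
#' confidence). A header row is detected automatically; STRING 0-1000
#' confidences are rescaled to (0, 1].
#'
#' @param path File path.
#' @return `read_network()` returns an [interaction_network()].
#' @export
read_network <- function(path) {
  first <- scan(path, what = character(), nlines = 1L, quiet = TRUE)
  header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
  edges <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  interaction_network(edges)
}

#' @rdname read_network
#' @param network An [interaction_network()] to write.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Symmetric degree-normalized network operator
#'
#' Builds the sparse symmetric operator used by propagation:
#' `W[i, j] = w_ij / sqrt(d_i * d_j)` with `d` the weighted degree
#' (`normalization = "symmetric"`), or the column-stochastic form
#' `w_ij / d_j` (`normalization = "row"`). Isolated nodes are retained with
#' zero rows.
#'
#' @param network An [interaction_network()].
#' @param normalization `"symmetric"` (default) or `"row"`.
#' @return A sparse `Matrix::dgCMatrix` with node dimnames.
#' @export
normalize_network <- function(network,
                              normalization = c("symmetric", "row")) {
  stopifnot(inherits(network, "interaction_network"))
  normalization <- match.arg(normalization)
  nodes <- network$nodes
  n <- length(nodes)
  e <- network$edges
  i <- match(e$gene_a, nodes)
  j <- match(e$gene_b, nodes)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = c(e$weight, e$weight), dims = c(n, n),
                              dimnames = list(nodes, nodes))
  d <- Matrix::rowSums(adj)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  w <- if (normalization == "symmetric") {
    Matrix::Diagonal(n, dinv) %*% adj %*% Matrix::Diagonal(n, dinv)
  } else {
    adj %*% Matrix::Diagonal(n, ifelse(d > 0, 1 / d, 0))
  }
  dimnames(w) <- list(nodes, nodes)
  w
}

# Batched fixed-point iteration: columns of `smat` are independent seed
# vectors (each already normalized to sum 1). Converges for alpha < 1 since
# the spectral radius of alpha * W is below 1.
propagate_matrix <- function(wnorm, smat, alpha, tol, max_iter) {
  f <- smat
  for (iter in seq_len(max_iter)) {
    f_new <- alpha * (wnorm %*% f) + (1 - alpha) * smat
    delta <- max(Matrix::colSums(abs(f_new - f)))
    f <- f_new
    if (delta < tol) return(as.matrix(f))
  }
  stop(sprintf("propagation did not converge in %d iterations (residual %.3g)",
               max_iter, delta))
}

#' Network propagation from mutated-gene seeds
#'
#' Iterates the random-walk-with-restart fixed point
#' `F <- alpha * W %*% F + (1 - alpha) * S`, where `W` is the normalized
#' network operator and `S` is the seed vector rescaled to sum 1, until the
#' L1 change drops below `tol`. Seed genes absent from the network are
#' dropped with a warning.
#'
#' @param seeds Named non-negative numeric vector of seed weights (e.g. UFV
#'   counts per gene).
#' @param network An [interaction_network()], or a pre-computed normalized
#'   operator from [normalize_network()].
#' @param alpha Smoothing parameter in (0, 1); the walk restarts at the
#'   seeds with probability `1 - alpha`. Default 0.5.
#' @param tol L1 convergence tolerance. Default 1e-6.
#' @param max_iter Iteration cap. Default 1000.
#' @param normalization Passed to [normalize_network()] when `network` is an
#'   `interaction_network`.
#' @return Named numeric vector of propagation scores over network nodes.
#' @export
propagate <- function(seeds, network, alpha = 0.5, tol = 1e-6,
                      max_iter = 1000, normalization = "symmetric") {
  stopifnot(is.numeric(seeds), !is.null(names(seeds)), all(seeds >= 0),
            alpha > 0, alpha < 1)
  wnorm <- if (inherits(network, "interaction_network"))
    normalize_network(network, normalization) else network
  nodes <- rownames(wnorm)
  drop <- setdiff(names(seeds)[seeds > 0], nodes)
  if (length(drop))
    warning(length(drop), " seed gene(s) not in the network dropped: ",
            paste(utils::head(drop, 5L), collapse = ", "))
  s <- numeric(length(nodes))
  names(s) <- nodes
  keep <- intersect(names(seeds), nodes)
  s[keep] <- seeds[keep]
  if (sum(s) <= 0) stop("no seed weight overlaps the network nodes")
  s <- s / sum(s)
  f <- propagate_matrix(wnorm, matrix(s, ncol = 1L), alpha, tol, max_iter)
  stats::setNames(f[, 1L], nodes)
}

#' Per-patient mutation profiles
#'
#' Expands a UFV table into one row per (variant, carrier) pair: the
#' multiset of mutated genes per patient, with one entry per UFV carried.
#' This is the unit the null ensemble preserves per patient.
#'
#' @param ufvs UFV variant table.
#' @return A `data.frame` with columns `sample_id` and `gene`.
#' @export
mutation_profiles <- function(ufvs) {
  carriers <- parse_carriers(ufvs$carriers)
  n <- lengths(carriers)
  data.frame(sample_id = unlist(carriers, use.names = FALSE),
             gene = rep(as.character(ufvs$gene), n))
}

#' Seed vector from mutation profiles
#'
#' Seed weight of a gene is the total number of UFV occurrences in it across
#' patients (`mode = "count"`), or 1 for any mutated gene
#' (`mode = "binary"`).
#'
#' @param profiles Output of [mutation_profiles()].
#' @param mode `"count"` (default) or `"binary"`.
#' @return Named numeric seed vector.
#' @export
seed_vector <- function(profiles, mode = c("count", "binary")) {
  mode <- match.arg(mode)
  counts <- table(profiles$gene)
  s <- as.numeric(counts)
  names(s) <- names(counts)
  if (mode == "binary") s[] <- 1
  s
}

#' Empirical null ensemble for propagation scores
#'
#' Estimates per-gene null moments of the propagation score under a null in
#' which each patient keeps their observed number of mutations but every
#' mutation is reassigned to a gene drawn uniformly (with replacement) from
#' the network's node set. Because reassignments are independent and
#' uniform, drawing the cohort-total number of mutations uniformly over
#' nodes is distributionally identical to per-patient draws, and is how the
#' replicates are realized. Seeds are rebuilt exactly as for the observed
#' data (count mode aggregates the multiset) and propagated; running mean
#' and SD are accumulated with Welford's one-pass update. Each replicate is
#' independently seeded from `rng_seed` via a replicate-indexed seed table.
#'
#' @param profiles Observed [mutation_profiles()]; only the total mutation
#'   count (and its per-patient decomposition) is used.
#' @param network An [interaction_network()] or normalized operator.
#' @param n_null Number of null replicates (>= 2). Default 10000.
#' @param rng_seed Integer seed for the ensemble.
#' @param chunk Replicates propagated per batch. Default 500.
#' @inheritParams propagate
#' @return A `data.frame` with columns `gene`, `null_mean`, `null_sd`.
#' @export
null_ensemble <- function(profiles, network, n_null = 10000, rng_seed = 1,
                          alpha = 0.5, tol = 1e-6, max_iter = 1000,
                          normalization = "symmetric", chunk = 500) {
  if (n_null < 2) stop("n_null must be at least 2 for the SD to be defined")
  wnorm <- if (inherits(network, "interaction_network"))
    normalize_network(network, normalization) else network
  nodes <- rownames(wnorm)
  n_nodes <- length(nodes)
  m_total <- nrow(profiles)
  if (m_total < 1) stop("no mutations in the cohort profiles")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(rng_seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_null)
  mean_vec <- numeric(n_nodes)
  m2_vec <- numeric(n_nodes)
  done <- 0L
  while (done < n_null) {
    k <- min(chunk, n_null - done)
    smat <- matrix(0, n_nodes, k)
    for (j in seq_len(k)) {
      set.seed(rep_seeds[done + j])
      idx <- sample.int(n_nodes, m_total, replace = TRUE)
      smat[, j] <- tabulate(idx, nbins = n_nodes) / m_total
    }
    f <- propagate_matrix(wnorm, smat, alpha, tol, max_iter)
    for (j in seq_len(k)) {
      i <- done + j
      delta <- f[, j] - mean_vec
      mean_vec <- mean_vec + delta / i
      m2_vec <- m2_vec + delta * (f[, j] - mean_vec)
    }
    done <- done + k
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  data.frame(gene = nodes, null_mean = mean_vec,
             null_sd = sqrt(m2_vec / (n_null - 1)), row.names = NULL)
}

#' Gene z-scores against the empirical null
#'
#' `z = (score - null_mean) / null_sd` per gene; genes with zero null SD get
#' `NA` (flagged undefined). Output is sorted by `z` descending with
#' undefined genes last.
#'
#' @param observed Named numeric vector of observed propagation scores.
#' @param null Null moments from [null_ensemble()].
#' @return A `data.frame` with columns `gene`, `score`, `null_mean`,
#'   `null_sd`, `z`.
#' @export
zscore_genes <- function(observed, null) {
  missing <- setdiff(names(observed), null$gene)
  if (length(missing))
    stop("gene(s) missing from the null ensemble: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  null <- null[match(names(observed), null$gene), , drop = FALSE]
  z <- ifelse(null$null_sd > 0,
              (observed - null$null_mean) / null$null_sd, NA_real_)
  out <- data.frame(gene = names(observed), score = as.numeric(observed),
                    null_mean = null$null_mean, null_sd = null$null_sd,
                    z = z, row.names = NULL)
  out[order(-out$z, out$gene, na.last = TRUE), , drop = FALSE] |>
    `rownames<-`(NULL)
}
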
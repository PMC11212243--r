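#' Synthetic-study configuration
#'
#' Parameters of the synthetic cohort / network / gene-set / expression
#' generator. Defaults are the study conditions the pipeline targets: a
#' 511-sample cohort, 2000 genes of which 50 form a connected disease
#' module whose variants are inflated 2-fold in the cohort over their
#' reference frequencies, a 10% novel-variant fraction, and disease genes
#' planted into designated gene sets at 5x the background rate.
#'
#' @param n_samples Diploid cohort size. Default 511.
#' @param n_genes Gene universe size. Default 2000.
#' @param n_disease_genes Planted disease genes. Default 50.
#' @param variants_per_gene Mean of the Poisson per-gene variant count.
#'   Default 8 (about 16,000 generated variants over the default 2000-gene
#'   universe, the scale of a cohort rare damaging variant table).
#' @param fold Cohort allele-frequency inflation factor for disease-gene
#'   variants; must be >= 1 (1 = no signal). Default 2.
#' @param novel_frac Fraction of variants absent from the reference panel.
#'   Default 0.1.
#' @param benign_frac Per-predictor probability of a benign label. Default
#'   0.15.
#' @param common_frac Fraction of variants drawn common (reference
#'   frequency above 5%), exercising the rarity filter. Default 0.05.
#' @param p_other Probability of a non-protein-altering consequence.
#'   Default 0.05.
#' @param af_pareto_min,af_pareto_shape,af_beta_shape1,af_beta_shape2,af_mix_pareto,af_max
#'   Rare allele-frequency law on `(0, af_max]`: a mixture (weight
#'   `af_mix_pareto`) of a truncated Pareto (scale `af_pareto_min`, shape
#'   `af_pareto_shape`) and a truncated Beta.
#' @param edge_prob Background edge probability of the interaction network.
#'   Default 0.005 (mean degree 10 at 2000 genes).
#' @param module_factor Multiplier on `edge_prob` among disease genes
#'   (planted module density). Default 20.
#' @param module_edge_prob Optional direct edge probability within the
#'   planted module, overriding `edge_prob * module_factor` (useful e.g.
#'   to build a module-only network with `edge_prob = 0`).
#' @param weight_min Lower bound of the uniform edge-confidence law on
#'   `(weight_min, 1]`. Default 0.15.
#' @param n_gene_sets,n_relevant_sets,set_size_range,geneset_planting_rate
#'   Gene-set collection: number of sets, number of designated relevant
#'   sets receiving disease genes at `geneset_planting_rate` times the
#'   background membership rate, and the set-size range.
#' @param n_cell_types,n_upregulated_types,cells_per_type,expression_effect_size
#'   Expression atlas: cell types, types in which disease genes are shifted
#'   upward, cells per type, and the multiplicative effect
#'   (`1 + effect` fold change; 0 = no signal).
#' @param drop_unobserved Drop variants with a cohort allele count of zero
#'   from the emitted table (a cohort variant table only contains observed
#'   variants). Set `FALSE` to keep them, e.g. to check the genotype model
#'   calibration against the reference frequencies without ascertainment.
#'   Default `TRUE`.
#' @param rng_seed Master seed; all generators derive from it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_samples = 511, n_genes = 2000,
                       n_disease_genes = 50, variants_per_gene = 8,
                       fold = 2, novel_frac = 0.1, benign_frac = 0.15,
                       common_frac = 0.05, p_other = 0.05,
                       af_pareto_min = 1e-4, af_pareto_shape = 1,
                       af_beta_shape1 = 0.5, af_beta_shape2 = 30,
                       af_mix_pareto = 0.8, af_max = 0.05,
                       edge_prob = 0.005, module_factor = 20,
                       module_edge_prob = NULL,
                       weight_min = 0.15, n_gene_sets = 20,
                       n_relevant_sets = 3, set_size_range = c(40, 200),
                       geneset_planting_rate = 5, n_cell_types = 8,
                       n_upregulated_types = 2, cells_per_type = 30,
                       expression_effect_size = 1, drop_unobserved = TRUE,
                       rng_seed = 1) {
  stopifnot(fold >= 1, n_disease_genes < n_genes, n_samples >= 1,
            novel_frac >= 0, novel_frac <= 1, common_frac >= 0,
            common_frac <= 1, af_max > 0, af_max <= 1,
            n_upregulated_types <= n_cell_types)
  structure(as.list(environment()), class = "sim_config")
}

# Heavy-tailed rare-AF law on (0, af_max]: truncated Pareto / truncated Beta
# mixture (inverse-CDF Pareto; rejection-free Beta via quantile truncation).
rare_af <- function(n, config) {
  use_pareto <- stats::runif(n) < config$af_mix_pareto
  out <- numeric(n)
  np <- sum(use_pareto)
  if (np) {
    xm <- config$af_pareto_min; a <- config$af_pareto_shape
    u <- stats::runif(np)
    fmax <- 1 - (xm / config$af_max)^a  # CDF mass below truncation point
    out[use_pareto] <- xm / (1 - u * fmax)^(1 / a)
  }
  nb <- n - np
  if (nb) {
    pmax_ <- stats::pbeta(config$af_max, config$af_beta_shape1,
                          config$af_beta_shape2)
    u <- stats::runif(nb, 0, pmax_)
    out[!use_pareto] <- stats::qbeta(u, config$af_beta_shape1,
                                     config$af_beta_shape2)
  }
  pmin(pmax(out, 1e-6), config$af_max)
}

# category frequencies typical of a cohort UFV table (missense-dominated,
# mostly SNPs, few indels)
CONSEQUENCE_WEIGHTS <- c(missense = 10132, nonsense = 775,
                         frameshift_del = 199, nonstop = 41,
                         inframe_del = 31, frameshift_ins = 22,
                         inframe_ins = 6, splice_site = 3)

#' Simulate an annotated cohort variant table with planted disease genes
#'
#' Draws per-gene variant counts, assigns each variant a reference allele
#' frequency from the rare-AF law (a configurable fraction novel, i.e.
#' recorded as absent while a latent frequency drives genotypes, plus a
#' configurable common fraction), and sets each individual's genotype by
#' two Bernoulli draws at probability `q`: the reference frequency for
#' background genes and `min(fold * q, 1)` (capped with a warning) for
#' disease genes. Variant types and consequences follow the observed
#' category proportions of cohort UFV tables. By default only observed
#' variants (cohort allele count of at least one) are emitted, matching the
#' ascertainment of a real cohort table; `drop_unobserved = FALSE` retains
#' every generated variant so the genotype model can be calibrated against
#' the reference frequencies.
#'
#' @param config A [sim_config()].
#' @return A list with `variants` (the variant-table dialect of
#'   [read_variants()]) and `truth` (list with `genes`, `disease_genes`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  disease <- sort(sample(genes, config$n_disease_genes))
  samples <- sprintf("S%04d", seq_len(config$n_samples))
  nv <- stats::rpois(config$n_genes, config$variants_per_gene)
  gene_of <- rep(genes, nv)
  m <- length(gene_of)
  af <- rare_af(m, config)
  common <- stats::runif(m) < config$common_frac
  af[common] <- stats::runif(sum(common), config$af_max, 3 * config$af_max)
  novel <- !common & stats::runif(m) < config$novel_frac
  is_disease <- gene_of %in% disease
  q <- ifelse(is_disease, config$fold * af, af)
  if (any(q > 1)) {
    warning(sum(q > 1), " variant(s) with fold * ref_af > 1 capped at 1")
    q <- pmin(q, 1)
  }
  csq <- sample(names(CONSEQUENCE_WEIGHTS), m, replace = TRUE,
                prob = CONSEQUENCE_WEIGHTS)
  other <- stats::runif(m) < config$p_other
  csq[other] <- "other"
  vtype <- ifelse(csq %in% c("frameshift_del", "inframe_del"), "DEL",
                  ifelse(csq %in% c("frameshift_ins", "inframe_ins"),
                         "INS", "SNP"))
  sift <- ifelse(stats::runif(m) < config$benign_frac, "benign", "damaging")
  polyphen <- ifelse(stats::runif(m) < config$benign_frac, "benign",
                     "probably_damaging")
  ac <- integer(m)
  carriers <- character(m)
  for (v in seq_len(m)) {
    g <- stats::rbinom(config$n_samples, 2L, q[v])
    ac[v] <- sum(g)
    carriers[v] <- paste(samples[g > 0], collapse = ",")
  }
  variants <- data.frame(
    variant_id = sprintf("var%06d", seq_len(m)),
    gene = gene_of, variant_type = vtype, consequence = csq,
    allele_count = ac, carriers = carriers,
    ref_af = ifelse(novel, NA_real_, af), sift = sift, polyphen = polyphen
  )
  if (isTRUE(config$drop_unobserved))
    variants <- variants[variants$allele_count > 0, , drop = FALSE]
  list(variants = variants,
       truth = list(genes = genes, disease_genes = disease,
                    samples = samples))
}

#' Simulate a confidence-weighted network with a planted disease module
#'
#' An Erdos-Renyi background graph over all genes plus extra edges among
#' the disease genes so that the planted module's internal edge probability
#' is `min(1, edge_prob * module_factor)`; confidence weights are uniform
#' on `(weight_min, 1]`. A module factor of 1 leaves disease genes
#' indistinguishable from background.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_cohort()] (uses `genes` and
#'   `disease_genes`).
#' @return An [interaction_network()] over all genes.
#' @export
simulate_network <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 1L)
  genes <- truth$genes
  n <- length(genes)
  bg <- sample_pairs(n, config$edge_prob)
  d_idx <- match(truth$disease_genes, genes)
  p_mod <- if (is.null(config$module_edge_prob))
    min(1, config$edge_prob * config$module_factor)
  else config$module_edge_prob
  mod <- sample_pairs(length(d_idx), p_mod)
  mod <- cbind(d_idx[mod[, 1L]], d_idx[mod[, 2L]])
  pairs <- rbind(bg, mod)
  if (nrow(pairs) == 0L)
    stop("simulated network has no edges; raise edge_prob or module_factor")
  edges <- data.frame(gene_a = genes[pairs[, 1L]], gene_b = genes[pairs[, 2L]],
                      weight = stats::runif(nrow(pairs), config$weight_min, 1))
  interaction_network(edges, nodes = genes)
}

# Sample unordered pairs from {1..n} each with probability p, without
# materializing all n*(n-1)/2 pairs.
sample_pairs <- function(n, p) {
  npairs <- n * (n - 1) / 2
  if (npairs < 1 || p <= 0) return(matrix(integer(), ncol = 2L))
  m <- stats::rbinom(1L, npairs, min(1, p))
  if (m == 0L) return(matrix(integer(), ncol = 2L))
  idx <- sort(sample(npairs, m))
  # map linear index k (1-based) over pairs (i<j) ordered by i then j
  i <- findInterval(idx - 1, cumsum((n - 1):1), left.open = FALSE) + 1L
  offset <- c(0, cumsum((n - 1):1))[i]
  j <- i + (idx - offset)
  cbind(i, j)
}

#' Simulate a gene-set collection with planted relevant sets
#'
#' Generates `n_gene_sets` sets over the full gene universe. The first
#' `n_relevant_sets` are "relevant": disease genes join them with
#' probability `min(1, geneset_planting_rate * size / n_genes)` (background
#' genes at the base rate keeping the expected size); remaining sets are
#' uniform draws.
#'
#' @inheritParams simulate_network
#' @return A list with `collection` (a [gene_set_collection()]) and
#'   `planted_gene_sets` (names of the relevant sets).
#' @export
simulate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 2L)
  genes <- truth$genes
  n <- length(genes)
  is_disease <- genes %in% truth$disease_genes
  nd <- sum(is_disease)
  sets <- list()
  for (s in seq_len(config$n_gene_sets)) {
    size <- sample(seq(config$set_size_range[1L], config$set_size_range[2L]),
                   1L)
    if (s <= config$n_relevant_sets) {
      base_p <- size / n
      p_d <- min(1, config$geneset_planting_rate * base_p)
      p_b <- max(0, (size - nd * p_d) / (n - nd))
      member <- stats::runif(n) < ifelse(is_disease, p_d, p_b)
      sets[[sprintf("relevant_%02d", s)]] <- genes[member]
    } else {
      sets[[sprintf("set_%02d", s)]] <- sort(sample(genes, size))
    }
  }
  list(collection = gene_set_collection(sets, universe = genes,
                                        name = "synthetic"),
       planted_gene_sets = names(sets)[seq_len(config$n_relevant_sets)])
}

#' Simulate a labeled expression atlas with upregulated disease genes
#'
#' Poisson counts with per-gene log-normal baseline rates; in
#' `n_upregulated_types` randomly chosen cell types, disease-gene rates are
#' multiplied by `1 + expression_effect_size`.
#'
#' @inheritParams simulate_network
#' @return A list with `expr` (genes x cells matrix), `cell_types` (named
#'   character vector) and `upregulated_cell_types`.
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 3L)
  genes <- truth$genes
  n <- length(genes)
  types <- sprintf("type%02d", seq_len(config$n_cell_types))
  up <- sort(sample(types, config$n_upregulated_types))
  lambda <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  cells <- character(0)
  labels <- character(0)
  mats <- list()
  is_disease <- genes %in% truth$disease_genes
  for (ct in types) {
    lam <- lambda
    if (ct %in% up)
      lam[is_disease] <- lam[is_disease] * (1 + config$expression_effect_size)
    k <- config$cells_per_type
    mats[[ct]] <- matrix(stats::rpois(n * k, rep(lam, k)), nrow = n)
    ids <- sprintf("%s_c%03d", ct, seq_len(k))
    cells <- c(cells, ids)
    labels <- c(labels, rep(ct, k))
  }
  expr <- do.call(cbind, mats)
  dimnames(expr) <- list(genes, cells)
  list(expr = expr, cell_types = stats::setNames(labels, cells),
       upregulated_cell_types = up)
}

#' Simulate a complete synthetic study
#'
#' Runs all generators under one configuration and merges the ground truth.
#'
#' @param config A [sim_config()].
#' @return A list with `variants`, `network`, `gene_sets` (a
#'   [gene_set_collection()]), `expr`, `cell_types`, `samples`, and `truth`
#'   (`genes`, `disease_genes`, `planted_gene_sets`,
#'   `upregulated_cell_types`).
#' @export
simulate_study <- function(config = sim_config()) {
  cohort <- simulate_cohort(config)
  network <- simulate_network(config, cohort$truth)
  gs <- simulate_gene_sets(config, cohort$truth)
  ex <- simulate_expression(config, cohort$truth)
  truth <- cohort$truth
  truth$planted_gene_sets <- gs$planted_gene_sets
  truth$upregulated_cell_types <- ex$upregulated_cell_types
  list(variants = cohort$variants, network = network,
       gene_sets = gs$collection, expr = ex$expr,
       cell_types = ex$cell_types, samples = cohort$truth$samples,
       truth = truth)
}
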
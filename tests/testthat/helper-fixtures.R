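# In-code fixtures shared across test files.

# Minimal well-formed variant row(s); override any field.
make_variants <- function(variant_id, gene, allele_count, carriers,
                          ref_af = NA_real_, variant_type = "SNP",
                          consequence = "missense", sift = "damaging",
                          polyphen = "probably_damaging") {
  data.frame(variant_id = variant_id, gene = gene,
             variant_type = variant_type, consequence = consequence,
             allele_count = allele_count, carriers = carriers,
             ref_af = ref_af, sift = sift, polyphen = polyphen,
             stringsAsFactors = FALSE)
}

# Five-sample toy cohort: geneA has 3 variants carried by {s1}, {s1,s2},
# {s3}; geneB one variant carried by {s4}.
toy_cohort <- function() {
  make_variants(
    variant_id = c("vA1", "vA2", "vA3", "vB1"),
    gene = c("geneA", "geneA", "geneA", "geneB"),
    allele_count = c(1, 2, 1, 1),
    carriers = c("s1", "s1,s2", "s3", "s4"),
    ref_af = c(0.001, 0.001, NA, 0.002)
  )
}

toy_samples <- paste0("s", 1:5)

# Unweighted path A - B - C as an interaction network.
path_network <- function(weights = c(1, 1)) {
  interaction_network(data.frame(a = c("A", "B"), b = c("B", "C"),
                                 w = weights))
}

# Dense linear-solve oracle for the propagation fixed point:
# f = (1 - alpha) * (I - alpha * W)^(-1) s, with s normalized to sum 1.
propagate_oracle <- function(network, seeds, alpha = 0.5,
                             normalization = "symmetric") {
  w <- as.matrix(normalize_network(network, normalization))
  s <- numeric(nrow(w))
  names(s) <- rownames(w)
  s[names(seeds)] <- seeds
  s <- s / sum(s)
  f <- solve(diag(nrow(w)) - alpha * w, (1 - alpha) * s)
  stats::setNames(as.numeric(f), rownames(w))
}

# Exhaustive enumeration oracle for the hypergeometric upper tail:
# probability that a random |query|-subset of the universe overlaps the
# annotation in at least `observed` genes. Feasible for |universe| <= 25.
hypergeom_oracle <- function(n_universe, n_set, n_query, observed) {
  draws <- utils::combn(n_universe, n_query)
  in_set <- draws <= n_set  # wlog annotation = first n_set elements
  mean(colSums(in_set) >= observed)
}

# Scaled-down synthetic study for fast tests; any sim_config() argument
# can be overridden.
small_sim_config <- function(...) {
  defaults <- list(n_samples = 120, n_genes = 150, n_disease_genes = 10,
                   edge_prob = 0.05, module_factor = 12, n_cell_types = 4,
                   cells_per_type = 12, set_size_range = c(10, 40),
                   n_gene_sets = 8, n_relevant_sets = 2, rng_seed = 1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
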
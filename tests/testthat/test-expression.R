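test_that("cell-type percentiles rank genes by mean expression with tie handling", {
  expr <- rbind(g1 = c(10, 10, 0, 0), g2 = c(5, 5, 1, 1),
                g3 = c(1, 1, 1, 1), g4 = c(0, 0, 1, 1))
  colnames(expr) <- paste0("c", 1:4)
  types <- c("T1", "T1", "T2", "T2")
  pct <- celltype_percentiles(expr, types)
  t1 <- pct[pct$cell_type == "T1", ]
  # hand-ranked T1 means: g1=10 > g2=5 > g3=1 > g4=0
  expect_equal(t1$percentile[match(c("g1", "g2", "g3", "g4"), t1$gene)],
               c(1, 2 / 3, 1 / 3, 0))
  # T2: g1=0 lowest alone; g2=g3=g4=1 tied at average rank 3 -> 2/3
  t2 <- pct[pct$cell_type == "T2", ]
  expect_equal(t2$percentile[t2$gene == "g1"], 0)
  expect_equal(unique(t2$percentile[t2$gene != "g1"]), 2 / 3)
  # all genes identical within a type -> all percentiles 0.5
  flat <- matrix(3, nrow = 4, ncol = 2,
                 dimnames = list(paste0("g", 1:4), c("c1", "c2")))
  pflat <- celltype_percentiles(flat, c("T1", "T1"))
  expect_true(all(pflat$percentile == 0.5))
})

test_that("percentiles are invariant to monotone transformation of expression", {
  set.seed(3)
  expr <- matrix(rpois(200, 5), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  types <- rep(c("A", "B"), each = 5)
  p1 <- celltype_percentiles(expr, types)
  p2 <- celltype_percentiles(2 * expr + 7, types)  # affine, monotone
  expect_equal(p1$percentile, p2$percentile)
})

test_that("gene-set comparison reports direction, BH-adjusted p and tiers", {
  # construct percentile tables directly: "hair" separates the two gene
  # groups completely, "dark" gives both groups the same distribution
  hi <- paste0("g", 1:20)
  lo <- paste0("g", 21:40)
  pct <- data.frame(
    gene = rep(paste0("g", 1:40), 2),
    cell_type = rep(c("hair", "dark"), each = 40),
    mean_expression = 1,
    percentile = c(seq(0.6, 1, length.out = 20),
                   seq(0, 0.4, length.out = 20),
                   rep(seq(0.05, 0.95, length.out = 20), 2))
  )
  res <- compare_gene_sets(pct, hi, lo)
  hair <- res[res$cell_type == "hair", ]
  expect_lt(hair$p_adj, 0.001)
  expect_identical(hair$tier, "***")
  expect_equal(hair$median_diff, 0.6)
  dark <- res[res$cell_type == "dark", ]
  expect_identical(dark$tier, "ns")
  expect_equal(dark$median_diff, 0)
  # identical sets: no difference, not significant
  same <- compare_gene_sets(pct, hi, hi)
  expect_true(all(same$median_diff == 0))
  expect_true(all(same$p_adj > 0.05))
  # swapping the sets flips the direction, same p
  swapped <- compare_gene_sets(pct, lo, hi)
  expect_equal(swapped$median_diff, -res$median_diff)
  expect_equal(swapped$p, res$p)
  # tiny sets are skipped with NA (one warning per cell type)
  w <- testthat::capture_warnings(
    small <- compare_gene_sets(pct, hi[1:2], lo))
  expect_match(w, "skipped", all = TRUE)
  expect_true(all(is.na(small$p)))
})

test_that("upregulated cell types attain the smallest adjusted p (planted atlas)", {
  set.seed(47)
  wins <- replicate(100, {
    # full-size atlas structure (8 cell types, 30 cells each, 2 planted),
    # reduced gene universe for speed; a 4-fold planted shift so the
    # upregulation is unambiguous relative to the baseline spread of a
    # 20-gene set
    cfg <- sim_config(n_genes = 300, n_disease_genes = 20, n_samples = 50,
                      expression_effect_size = 3,
                      rng_seed = sample.int(1e6, 1))
    co <- simulate_cohort(cfg)
    ex <- simulate_expression(cfg, co$truth)
    pct <- celltype_percentiles(ex$expr, ex$cell_types)
    res <- compare_gene_sets(pct, co$truth$disease_genes, co$truth$genes)
    up <- ex$upregulated_cell_types
    ranked <- res$cell_type[order(res$p_adj)]
    setequal(ranked[seq_along(up)], up)
  })
  expect_gte(mean(wins), 0.95)
})

test_that("a zero effect size yields no significant cell types (type-I calibration)", {
  set.seed(53)
  clean <- replicate(100, {
    cfg <- small_sim_config(expression_effect_size = 0,
                            rng_seed = sample.int(1e6, 1))
    co <- simulate_cohort(cfg)
    ex <- simulate_expression(cfg, co$truth)
    pct <- celltype_percentiles(ex$expr, ex$cell_types)
    res <- compare_gene_sets(pct, co$truth$disease_genes, co$truth$genes)
    all(res$p_adj > 0.05, na.rm = TRUE)
  })
  expect_gte(mean(clean), 0.90)
})

test_that("relative expression min-max scales cell-type means per gene", {
  expr <- rbind(g1 = c(0, 0, 10, 10), g2 = c(4, 4, 4, 4))
  colnames(expr) <- paste0("c", 1:4)
  rel <- relative_expression(expr, c("A", "A", "B", "B"))
  expect_equal(unname(rel["g1", c("A", "B")]), c(0, 1))
  expect_equal(unname(rel["g2", c("A", "B")]), c(0, 0))  # flat gene
})

test_that("expression matrices round-trip through MTX and TSV with labels", {
  set.seed(59)
  expr <- matrix(rpois(60, 2), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
  dir <- withr::local_tempdir()
  mtx <- file.path(dir, "expr.mtx")
  Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), mtx)
  writeLines(rownames(expr), file.path(dir, "genes.txt"))
  writeLines(colnames(expr), file.path(dir, "cells.txt"))
  back <- read_expression(mtx, file.path(dir, "genes.txt"),
                          file.path(dir, "cells.txt"))
  expect_equal(as.matrix(back), expr, ignore_attr = TRUE)
  expect_identical(dimnames(back), dimnames(expr))
  labels <- data.frame(cell = colnames(expr),
                       cell_type = rep(c("A", "B"), 3))
  lab_path <- file.path(dir, "labels.tsv")
  utils::write.table(labels, lab_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_identical(read_cell_labels(lab_path),
                   stats::setNames(labels$cell_type, labels$cell))
})
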
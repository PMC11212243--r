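test_that("cohort allele frequency follows the diploid AC/(2N) convention", {
  expect_equal(round(100 * cohort_allele_frequency(52, 511), 1), 5.1)
  expect_equal(cohort_allele_frequency(0, 511), 0)
  expect_equal(cohort_allele_frequency(1022, 511), 1)
  expect_error(cohort_allele_frequency(1023, 511), "invalid genotype")
  expect_error(cohort_allele_frequency(-1, 511), "non-negative")
})

test_that("rare/damaging filter removes common, benign and non-protein-altering variants", {
  v <- make_variants(
    variant_id = paste0("v", 1:6), gene = paste0("g", 1:6),
    allele_count = rep(2, 6), carriers = rep("s1,s2", 6),
    ref_af = c(0.06, 0.0, 0.05, 0.01, 0.01, 0.01),
    consequence = c("missense", "missense", "missense", "missense",
                    "missense", "other"),
    sift = c("damaging", "damaging", "damaging", "benign", "damaging",
             "damaging"),
    polyphen = c("probably_damaging", "probably_damaging",
                 "probably_damaging", "probably_damaging", "benign",
                 "probably_damaging")
  )
  out <- filter_rare_damaging(v)
  # common (>5%) out; exactly 5% retained (strict >); benign by EITHER
  # predictor out; non-protein-altering out
  expect_identical(out$variant_id, c("v2", "v3"))
  # order preserved and idempotent
  expect_identical(filter_rare_damaging(out), out)
})

test_that("rare filter takes the maximum frequency across reference panels", {
  v <- make_variants(variant_id = c("v1", "v2"), gene = c("g1", "g2"),
                     allele_count = c(1, 1), carriers = c("s1", "s1"),
                     ref_af = c(0.01, 0.01))
  v$exac_af <- c(0.2, 0.01)
  cfg <- filter_config(extra_panel_cols = "exac_af")
  expect_identical(filter_rare_damaging(v, cfg)$variant_id, "v2")
})

test_that("missing and unknown consequence annotations are handled", {
  v <- make_variants("v1", "g1", 1, "s1", 0.01, consequence = NA)
  expect_error(filter_rare_damaging(v), "v1")
  v2 <- make_variants("v2", "g1", 1, "s1", 0.01,
                      consequence = "stop_gained_weird")
  expect_warning(out <- validate_variants(v2), "other")
  expect_identical(out$consequence, "other")
})

test_that("UFV filter keeps novel variants and fold-over-expectation exceedances", {
  n <- 511
  v <- make_variants(
    variant_id = paste0("v", 1:4), gene = paste0("g", 1:4),
    allele_count = c(52, 52, 40, 3),
    carriers = c(strrep("s,", 51) |> paste0("x"),
                 strrep("s,", 51) |> paste0("x"),
                 strrep("s,", 39) |> paste0("x"), "s1,s2,s3"),
    ref_af = c(0.039, 52 / 1022, NA, 0.01)
  )
  out <- ufv_filter(v, n)
  # 5.1%/3.9% ~ 1.30 > 1.3 retained; ratio exactly 1 removed; novel
  # retained; 3/1022 / 0.01 = 0.29 removed
  expect_identical(out$variant_id, c("v1", "v3"))
  expect_identical(ufv_filter(out, n), out)
})

test_that("ref_af of zero without a novel flag is treated as novel with a warning", {
  v <- make_variants("v1", "g1", 2, "s1,s2", ref_af = 0)
  expect_warning(out <- ufv_filter(v, 100), "novel")
  expect_equal(nrow(out), 1L)
})

test_that("UFV filter limits: ratio_min 0 keeps everything, ratio_min Inf keeps only novels", {
  v <- make_variants(variant_id = paste0("v", 1:3), gene = paste0("g", 1:3),
                     allele_count = c(5, 5, 5),
                     carriers = rep("s1,s2,s3,s4,s5", 3),
                     ref_af = c(0.001, 0.02, NA))
  expect_equal(nrow(ufv_filter(v, 50, filter_config(ratio_min = 0))), 3L)
  out <- ufv_filter(v, 50, filter_config(ratio_min = Inf))
  expect_identical(out$variant_id, "v3")
})

test_that("binomial variant-level p-value matches exhaustive tail enumeration", {
  expect_equal(variant_count_pvalue(0, 511, 0.039), 1.0)
  expect_equal(variant_count_pvalue(10, 5, 0.5), 0.5^10)
  # enumerate P(X >= 3) for X ~ Bin(10, 0.1) term by term
  manual <- sum(vapply(3:10, function(k)
    choose(10, k) * 0.1^k * 0.9^(10 - k), numeric(1)))
  expect_equal(variant_count_pvalue(3, 5, 0.1), manual, tolerance = 1e-12)
  expect_error(variant_count_pvalue(3, 5, 0), "\\(0, 1\\)")
  expect_error(variant_count_pvalue(3, 5, 1), "\\(0, 1\\)")
})

test_that("filter summary reproduces stage counts, percentages and category tallies", {
  n_rd <- 16790L
  n_ufv <- 11209L
  all_v <- make_variants(variant_id = sprintf("v%05d", seq_len(n_rd)),
                         gene = "g1", allele_count = 1, carriers = "s1",
                         ref_af = NA)
  s <- summarize_filtering(all_v, all_v, all_v[seq_len(n_ufv), ])
  expect_equal(s$pct_ufv, 66.8)
  expect_equal(s$n_input, n_rd)
  expect_equal(s$n_ufv, n_ufv)

  toy <- make_variants(variant_id = c("a", "b"), gene = c("g1", "g2"),
                       allele_count = c(1, 1), carriers = c("s1", "s2"),
                       ref_af = NA,
                       variant_type = c("SNP", "DEL"),
                       consequence = c("missense", "frameshift_del"))
  s2 <- summarize_filtering(toy, toy, toy)
  expect_equal(s2$counts_by_type$SNP, 1L)
  expect_equal(s2$counts_by_type$DEL, 1L)
  expect_equal(sum(unlist(s2$counts_by_type)), s2$n_ufv)
  expect_equal(sum(unlist(s2$counts_by_consequence)), s2$n_ufv)

  s3 <- summarize_filtering(toy, toy, toy[0, ])
  expect_equal(s3$n_ufv, 0L)
  expect_equal(s3$pct_ufv, 0)
  expect_error(summarize_filtering(toy[1, ], toy, toy), "subsets")
})

test_that("carrier/allele-count diploid invariant is enforced", {
  bad <- make_variants("v1", "g1", allele_count = 5, carriers = "s1,s2",
                       ref_af = 0.01)
  expect_error(validate_variants(bad), "invalid genotype")
  bad2 <- make_variants("v2", "g1", allele_count = 1, carriers = "s1,s2",
                        ref_af = 0.01)
  expect_error(validate_variants(bad2), "invalid genotype")
})

test_that("planted disease-gene variants are retained as UFVs more often than background", {
  # Monte Carlo over 100 small cohorts at planting fold 2
  set.seed(42)
  hits <- replicate(100, {
    cfg <- small_sim_config(rng_seed = sample.int(1e6, 1))
    sim <- simulate_cohort(cfg)
    rd <- suppressWarnings(filter_rare_damaging(sim$variants))
    ufv <- suppressWarnings(ufv_filter(rd, cfg$n_samples))
    dis <- rd$gene %in% sim$truth$disease_genes
    kept <- rd$variant_id %in% ufv$variant_id
    c(p_dis = mean(kept[dis]), p_bg = mean(kept[!dis]))
  })
  expect_gt(mean(hits["p_dis", ], na.rm = TRUE),
            mean(hits["p_bg", ], na.rm = TRUE))
})
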
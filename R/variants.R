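#' Consequence and variant-type vocabularies
#'
#' Fixed controlled vocabularies for the cohort variant table. Consequences
#' other than `"other"` are considered protein-altering; unknown strings are
#' mapped to `"other"` with a warning.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
CONSEQUENCES <- c(
  "missense", "nonsense", "frameshift_del", "frameshift_ins",
  "inframe_del", "inframe_ins", "nonstop", "splice_site", "other"
)

#' @rdname vocabularies
#' @export
VARIANT_TYPES <- c("SNP", "DEL", "INS")

PROTEIN_ALTERING <- setdiff(CONSEQUENCES, "other")

#' Filtering configuration
#'
#' Thresholds for reducing an annotated cohort variant table to rare,
#' damaging, protein-altering, unusually frequent variants (UFVs).
#'
#' @param common_af_max Variants with a reference-population allele frequency
#'   strictly above this value in any supplied panel are removed as common.
#'   Default 0.05.
#' @param ratio_min A variant is unusually frequent when its cohort allele
#'   frequency exceeds `ratio_min` times its expected (reference) frequency.
#'   Strict inequality; default 1.3.
#' @param keep_protein_altering_only Drop variants whose consequence is
#'   `"other"` (non-protein-altering). Default `TRUE`.
#' @param benign_predictors Column names of deleteriousness predictors; a
#'   variant labelled `"benign"` by ANY of them is removed. Default
#'   `c("sift", "polyphen")`.
#' @param extra_panel_cols Optional additional reference-panel allele-frequency
#'   columns; the common-variant filter uses the maximum frequency across
#'   `ref_af` and these columns, while the fold-over-expectation filter uses
#'   `ref_af` alone (the designated expected panel).
#' @return An object of class `"filter_config"`.
#' @export
filter_config <- function(common_af_max = 0.05, ratio_min = 1.3,
                          keep_protein_altering_only = TRUE,
                          benign_predictors = c("sift", "polyphen"),
                          extra_panel_cols = character()) {
  stopifnot(is.numeric(common_af_max), length(common_af_max) == 1L,
            common_af_max > 0, common_af_max <= 1,
            is.numeric(ratio_min), length(ratio_min) == 1L, ratio_min >= 0)
  structure(
    list(common_af_max = common_af_max, ratio_min = ratio_min,
         keep_protein_altering_only = isTRUE(keep_protein_altering_only),
         benign_predictors = as.character(benign_predictors),
         extra_panel_cols = as.character(extra_panel_cols)),
    class = "filter_config"
  )
}

#' Cohort allele frequency under the diploid convention
#'
#' Allele frequency of a variant in a cohort of diploid individuals:
#' `allele_count / (2 * n_samples)`.
#'
#' @param allele_count Non-negative integer count of alternate alleles
#'   observed in the cohort (vectorized).
#' @param n_samples Number of diploid individuals in the cohort.
#' @return Numeric allele frequency in `[0, 1]`.
#' @examples
#' cohort_allele_frequency(52, 511)   # ~0.0509, i.e. 5.1%
#' @export
cohort_allele_frequency <- function(allele_count, n_samples) {
  if (length(n_samples) != 1L || !is.numeric(n_samples) || n_samples <= 0)
    stop("`n_samples` must be a single positive number")
  allele_count <- as.numeric(allele_count)
  if (any(is.na(allele_count)) || any(allele_count < 0))
    stop("`allele_count` must be non-negative")
  if (any(allele_count > 2 * n_samples))
    stop("invalid genotype: allele_count exceeds 2 * n_samples")
  allele_count / (2 * n_samples)
}

normalize_consequence <- function(consequence, variant_id = NULL) {
  consequence <- as.character(consequence)
  missing <- is.na(consequence) | consequence == ""
  if (any(missing)) {
    ids <- if (is.null(variant_id)) which(missing) else variant_id[missing]
    stop("missing consequence annotation for variant(s): ",
         paste(utils::head(ids, 5L), collapse = ", "))
  }
  unknown <- !(consequence %in% CONSEQUENCES)
  if (any(unknown)) {
    warning(sum(unknown), " unknown consequence value(s) mapped to \"other\": ",
            paste(utils::head(unique(consequence[unknown]), 5L), collapse = ", "))
    consequence[unknown] <- "other"
  }
  consequence
}

#' Validate a cohort variant table
#'
#' Checks the tab-separated variant-table dialect: required columns, the
#' diploid carrier invariant `n_carriers <= allele_count <= 2 * n_carriers`,
#' and the consequence vocabulary (unknown values mapped to `"other"`).
#' `ref_af` equal to `NA` (empty field) flags a novel variant.
#'
#' @param variants A `data.frame` with columns `variant_id`, `gene`,
#'   `variant_type`, `consequence`, `allele_count`, `carriers`
#'   (comma-joined sample ids), `ref_af`, plus one column per predictor.
#' @return The validated (possibly consequence-normalized) `data.frame`.
#' @export
validate_variants <- function(variants) {
  required <- c("variant_id", "gene", "variant_type", "consequence",
                "allele_count", "carriers", "ref_af")
  miss <- setdiff(required, names(variants))
  if (length(miss))
    stop("variant table lacks required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(variants$variant_id))
    stop("duplicated variant_id values in variant table")
  variants$consequence <- normalize_consequence(variants$consequence,
                                                variants$variant_id)
  nc <- carrier_counts(variants$carriers)
  ac <- variants$allele_count
  bad <- !is.na(ac) & (ac < nc | ac > 2 * nc)
  if (any(bad))
    stop("invalid genotype (carrier/allele-count mismatch) for variant(s): ",
         paste(utils::head(variants$variant_id[bad], 5L), collapse = ", "))
  variants
}

carrier_counts <- function(carriers) {
  vapply(parse_carriers(carriers), length, integer(1))
}

parse_carriers <- function(carriers) {
  out <- strsplit(as.character(carriers), ",", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}

#' Remove common, benign, and non-protein-altering variants
#'
#' The rare/damaging reduction: removes variants whose maximum
#' reference-panel allele frequency is strictly above
#' `config$common_af_max`, variants labelled `"benign"` by any configured
#' predictor, and (optionally) variants whose consequence is not
#' protein-altering. Input order is preserved and the operation is
#' idempotent. Novel variants (`ref_af` absent) pass the rarity filter.
#'
#' @param variants Validated variant table (see [validate_variants()]).
#' @param config A [filter_config()].
#' @return The filtered variant table.
#' @export
filter_rare_damaging <- function(variants, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  variants <- validate_variants(variants)
  af_cols <- c("ref_af", intersect(config$extra_panel_cols, names(variants)))
  af <- as.matrix(variants[, af_cols, drop = FALSE])
  max_af <- suppressWarnings(apply(af, 1L, max, na.rm = TRUE))
  max_af[!is.finite(max_af)] <- NA_real_  # all panels absent: novel
  keep <- is.na(max_af) | max_af <= config$common_af_max
  for (pred in intersect(config$benign_predictors, names(variants))) {
    lab <- tolower(as.character(variants[[pred]]))
    keep <- keep & !(!is.na(lab) & lab == "benign")
  }
  if (config$keep_protein_altering_only)
    keep <- keep & variants$consequence %in% PROTEIN_ALTERING
  variants[keep, , drop = FALSE]
}

#' Retain unusually frequent variants (UFVs)
#'
#' Keeps a variant when it is novel (`ref_af` absent) or when its cohort
#' allele frequency exceeds `ratio_min` times its reference frequency
#' (strict inequality). A `ref_af` of exactly 0 that is not flagged novel is
#' treated as novel with a warning. Idempotent on its own output.
#'
#' @inheritParams filter_rare_damaging
#' @param n_samples Number of diploid individuals in the cohort.
#' @return The UFV subset of `variants`, order preserved.
#' @export
ufv_filter <- function(variants, n_samples, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  variants <- validate_variants(variants)
  af <- cohort_allele_frequency(variants$allele_count, n_samples)
  ref <- variants$ref_af
  zero_ref <- !is.na(ref) & ref == 0
  if (any(zero_ref)) {
    warning(sum(zero_ref),
            " variant(s) with ref_af = 0 not flagged novel; treated as novel")
    ref[zero_ref] <- NA_real_
  }
  keep <- is.na(ref) | af / ref > config$ratio_min
  variants[keep, , drop = FALSE]
}

#' Observed-over-expected frequency ratio per variant
#'
#' @inheritParams ufv_filter
#' @return Numeric vector of `cohort AF / ref_af`; `NA` for novel variants.
#' @export
obs_exp_ratio <- function(variants, n_samples) {
  af <- cohort_allele_frequency(variants$allele_count, n_samples)
  ifelse(is.na(variants$ref_af) | variants$ref_af == 0, NA_real_,
         af / variants$ref_af)
}

#' Binomial variant-level p-value (rejected comparator filter)
#'
#' Upper-tail probability of observing at least `allele_count` alternate
#' alleles among `2 * n_samples` chromosomes when the per-chromosome success
#' probability is the reference allele frequency. This is the variant-level
#' alternative to the fold-over-expectation filter; it is provided for
#' comparison because the fold filter recovers relevant phenotype
#' annotations better in practice.
#'
#' @inheritParams cohort_allele_frequency
#' @param ref_af Reference-population allele frequency, strictly in (0, 1).
#' @return Upper-tail binomial probability `P(X >= allele_count)`.
#' @export
variant_count_pvalue <- function(allele_count, n_samples, ref_af) {
  if (any(is.na(ref_af)) || any(ref_af <= 0) || any(ref_af >= 1))
    stop("`ref_af` must be strictly inside (0, 1)")
  if (any(allele_count < 0) || any(allele_count > 2 * n_samples))
    stop("invalid genotype: allele_count outside [0, 2 * n_samples]")
  stats::pbinom(allele_count - 1, size = 2 * n_samples, prob = ref_af,
                lower.tail = FALSE)
}

#' Summarize the filtering cascade
#'
#' Counts at each stage of the reduction (input, rare/damaging, UFV), the
#' UFV percentage of the rare/damaging set (one decimal), and UFV category
#' tallies by variant type and consequence.
#'
#' @param variants_in Full input variant table.
#' @param variants_rare_damaging Output of [filter_rare_damaging()].
#' @param variants_ufv Output of [ufv_filter()].
#' @return An object of class `"filter_summary"`.
#' @export
summarize_filtering <- function(variants_in, variants_rare_damaging,
                                variants_ufv) {
  if (!all(variants_rare_damaging$variant_id %in% variants_in$variant_id) ||
      !all(variants_ufv$variant_id %in% variants_rare_damaging$variant_id))
    stop("inconsistent inputs: filtering stages must be successive subsets")
  n_in <- nrow(variants_in)
  n_rd <- nrow(variants_rare_damaging)
  n_ufv <- nrow(variants_ufv)
  pct <- if (n_rd > 0) round(100 * n_ufv / n_rd, 1) else 0
  by_type <- table(factor(variants_ufv$variant_type, levels = VARIANT_TYPES))
  by_csq <- table(factor(variants_ufv$consequence, levels = CONSEQUENCES))
  structure(
    list(n_input = n_in, n_after_rare_damaging = n_rd, n_ufv = n_ufv,
         pct_ufv = pct,
         counts_by_type = as.list(as.integer(by_type)) |>
           stats::setNames(names(by_type)),
         counts_by_consequence = as.list(as.integer(by_csq)) |>
           stats::setNames(names(by_csq))),
    class = "filter_summary"
  )
}

#' @method print filter_summary
#' @export
print.filter_summary <- function(x, ...) {
  cat("Variant filtering summary\n")
  cat(sprintf("  input variants:        %d\n", x$n_input))
  cat(sprintf("  rare damaging:         %d\n", x$n_after_rare_damaging))
  cat(sprintf("  unusually frequent:    %d (%.1f%%)\n", x$n_ufv, x$pct_ufv))
  ty <- unlist(x$counts_by_type)
  cat("  by type:        ", paste(names(ty), ty, sep = "=", collapse = "  "), "\n")
  cs <- unlist(x$counts_by_consequence)
  cs <- cs[cs > 0]
  if (length(cs))
    cat("  by consequence: ", paste(names(cs), cs, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Read / write the cohort variant table
#'
#' Tab-separated dialect with columns `variant_id`, `gene`, `variant_type`,
#' `consequence`, `allele_count`, `carriers` (comma-joined sample ids),
#' `ref_af` (empty = novel), and one column per deleteriousness predictor.
#'
#' @param path File path.
#' @return `read_variants()` returns the validated `data.frame`.
#' @export
read_variants <- function(path) {
  variants <- utils::read.delim(path, stringsAsFactors = FALSE,
                                colClasses = c(carriers = "character"),
                                na.strings = c("NA", ""))
  variants$carriers[is.na(variants$carriers)] <- ""
  validate_variants(variants)
}

#' @rdname read_variants
#' @param variants Variant table to write.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
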
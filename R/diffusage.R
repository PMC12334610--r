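#' Two-sided exact test of a 2x2 table
#'
#' Fisher's exact test by the point-probability method: with all margins
#' fixed, the p-value is the sum of hypergeometric point probabilities not
#' exceeding that of the observed table (a small relative tolerance absorbs
#' floating-point ties, as in [stats::fisher.test()]).
#'
#' @param a,b,c,d Cell counts of the table `[[a, b], [c, d]]` (rows =
#'   alleles, columns = isoform / rest).
#' @return The two-sided p-value.
#' @export
exact_test_2x2 <- function(a, b, c, d) {
  m <- a + c          # column 1 (isoform) total
  n <- b + d          # column 2 (rest) total
  k <- a + b          # row 1 (allele 1) total
  support <- max(0L, k - n):min(k, m)
  pmf <- stats::dhyper(support, m, n, k)
  p_obs <- pmf[support == a]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}

#' Per-isoform exact tests between the two alleles
#'
#' For each isoform i, forms the 2x2 table
#' `[count(i, allele1), rest(allele1); count(i, allele2), rest(allele2)]`
#' and computes the two-sided exact p-value. Isoforms with zero counts in
#' both alleles are uninformative and excluded.
#'
#' @param counts A matrix or data.frame with one row per isoform and two
#'   columns (allele 1, allele 2) of raw read counts; row names are isoform
#'   labels.
#' @return A named numeric vector of p-values (one per tested isoform).
#'   Errors when either allele has zero total reads.
#' @export
per_isoform_exact_test <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L) stop("counts must have exactly two allele columns")
  tot <- colSums(counts)
  if (any(tot < 1)) stop("both alleles need at least one assigned read")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  p <- vapply(seq_len(nrow(counts)), function(i) {
    exact_test_2x2(counts[i, 1], tot[1] - counts[i, 1],
                   counts[i, 2], tot[2] - counts[i, 2])
  }, numeric(1))
  names(p) <- rownames(counts)
  p
}

#' Summarize one variant-site pair
#'
#' One output row per (splicing variant, allele-informative site or
#' haplotype) pair: per-allele coverage at the site and the minimum
#' per-isoform p-value, uncorrected.
#'
#' @param variant_id Splicing-variant identifier.
#' @param site_id Informative SNV or haplotype-block identifier.
#' @param pvalues Per-isoform p-values from [per_isoform_exact_test()].
#' @param partition The pair's `allele_partition`.
#' @param haplotype_info Free-text phasing summary (empty when the pair is
#'   a single-SNV separation).
#' @return A one-row data.frame (`diff_usage_record`).
#' @export
summarize_pair <- function(variant_id, site_id, pvalues, partition,
                           haplotype_info = "") {
  if (!length(pvalues)) stop("no per-isoform p-values to summarize")
  data.frame(
    splicing_variant = variant_id,
    allele_informative_site = site_id,
    ref_coverage = length(partition$ref_read_ids),
    alt_coverage = length(partition$alt_read_ids),
    min_p = min(pvalues),
    corrected_p = NA_real_,
    haplotype_info = haplotype_info,
    stringsAsFactors = FALSE
  )
}

#' Bonferroni correction across tested splicing variants
#'
#' `corrected_p = min(1, min_p * n_variants_tested)`, where the denominator
#' is the number of unique splicing variants that reached the test stage
#' (every pair of one variant inherits the same denominator). A variant is
#' significant when any of its pairs has `corrected_p < alpha`.
#'
#' @param records Data.frame of pair records from [summarize_pair()].
#' @param n_variants_tested Number of unique splicing variants tested
#'   (>= 1). With `pairs_level = TRUE` the number of pairs is used instead.
#' @param alpha Family-wise significance level (default 0.05).
#' @param pairs_level Correct over pairs rather than unique variants.
#' @return `records` with `corrected_p` filled and a logical `significant`
#'   column added.
#' @export
bonferroni_correct <- function(records, n_variants_tested, alpha = 0.05,
                               pairs_level = FALSE) {
  if (pairs_level) n_variants_tested <- nrow(records)
  if (n_variants_tested < 1) {
    stop("n_variants_tested must be at least 1")
  }
  records$corrected_p <- pmin(1, records$min_p * n_variants_tested)
  records$significant <- records$corrected_p < alpha
  records
}
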
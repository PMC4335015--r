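#' Theoretical per-sample coverage of a region
#'
#' `(reads * bp_per_read_pair) / (n_samples * region_size)`: aligned read
#' pairs carrying an average `bp_per_read_pair` of aligned sequence
#' (75 bp per end by default convention), spread over `n_samples`
#' libraries and a region of `region_size` bp.
#'
#' @param reads Aligned read count for the region.
#' @param bp_per_read_pair Aligned bp per read pair (default 150).
#' @param n_samples Number of multiplexed libraries.
#' @param region_size Region size in bp.
#' @return Fold coverage (full precision; see [capture_summary()] for the
#'   reporting conventions).
#' @examples
#' theoretical_coverage(699823384, 150, 54, 2.43e9)  # ~0.80x genome-wide
#' @export
theoretical_coverage <- function(reads, bp_per_read_pair = 150, n_samples,
                                 region_size) {
  if (any(c(reads, bp_per_read_pair, n_samples, region_size) <= 0)) {
    abort("all coverage inputs must be positive", class = "sweepwatch_error")
  }
  (reads * bp_per_read_pair) / (n_samples * region_size)
}

#' Fold enrichment of target over reference coverage
#'
#' Ratio of unrounded coverages; rounding happens only at report time.
#'
#' @param cov_target,cov_reference Fold coverages from
#'   [theoretical_coverage()].
#' @return Fold enrichment.
#' @export
enrichment <- function(cov_target, cov_reference) {
  if (any(cov_reference <= 0)) {
    abort("reference coverage must be positive", class = "sweepwatch_error")
  }
  cov_target / cov_reference
}

#' Capture-experiment coverage and enrichment summary
#'
#' Tabulates theoretical per-sample coverage for the whole reference, the
#' total capture target and its repeat-masked subset, plus fold enrichment
#' of each target row over the reference. Numeric columns are full
#' precision; `*_trunc` truncates towards zero and `*_round` rounds to the
#' nearest unit (two decimals for values below 1), since published
#' summaries mix the two conventions.
#'
#' @param reference_size_bp,target_size_bp,target_masked_size_bp Region
#'   sizes in bp.
#' @param aligned_reads_total,aligned_reads_target,aligned_reads_target_masked
#'   Aligned read counts per region.
#' @param n_samples Number of libraries.
#' @param bp_per_read_pair Aligned bp per read pair (default 150).
#' @return A tibble with one row per region (`reference`, `target_total`,
#'   `target_masked`): `size_bp`, `aligned_reads`, `coverage`,
#'   `coverage_trunc`, `coverage_round`, `enrichment`, `enrichment_trunc`,
#'   `enrichment_round` (enrichment `NA` on the reference row).
#' @export
capture_summary <- function(reference_size_bp, target_size_bp,
                            target_masked_size_bp, aligned_reads_total,
                            aligned_reads_target, aligned_reads_target_masked,
                            n_samples, bp_per_read_pair = 150) {
  if (target_size_bp > reference_size_bp ||
      target_masked_size_bp > target_size_bp) {
    abort("target sizes must satisfy masked <= total <= reference",
          class = "sweepwatch_error")
  }
  sizes <- c(reference_size_bp, target_size_bp, target_masked_size_bp)
  reads <- c(aligned_reads_total, aligned_reads_target,
             aligned_reads_target_masked)
  cov <- theoretical_coverage(reads, bp_per_read_pair, n_samples, sizes)
  enr <- c(NA_real_, enrichment(cov[2:3], cov[1]))
  digits <- ifelse(abs(cov) < 1, 2L, 0L)
  edigits <- ifelse(is.na(enr) | abs(enr) >= 1, 0L, 2L)
  tibble(
    region = c("reference", "target_total", "target_masked"),
    size_bp = sizes, aligned_reads = reads,
    coverage = cov,
    coverage_trunc = trunc_at(cov, digits),
    coverage_round = round(cov, digits),
    enrichment = enr,
    enrichment_trunc = trunc_at(enr, edigits),
    enrichment_round = round(enr, edigits))
}
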
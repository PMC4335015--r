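#' Build a phenotype x genotype count table
#'
#' The shape of a melanism genotype table: two phenotype rows
#' (non-melanistic first, then melanistic) by three genotype columns
#' (homozygous ancestral, heterozygous, homozygous derived).
#'
#' @param non_melanistic,melanistic Length-3 integer vectors of counts
#'   `(hom_ancestral, het, hom_derived)`.
#' @param species Optional species label.
#' @param variant Optional [core_variant()].
#' @return A tibble of class `genotype_counts` with columns `phenotype`,
#'   `hom_ancestral`, `het`, `hom_derived`.
#' @examples
#' # pampas cat, ASIP R120C
#' genotype_counts(non_melanistic = c(2, 6, 0), melanistic = c(0, 0, 9))
#' @export
genotype_counts <- function(non_melanistic, melanistic, species = NULL,
                            variant = NULL) {
  stopifnot(length(non_melanistic) == 3, length(melanistic) == 3)
  m <- rbind(as.integer(non_melanistic), as.integer(melanistic))
  if (anyNA(m) || any(m < 0)) {
    abort("counts must be non-negative integers", class = "sweepwatch_error")
  }
  if (sum(m) == 0) abort("empty genotype table", class = "sweepwatch_error")
  out <- tibble(phenotype = c("non_melanistic", "melanistic"),
                hom_ancestral = m[, 1], het = m[, 2], hom_derived = m[, 3])
  structure(out, class = c("genotype_counts", class(out)),
            species = species, variant = variant)
}

counts_matrix <- function(t) {
  t <- as_tibble(t)
  m <- as.matrix(t[, c("hom_ancestral", "het", "hom_derived")])
  rownames(m) <- t$phenotype
  m
}

#' Derived (melanism) allele frequency from genotype counts
#'
#' `q = (2 * hom_derived + het) / (2 n)` over all individuals in the
#' table, regardless of phenotype. Rounding to two decimals is a reporting
#' concern (see [melanism_summary()]), never applied here.
#'
#' @param t A [genotype_counts()] table.
#' @return The allele frequency in `[0, 1]`.
#' @export
derived_allele_frequency <- function(t) {
  m <- counts_matrix(t)
  n <- sum(m)
  if (n == 0) abort("no individuals", class = "sweepwatch_error")
  (2 * sum(m[, "hom_derived"]) + sum(m[, "het"])) / (2 * n)
}

#' Hardy-Weinberg predicted phenotype frequency
#'
#' Under random mating with derived allele frequency `q`, the melanistic
#' phenotype frequency is `q^2` when melanism is recessive (ASIP
#' loss-of-function) and `1 - (1 - q)^2` when dominant (MC1R
#' gain-of-function).
#'
#' @param q Derived allele frequency in `[0, 1]`.
#' @param mode `"recessive"` or `"dominant"`.
#' @return Predicted phenotype frequency.
#' @export
predicted_phenotype_frequency <- function(q, mode = c("recessive", "dominant")) {
  mode <- match.arg(mode)
  if (any(q < 0 | q > 1)) abort("q must lie in [0, 1]", class = "sweepwatch_error")
  if (mode == "recessive") q^2 else 1 - (1 - q)^2
}

#' Genotype-phenotype association chi-square
#'
#' Uncorrected Pearson chi-square on the 2x2 obtained by collapsing the
#' genotype columns under the inheritance model: `hom_derived_vs_rest`
#' (recessive) or `carrier_vs_noncarrier` (dominant). No continuity
#' correction is applied; for a perfectly associated table (both
#' off-diagonal cells zero) the statistic equals the sample size `n`.
#'
#' @param t A [genotype_counts()] table.
#' @param collapse `"hom_derived_vs_rest"` or `"carrier_vs_noncarrier"`.
#' @return An object of class `assoc_test` with fields `chi2`, `dof`,
#'   `p_value`, `collapse_rule`, `table` (the collapsed 2x2). Use
#'   [tidy()]/[glance()] for tibble output.
#' @export
association_chi2 <- function(t, collapse = c("hom_derived_vs_rest",
                                             "carrier_vs_noncarrier")) {
  collapse <- match.arg(collapse)
  m <- counts_matrix(t)
  tab <- if (collapse == "hom_derived_vs_rest") {
    cbind(rest = m[, "hom_ancestral"] + m[, "het"],
          hom_derived = m[, "hom_derived"])
  } else {
    cbind(noncarrier = m[, "hom_ancestral"],
          carrier = m[, "het"] + m[, "hom_derived"])
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate table: a margin is zero", class = "sweepwatch_error")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(
    list(chi2 = unname(ct$statistic), dof = unname(ct$parameter),
         p_value = unname(ct$p.value),
         collapse_rule = sprintf("phenotype x {%s}",
                                 paste(colnames(tab), collapse = " vs ")),
         table = tab),
    class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("<assoc_test> chi2 = %.4g on %d df, p = %.3g (%s)\n",
              x$chi2, x$dof, x$p_value, x$collapse_rule))
  invisible(x)
}

#' @method tidy assoc_test
#' @export
tidy.assoc_test <- function(x, ...) {
  tibble(chi2 = x$chi2, dof = x$dof, p_value = x$p_value,
         collapse_rule = x$collapse_rule)
}

#' @method glance assoc_test
#' @export
glance.assoc_test <- function(x, ...) {
  tibble(chi2 = x$chi2, dof = x$dof, p_value = x$p_value, n = sum(x$table))
}

#' Tabulate genotypes at the core variant from phased calls
#'
#' Each individual's genotype is the count of derived alleles across its
#' two chromosomes; phenotype rows come from the metadata.
#'
#' @param hap A [hap_matrix()] with `<sample>_A`/`<sample>_B` chromosomes.
#' @param core A [core_variant()] present in `hap`.
#' @param meta Metadata tibble ([read_metadata()] layout) covering every
#'   sample in the matrix.
#' @return A [genotype_counts()] table.
#' @export
genotype_table_from_calls <- function(hap, core, meta) {
  i <- core_site_index(hap, core)
  samples <- sub("_[AB]$", "", chrom_ids(hap))
  missing <- setdiff(unique(samples), meta$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("sample(s) missing from metadata: %s",
                  paste(missing, collapse = ", ")),
          class = "sweepwatch_error")
  }
  derived <- as.integer(hap$geno[, i] == core$derived_allele_code)
  dosage <- tapply(derived, samples, sum)
  pheno <- setNames(meta$phenotype, meta$sample_id)[names(dosage)]
  cnt <- function(ph) {
    d <- dosage[pheno == ph]
    c(sum(d == 0), sum(d == 1), sum(d == 2))
  }
  genotype_counts(non_melanistic = cnt("non_melanistic"),
                  melanistic = cnt("melanistic"),
                  species = unique(meta$species)[1], variant = core)
}

#' Table-1-style association summary
#'
#' One row per table: observed genotype counts, derived allele frequency,
#' Hardy-Weinberg predicted phenotype frequency under the inheritance
#' mode, and the association chi-square. `*_rendered` columns carry the
#' two-decimal reporting convention; the numeric columns are exact.
#'
#' @param t A [genotype_counts()] table.
#' @param mode `"recessive"` or `"dominant"`; the collapse rule for the
#'   chi-square follows it (`hom_derived_vs_rest` / `carrier_vs_noncarrier`).
#' @param species Optional label (defaults to the table's attribute).
#' @return A one-row tibble.
#' @export
melanism_summary <- function(t, mode = c("recessive", "dominant"),
                             species = NULL) {
  mode <- match.arg(mode)
  m <- counts_matrix(t)
  q <- derived_allele_frequency(t)
  pred <- predicted_phenotype_frequency(q, mode)
  at <- association_chi2(t, collapse = if (mode == "recessive")
    "hom_derived_vs_rest" else "carrier_vs_noncarrier")
  tibble(
    species = species %||% attr(t, "species") %||% NA_character_,
    mode = mode, n = sum(m),
    nm_hom_ancestral = m["non_melanistic", "hom_ancestral"],
    nm_het = m["non_melanistic", "het"],
    nm_hom_derived = m["non_melanistic", "hom_derived"],
    mel_hom_ancestral = m["melanistic", "hom_ancestral"],
    mel_het = m["melanistic", "het"],
    mel_hom_derived = m["melanistic", "hom_derived"],
    allele_freq = q, allele_freq_rendered = fmt_freq(q),
    predicted_phenotype_freq = pred,
    predicted_phenotype_freq_rendered = fmt_freq(pred),
    chi2 = at$chi2, chi2_dof = at$dof, chi2_p = at$p_value)
}
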
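# Shared builders and independent brute-force oracles.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A tiny hap_matrix from a 0/1 matrix; positions default to 10, 20, 30, ...
make_hap <- function(geno, pos = NULL, chrom = "chrT", qual = NULL,
                     ids = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  m <- ncol(geno)
  pos <- pos %||% (10L * seq_len(m))
  ids <- ids %||% as.vector(rbind(
    sprintf("s%02d_A", seq_len(ceiling(nrow(geno) / 2))),
    sprintf("s%02d_B", seq_len(ceiling(nrow(geno) / 2)))))[seq_len(nrow(geno))]
  rownames(geno) <- ids
  ref <- rep(c("A", "C", "G", "T"), length.out = m)
  alt <- rep(c("G", "T", "A", "C"), length.out = m)
  hap_matrix(
    tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                   qual = qual %||% rep(NA_real_, m)),
    geno)
}

random_hap <- function(n, m, seed, maf = NULL) {
  set.seed(seed)
  p <- maf %||% runif(m, 0.05, 0.95)
  geno <- matrix(rbinom(n * m, 1L, rep(p, each = n)), nrow = n)
  make_hap(geno)
}

window_over <- function(hap, pad = 0) {
  tibble::tibble(chrom = hap$sites$chrom[1],
                 start = 0L,
                 end = max(hap$sites$pos) + pad)
}

# Brute-force nucleotide diversity: explicit double loop over pairs/sites.
oracle_pi <- function(geno, window_len) {
  n <- nrow(geno)
  total <- 0
  pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sum(geno[i, ] != geno[j, ])
      pairs <- pairs + 1
    }
  }
  total / pairs / window_len
}

# Brute-force EHH: count identical pairs over the inclusive core..target span.
oracle_ehh <- function(geno_class, col_core, col_target) {
  span <- seq(min(col_core, col_target), max(col_core, col_target))
  n <- nrow(geno_class)
  same <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (all(geno_class[i, span] == geno_class[j, span])) same <- same + 1
    }
  }
  same / choose(n, 2)
}

# Write a VCF from raw lines (for malformed-input tests).
write_vcf_lines <- function(body, samples = c("s1", "s2")) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "FORMAT",
            samples), collapse = "\t"))
  writeLines(c(header, body), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts, qual = "50") {
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS", "GT", gts), collapse = "\t")
}

write_meta_lines <- function(df) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path)
  path
}

write_bed_lines <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# Table 1 genotype counts (printed inputs used across tests).
pampas_counts <- function() genotype_counts(c(2, 6, 0), c(0, 0, 9), species = "pampas cat")
kodkod_counts <- function() genotype_counts(c(5, 6, 0), c(0, 0, 5), species = "kodkod")
geoffroys_counts <- function() genotype_counts(c(16, 0, 0), c(0, 7, 0), species = "Geoffroy's cat")
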
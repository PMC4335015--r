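#' Construct a phased haplotype matrix
#'
#' The central container of the package: a panel of phased chromosomes
#' (rows) typed at ordered biallelic SNPs (columns). Allele code 0 is the
#' reference allele, 1 the alternate. Each chromosome has a unique id;
#' chromosomes read from a VCF are labelled `<sample>_A` / `<sample>_B`.
#'
#' @param sites A data frame with one row per site and columns `chrom`,
#'   `pos` (1-based, as in VCF), `ref`, `alt` (single nucleotides) and
#'   optionally `qual` (non-negative or `NA`).
#' @param geno An integer matrix of 0/1 allele codes, one row per
#'   chromosome and one column per site, with unique rownames giving the
#'   chromosome ids.
#' @return An object of class `hap_matrix`.
#' @examples
#' sites <- tibble::tibble(chrom = "chr1", pos = c(100, 200),
#'                         ref = c("A", "C"), alt = c("G", "T"), qual = NA_real_)
#' geno <- matrix(c(0L, 1L, 1L, 0L), nrow = 2,
#'                dimnames = list(c("s1_A", "s1_B"), NULL))
#' hap_matrix(sites, geno)
#' @export
hap_matrix <- function(sites, geno) {
  sites <- as_tibble(sites)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites))) {
    abort("`sites` needs columns chrom, pos, ref, alt", class = "sweepwatch_error")
  }
  if (!"qual" %in% names(sites)) sites$qual <- NA_real_
  sites <- sites[, c("chrom", "pos", "ref", "alt", "qual")]
  sites$pos <- as.integer(sites$pos)
  if (!is.matrix(geno)) geno <- matrix(geno, nrow = NROW(geno))
  storage.mode(geno) <- "integer"
  if (ncol(geno) != nrow(sites)) {
    abort("`geno` must have one column per site", class = "sweepwatch_error")
  }
  if (nrow(sites) > 0) {
    if (any(sites$pos < 1L)) abort("positions must be >= 1", class = "sweepwatch_error")
    if (any(sites$ref == sites$alt)) {
      abort("ref and alt alleles must differ", class = "sweepwatch_error")
    }
    ord <- order(sites$chrom, sites$pos)
    if (!identical(ord, seq_len(nrow(sites)))) {
      abort("sites must be sorted by (chrom, pos)", class = "sweepwatch_error")
    }
    if (anyDuplicated(sites[, c("chrom", "pos")])) {
      abort("duplicate site positions", class = "sweepwatch_error")
    }
    if (anyNA(geno) || !all(geno %in% c(0L, 1L))) {
      abort("allele codes must be 0 or 1 with no missing entries",
            class = "sweepwatch_error")
    }
  }
  ids <- rownames(geno)
  if (nrow(geno) > 0 && (is.null(ids) || anyDuplicated(ids))) {
    abort("`geno` needs unique rownames (chromosome ids)", class = "sweepwatch_error")
  }
  structure(list(sites = sites, geno = geno), class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix> %d chromosomes x %d sites\n", n_chrom(x), n_sites(x)))
  if (n_sites(x) > 0) {
    cat(sprintf("  contig(s): %s; positions %d..%d\n",
                paste(unique(x$sites$chrom), collapse = ", "),
                min(x$sites$pos), max(x$sites$pos)))
  }
  cat("  chromosomes:", paste(head(chrom_ids(x), 6), collapse = ", "),
      if (n_chrom(x) > 6) "..." else "", "\n")
  invisible(x)
}

#' Dimensions and identifiers of a haplotype matrix
#'
#' @param hap A [hap_matrix()].
#' @return `n_chrom()`/`n_sites()` return integers; `chrom_ids()` a
#'   character vector; `sample_ids()` the unique sample names implied by
#'   `<sample>_A`/`<sample>_B` chromosome ids.
#' @export
n_chrom <- function(hap) nrow(hap$geno)

#' @rdname n_chrom
#' @export
n_sites <- function(hap) ncol(hap$geno)

#' @rdname n_chrom
#' @export
chrom_ids <- function(hap) rownames(hap$geno)

#' @rdname n_chrom
#' @export
sample_ids <- function(hap) unique(sub("_[AB]$", "", chrom_ids(hap)))

#' @method as_tibble hap_matrix
#' @export
as_tibble.hap_matrix <- function(x, ...) {
  if (n_sites(x) == 0) {
    return(tibble(chrom_id = character(), chrom = character(),
                  pos = integer(), allele = integer()))
  }
  tibble(
    chrom_id = rep(chrom_ids(x), times = n_sites(x)),
    chrom = rep(x$sites$chrom, each = n_chrom(x)),
    pos = rep(x$sites$pos, each = n_chrom(x)),
    allele = as.integer(x$geno)
  )
}

#' Subset a haplotype matrix
#'
#' @param hap A [hap_matrix()].
#' @param chroms Chromosome ids (character) or indices to keep.
#' @param sites Site indices to keep (kept in their original order).
#' @return A [hap_matrix()].
#' @export
hap_subset <- function(hap, chroms = NULL, sites = NULL) {
  geno <- hap$geno
  st <- hap$sites
  if (!is.null(sites)) {
    sites <- sort(unique(as.integer(sites)))
    st <- st[sites, , drop = FALSE]
    geno <- geno[, sites, drop = FALSE]
  }
  if (!is.null(chroms)) {
    if (is.character(chroms)) {
      missing <- setdiff(chroms, rownames(geno))
      if (length(missing) > 0) {
        abort(paste0("unknown chromosome id(s): ", paste(missing, collapse = ", ")),
              class = "sweepwatch_error")
      }
    }
    geno <- geno[chroms, , drop = FALSE]
  }
  hap_matrix(st, geno)
}

#' Indices of sites falling in a window
#'
#' Windows use the 0-based half-open convention (as in BED), site positions
#' the 1-based VCF convention; a site at `pos` lies in `[start, end)` when
#' `start < pos <= end`.
#'
#' @param hap A [hap_matrix()].
#' @param chrom Contig of the window.
#' @param start,end Window bounds, 0-based half-open.
#' @return Integer site indices.
#' @export
sites_in_window <- function(hap, chrom, start, end) {
  which(hap$sites$chrom == chrom & hap$sites$pos > start & hap$sites$pos <= end)
}

#' Describe the candidate causal (core) variant
#'
#' @param chrom Contig the variant lies on.
#' @param pos 1-based position (as in the VCF).
#' @param derived_allele_code Which allele code (0 = ref, 1 = alt) is the
#'   derived, putatively causal allele. Default 1.
#' @param mode Inheritance mode of the phenotype: `"recessive"` (e.g. ASIP
#'   loss-of-function melanism) or `"dominant"` (e.g. MC1R gain-of-function).
#' @param name Optional display name, e.g. `"ASIP R120C"`.
#' @return An object of class `core_variant`.
#' @export
core_variant <- function(chrom, pos, derived_allele_code = 1L,
                         mode = c("recessive", "dominant"), name = NULL) {
  mode <- match.arg(mode)
  if (!derived_allele_code %in% c(0L, 1L)) {
    abort("`derived_allele_code` must be 0 or 1", class = "sweepwatch_error")
  }
  if (pos < 1) abort("`pos` must be >= 1", class = "sweepwatch_error")
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         derived_allele_code = as.integer(derived_allele_code),
         mode = mode, name = name %||% sprintf("%s:%d", chrom, pos)),
    class = "core_variant"
  )
}

#' @export
print.core_variant <- function(x, ...) {
  cat(sprintf("<core_variant> %s at %s:%d (derived = allele code %d, %s)\n",
              x$name, x$chrom, x$pos, x$derived_allele_code, x$mode))
  invisible(x)
}

# Column index of the core site; error if absent.
core_site_index <- function(hap, core) {
  i <- which(hap$sites$chrom == core$chrom & hap$sites$pos == core$pos)
  if (length(i) != 1) {
    abort(sprintf("core variant %s:%d not found in haplotype matrix",
                  core$chrom, core$pos),
          class = "sweepwatch_error")
  }
  i
}

vcf_abort <- function(msg, record = NULL) {
  abort(if (is.null(record)) msg else sprintf("%s at %s", msg, record),
        class = "sweepwatch_parse_error")
}

#' Read a phased VCF into a haplotype matrix
#'
#' Retains only biallelic SNP records; every sample must have a phased
#' diploid genotype (`x|y`) at every retained record. Missing, unphased or
#' non-diploid genotypes are hard errors: phasing and imputation are
#' upstream concerns and the matrix admits no missing entries. Gzipped
#' files are handled transparently.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @param region Optional region filter `"chrom"` or `"chrom:from-to"`
#'   (1-based, inclusive).
#' @return A [hap_matrix()] whose chromosomes are ordered sample-by-sample
#'   as `<sample>_A`, `<sample>_B`.
#' @export
read_phased_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("VCF file not found: %s", path), class = "sweepwatch_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(v@gt) == 0 && nrow(fix) == 0) {
    vcf_abort(sprintf("no records in %s", path))
  }
  if (is.null(dim(fix))) fix <- t(fix)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if ("FORMAT" %in% colnames(gt)) {
    gt <- gt[, setdiff(colnames(gt), "FORMAT"), drop = FALSE]
  }
  samples <- colnames(gt)
  if (length(samples) == 0) vcf_abort("VCF has no sample columns")
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1]]
    if (length(m) == 0) vcf_abort(sprintf("cannot parse region '%s'", region))
    keep <- keep & fix$CHROM == m[2]
    if (m[3] != "") {
      keep <- keep & as.integer(fix$POS) >= as.integer(m[3]) &
        as.integer(fix$POS) <= as.integer(m[4])
    }
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  if (nrow(fix) == 0) vcf_abort("no records after region filtering")
  rec <- sprintf("%s:%s", fix$CHROM, fix$POS)
  for (i in seq_len(nrow(fix))) {
    if (grepl(",", fix$ALT[i], fixed = TRUE)) {
      vcf_abort("multiallelic record", rec[i])
    }
    if (!fix$REF[i] %in% c("A", "C", "G", "T") ||
        !fix$ALT[i] %in% c("A", "C", "G", "T")) {
      vcf_abort("non-SNP alleles", rec[i])
    }
  }
  pos <- as.integer(fix$POS)
  ord_ok <- !is.unsorted(order(fix$CHROM, pos)) &&
    all(tapply(pos, fix$CHROM, function(p) !is.unsorted(p, strictly = TRUE)))
  if (!ord_ok) vcf_abort("records are not sorted by position")

  # GT is the first (or only) colon-separated field
  gt_only <- sub(":.*$", "", gt)
  n_rec <- nrow(fix)
  geno <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = n_rec)
  for (j in seq_along(samples)) {
    g <- gt_only[, j]
    bad <- which(is.na(g) | g %in% c(".", "./.", ".|."))
    if (length(bad) > 0) vcf_abort("missing genotype", rec[bad[1]])
    unph <- which(grepl("/", g, fixed = TRUE))
    if (length(unph) > 0) vcf_abort("unphased genotype", rec[unph[1]])
    parts <- strsplit(g, "|", fixed = TRUE)
    len <- lengths(parts)
    if (any(len != 2)) vcf_abort("genotype is not diploid", rec[which(len != 2)[1]])
    al <- suppressWarnings(matrix(as.integer(unlist(parts)), nrow = 2))
    if (anyNA(al)) vcf_abort("missing genotype", rec[which(is.na(al[1, ] * al[2, ]))[1]])
    if (any(al > 1)) vcf_abort("allele index beyond biallelic", rec[which(al[1, ] > 1 | al[2, ] > 1)[1]])
    geno[2L * j - 1L, ] <- al[1, ]
    geno[2L * j, ] <- al[2, ]
  }
  rownames(geno) <- as.vector(rbind(paste0(samples, "_A"), paste0(samples, "_B")))
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  sites <- tibble(chrom = fix$CHROM, pos = pos, ref = fix$REF, alt = fix$ALT,
                  qual = qual)
  hap_matrix(sites, geno)
}

#' Write a haplotype matrix as a phased VCF
#'
#' Chromosome ids must pair up as `<sample>_A` / `<sample>_B` in adjacent
#' rows; each pair becomes one diploid sample with phased genotypes.
#'
#' @param hap A [hap_matrix()].
#' @param path Output path; plain text VCF 4.2.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hap, path) {
  ids <- chrom_ids(hap)
  if (n_chrom(hap) %% 2 != 0) {
    abort("odd number of chromosomes cannot be written as diploid samples",
          class = "sweepwatch_error")
  }
  a <- ids[seq(1, length(ids), by = 2)]
  b <- ids[seq(2, length(ids), by = 2)]
  if (!all(grepl("_A$", a)) || !all(grepl("_B$", b)) ||
      !all(sub("_A$", "", a) == sub("_B$", "", b))) {
    abort("chromosome ids must alternate <sample>_A, <sample>_B",
          class = "sweepwatch_error")
  }
  samples <- sub("_A$", "", a)
  st <- hap$sites
  gt <- matrix(paste(t(hap$geno[seq(1, n_chrom(hap), 2), , drop = FALSE]),
                     t(hap$geno[seq(2, n_chrom(hap), 2), , drop = FALSE]),
                     sep = "|"),
               nrow = n_sites(hap))
  qual_str <- ifelse(is.na(st$qual), ".", formatC(st$qual, format = "fg"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepwatch",
    sprintf("##contig=<ID=%s>", unique(st$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "FORMAT",
            samples), collapse = "\t")
  )
  body <- paste(st$chrom, st$pos, ".", st$ref, st$alt, qual_str, "PASS", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  if (n_sites(hap) == 0) body <- character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path TSV with header columns `sample_id`, `species`, `phenotype`;
#'   phenotype must be `melanistic` or `non_melanistic`. Gzip accepted.
#' @return A tibble with those three columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("metadata file not found: %s", path), class = "sweepwatch_io_error")
  }
  meta <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  need <- c("sample_id", "species", "phenotype")
  if (!all(need %in% names(meta))) {
    abort(sprintf("metadata must have columns %s", paste(need, collapse = ", ")),
          class = "sweepwatch_parse_error")
  }
  if (nrow(meta) == 0) abort("no samples in metadata", class = "sweepwatch_parse_error")
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample id(s): %s", paste(unique(dup), collapse = ", ")),
          class = "sweepwatch_parse_error")
  }
  ok <- c("melanistic", "non_melanistic")
  bad <- setdiff(unique(meta$phenotype), ok)
  if (length(bad) > 0) {
    abort(sprintf("unknown phenotype token(s) %s; accepted: %s",
                  paste(bad, collapse = ", "), paste(ok, collapse = ", ")),
          class = "sweepwatch_parse_error")
  }
  meta[, need]
}

#' Read analysis windows from BED
#'
#' BED3+name, 0-based half-open, as used for the fosmid intervals that tile
#' a capture target. Windows are returned sorted by (chrom, start);
#' overlapping windows are allowed but trigger a warning.
#'
#' @param path BED file (optionally gzipped) with columns chrom, start,
#'   end, name.
#' @return A tibble with columns `label`, `chrom`, `start`, `end`.
#' @export
read_windows <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("window file not found: %s", path), class = "sweepwatch_io_error")
  }
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "label"),
                         show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           start = readr::col_double(),
                           end = readr::col_double(),
                           label = readr::col_character()))
  if (nrow(bed) == 0) abort("no windows in BED", class = "sweepwatch_parse_error")
  windows <- tibble(label = bed$label, chrom = bed$chrom,
                    start = as.integer(bed$start), end = as.integer(bed$end))
  validate_windows(windows)
}

validate_windows <- function(windows) {
  windows <- as_tibble(windows)[, c("label", "chrom", "start", "end")]
  bad <- which(windows$end <= windows$start)
  if (length(bad) > 0) {
    abort(sprintf("window '%s' has end <= start", windows$label[bad[1]]),
          class = "sweepwatch_parse_error")
  }
  if (anyDuplicated(windows$label)) {
    abort(sprintf("duplicate window label(s): %s",
                  paste(unique(windows$label[duplicated(windows$label)]),
                        collapse = ", ")),
          class = "sweepwatch_parse_error")
  }
  windows <- windows[order(windows$chrom, windows$start), ]
  by_chrom <- split(windows, windows$chrom)
  overlap <- any(vapply(by_chrom, function(w) {
    nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)])
  }, logical(1)))
  if (overlap) warn("windows overlap", class = "sweepwatch_warning")
  windows
}

#' Tile an interval into equal windows
#'
#' Convenience builder for simulated data: splits `[0, L)` into `n` equal
#' 0-based half-open windows labelled `W01`, `W02`, ...
#'
#' @param L Total length in bp.
#' @param n Number of windows.
#' @param chrom Contig label.
#' @return A windows tibble as from [read_windows()].
#' @export
make_tiling_windows <- function(L, n = 10, chrom = "chrSim") {
  edges <- round(seq(0, L, length.out = n + 1))
  tibble(label = sprintf("W%02d", seq_len(n)), chrom = chrom,
         start = as.integer(edges[-(n + 1)]), end = as.integer(edges[-1]))
}

#' Write windows as BED3+name
#'
#' @param windows A windows tibble ([read_windows()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  readr::write_tsv(windows[, c("chrom", "start", "end", "label")], path,
                   col_names = FALSE)
  invisible(path)
}
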
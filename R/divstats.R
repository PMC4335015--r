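# Pairwise difference counts between chromosomes over a 0/1 matrix:
# diff[i,j] = number of sites where rows i and j disagree.
pairwise_diffs <- function(g) {
  g <- matrix(as.numeric(g), nrow = nrow(g))
  tcrossprod(g, 1 - g) + tcrossprod(1 - g, g)
}

#' Nucleotide diversity over a window
#'
#' Average per-site pairwise difference among a set of chromosomes:
#' `pi = sum over unordered pairs of differing-site counts / C(n,2) /
#' window length in bp`. The bp denominator counts monomorphic positions
#' implicitly, matching diversity reported as a percentage of sequence
#' length; `denominator = "variant_sites"` divides by the number of
#' segregating sites in the window instead (debugging aid). The SEM is the
#' standard deviation of the per-pair per-site differences divided by
#' `sqrt(C(n,2))`; pairs sharing a chromosome are not independent, so this
#' is a descriptive error bar, not a confidence interval.
#'
#' @param hap A [hap_matrix()].
#' @param window One-row data frame with `chrom`, `start`, `end` (0-based
#'   half-open) — a row of a windows tibble.
#' @param chroms Chromosome ids or indices to include (default: all).
#' @param denominator `"bp"` (default) or `"variant_sites"`.
#' @return A one-row tibble: `pi`, `pi_percent`, `sem`, `n_pairs`,
#'   `n_chrom`, `n_sites`.
#' @examples
#' h <- hap_matrix(
#'   tibble::tibble(chrom = "c", pos = c(10, 20, 30), ref = "A", alt = "G"),
#'   matrix(c(0L,0L,0L, 1L,1L,1L), nrow = 2, byrow = TRUE,
#'          dimnames = list(c("x_A", "x_B"), NULL)))
#' nucleotide_diversity(h, tibble::tibble(chrom = "c", start = 0, end = 1000))
#' @export
nucleotide_diversity <- function(hap, window, chroms = NULL,
                                 denominator = c("bp", "variant_sites")) {
  denominator <- match.arg(denominator)
  window <- as.list(as_tibble(window)[1, ])
  len <- window$end - window$start
  if (len <= 0) abort("window has length 0", class = "sweepwatch_error")
  if (!is.null(chroms)) hap <- hap_subset(hap, chroms = chroms)
  n <- n_chrom(hap)
  if (n < 2) abort("need at least 2 chromosomes for diversity",
                   class = "sweepwatch_error")
  idx <- sites_in_window(hap, window$chrom, window$start, window$end)
  g <- hap$geno[, idx, drop = FALSE]
  denom <- if (denominator == "bp") len else max(length(idx), 1L)
  d <- pairwise_diffs(g)
  pair_diffs <- d[lower.tri(d)]
  per_pair <- pair_diffs / denom
  pi <- sum(pair_diffs) / length(pair_diffs) / denom
  tibble(pi = pi, pi_percent = 100 * pi,
         sem = if (length(per_pair) > 1) sd(per_pair) / sqrt(length(per_pair)) else 0,
         n_pairs = length(per_pair), n_chrom = n, n_sites = length(idx))
}

#' Windowed diversity profile stratified by class
#'
#' Computes nucleotide diversity per window for each chromosome class
#' (derived vs ancestral allele at the core site) or each individual
#' phenotype class (both chromosomes of every individual in the class).
#' A class with fewer than 2 chromosomes in scope yields `NA` diversity
#' for that cell, never 0.
#'
#' @param hap A [hap_matrix()].
#' @param windows Windows tibble ([read_windows()] layout).
#' @param classing A classing from [classify()].
#' @param by `"chromosome_class"` or `"individual_class"`.
#' @param denominator Passed to [nucleotide_diversity()].
#' @return A tibble of class `diversity_profile`: one row per
#'   (window, class) with `window`, `chrom`, `start`, `end`, `class`,
#'   `n_chrom`, `n_sites`, `pi`, `pi_percent`, `sem`.
#' @export
diversity_profile <- function(hap, windows, classing,
                              by = c("chromosome_class", "individual_class"),
                              denominator = c("bp", "variant_sites")) {
  by <- match.arg(by)
  denominator <- match.arg(denominator)
  groups <- class_members(hap, classing, by)
  out <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    win <- windows[w, ]
    purrr::map_dfr(names(groups), function(cl) {
      ids <- groups[[cl]]
      if (length(ids) < 2) {
        idx <- sites_in_window(hap, win$chrom, win$start, win$end)
        return(tibble(window = win$label, chrom = win$chrom, start = win$start,
                      end = win$end, class = cl, n_chrom = length(ids),
                      n_sites = length(idx), pi = NA_real_,
                      pi_percent = NA_real_, sem = NA_real_))
      }
      d <- nucleotide_diversity(hap, win, chroms = ids, denominator = denominator)
      tibble(window = win$label, chrom = win$chrom, start = win$start,
             end = win$end, class = cl, n_chrom = d$n_chrom,
             n_sites = d$n_sites, pi = d$pi, pi_percent = d$pi_percent,
             sem = d$sem)
    })
  })
  class(out) <- c("diversity_profile", class(out))
  out
}

# Resolve a classing into named lists of chromosome ids.
class_members <- function(hap, classing, by) {
  if (by == "chromosome_class") {
    ch <- classing$chromosomes
    list(derived = ch$chrom_id[ch$class == "derived"],
         ancestral = ch$chrom_id[ch$class == "ancestral"])
  } else {
    ind <- classing$individuals
    of <- function(ph) {
      s <- ind$sample_id[ind$phenotype == ph]
      chrom_ids(hap)[sub("_[AB]$", "", chrom_ids(hap)) %in% s]
    }
    list(melanistic = of("melanistic"), non_melanistic = of("non_melanistic"))
  }
}

#' Count distinct haplotypes over a window
#'
#' @param hap A [hap_matrix()].
#' @param window One-row window data frame (`chrom`, `start`, `end`).
#' @param chroms Chromosome ids or indices (default all; must be nonempty).
#' @return Integer count of distinct allele strings over the window's
#'   sites; 1 by convention when the window contains no site.
#' @export
haplotype_count <- function(hap, window, chroms = NULL) {
  if (!is.null(chroms)) hap <- hap_subset(hap, chroms = chroms)
  if (n_chrom(hap) == 0) abort("empty chromosome subset", class = "sweepwatch_error")
  window <- as.list(as_tibble(window)[1, ])
  idx <- sites_in_window(hap, window$chrom, window$start, window$end)
  if (length(idx) == 0) return(1L)
  strings <- apply(hap$geno[, idx, drop = FALSE], 1, paste, collapse = "")
  length(unique(strings))
}

#' Density-thin variants to about one per kilobase
#'
#' Partitions every window into consecutive `bin_bp` bins from the window
#' start and keeps the single best site per bin: highest quality, ties and
#' missing qualities resolved to the smallest position. Sites outside all
#' windows are dropped (off-target).
#'
#' @param hap A [hap_matrix()].
#' @param windows Windows tibble.
#' @param bin_bp Bin width in bp (default 1000).
#' @return A thinned [hap_matrix()]; the retained original site indices
#'   are in `attr(, "retained")`.
#' @export
thin_variants <- function(hap, windows, bin_bp = 1000) {
  st <- hap$sites
  keep <- logical(nrow(st))
  for (w in seq_len(nrow(windows))) {
    win <- windows[w, ]
    idx <- sites_in_window(hap, win$chrom, win$start, win$end)
    if (length(idx) == 0) next
    bin <- (st$pos[idx] - 1L - win$start) %/% bin_bp
    for (b in unique(bin)) {
      cand <- idx[bin == b]
      q <- st$qual[cand]
      q[is.na(q)] <- -Inf
      best <- cand[q == max(q)]
      keep[min(best)] <- TRUE
    }
  }
  out <- hap_subset(hap, sites = which(keep))
  attr(out, "retained") <- which(keep)
  out
}
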
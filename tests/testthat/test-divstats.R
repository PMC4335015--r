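test_that("pairwise diversity matches hand-computed examples", {
  win <- tibble::tibble(chrom = "chrT", start = 0, end = 1000)
  # identical pair
  h0 <- make_hap(matrix(0L, 2, 3))
  d0 <- nucleotide_diversity(h0, win)
  expect_equal(d0$pi, 0)
  expect_equal(d0$sem, 0)
  # one pair differing at 3 of 1000 bp
  h1 <- make_hap(rbind(c(0L, 0L, 0L), c(1L, 1L, 1L)))
  d1 <- nucleotide_diversity(h1, win)
  expect_equal(d1$pi, 0.003)
  expect_equal(d1$pi_percent, 0.3)
  # 4 chromosomes, 5 sites: brute-force over all 6 pairs gives 16/6/1000
  h2 <- make_hap(rbind(c(0,0,0,0,0), c(0,0,0,0,1), c(0,0,0,1,1), c(1,1,1,1,1)))
  d2 <- nucleotide_diversity(h2, win)
  expect_equal(d2$pi, 16 / 6 / 1000)
  expect_equal(d2$n_pairs, 6)
})

test_that("diversity equals the brute-force pair/site double loop on random matrices", {
  for (case in 1:30) {
    n <- sample(2:12, 1)
    m <- sample(1:50, 1)
    hap <- random_hap(n, m, seed = 1000 + case)
    win <- window_over(hap, pad = 5)
    got <- nucleotide_diversity(hap, win)
    expect_identical(got$pi, oracle_pi(hap$geno, win$end - win$start))
  }
})

test_that("diversity is invariant to chromosome order and to 0/1 label swaps", {
  hap <- random_hap(8, 30, seed = 77)
  win <- window_over(hap)
  base <- nucleotide_diversity(hap, win)$pi
  perm <- hap_subset(hap, chroms = sample(chrom_ids(hap)))
  expect_equal(nucleotide_diversity(perm, win)$pi, base)
  flipped <- hap
  flip <- sample(ncol(hap$geno), 10)
  flipped$geno[, flip] <- 1L - flipped$geno[, flip]
  expect_equal(nucleotide_diversity(flipped, win)$pi, base)
})

test_that("diversity over concatenated equal windows is the mean of the parts", {
  hap <- random_hap(6, 40, seed = 55)
  mid <- 200L  # positions run 10..400
  w1 <- tibble::tibble(chrom = "chrT", start = 0, end = mid)
  w2 <- tibble::tibble(chrom = "chrT", start = mid, end = 2 * mid)
  whole <- tibble::tibble(chrom = "chrT", start = 0, end = 2 * mid)
  expect_equal(nucleotide_diversity(hap, whole)$pi,
               mean(c(nucleotide_diversity(hap, w1)$pi,
                      nucleotide_diversity(hap, w2)$pi)))
})

test_that("per-variant-site denominator is exposed as an option", {
  h <- make_hap(rbind(c(0L, 0L, 0L), c(1L, 1L, 0L)))
  win <- tibble::tibble(chrom = "chrT", start = 0, end = 1000)
  expect_equal(nucleotide_diversity(h, win, denominator = "variant_sites")$pi,
               2 / 3)
})

test_that("diversity agrees with an established implementation to 6+ decimals", {
  skip_if_not_installed("ape")
  hap <- random_hap(10, 40, seed = 99)
  L <- 500L
  win <- tibble::tibble(chrom = "chrT", start = 0, end = L)
  # expand to full-length sequences: background 'a', alt allele 'c'
  seqs <- matrix("a", nrow = n_chrom(hap), ncol = L)
  for (j in seq_len(n_sites(hap))) {
    seqs[hap$geno[, j] == 1L, hap$sites$pos[j]] <- "c"
  }
  # mean raw pairwise distance over full-length sequences = pi per bp
  nd <- mean(ape::dist.dna(ape::as.DNAbin(seqs), model = "raw"))
  expect_equal(nucleotide_diversity(hap, win)$pi, nd, tolerance = 1e-9)
})

test_that("diversity profile stratifies by chromosome class and phenotype", {
  dir <- withr::local_tempdir()
  p <- sweep_sim_params(seed = 61, muG = 0)
  ds <- emit_dataset(p, dir)
  classing <- classify(ds$hap, ds$core, ds$meta)
  prof <- diversity_profile(ds$hap, ds$windows, classing, "chromosome_class")
  expect_s3_class(prof, "diversity_profile")
  expect_equal(nrow(prof), 2 * nrow(ds$windows))
  core_win <- ds$windows$label[ds$windows$start < p$core_pos &
                               ds$windows$end >= p$core_pos]
  pid <- prof$pi[prof$window == core_win & prof$class == "derived"]
  pia <- prof$pi[prof$window == core_win & prof$class == "ancestral"]
  expect_lt(pid, pia)  # sweep construction
  # permuting window order permutes rows only
  prof_rev <- diversity_profile(ds$hap, ds$windows[nrow(ds$windows):1, ],
                                classing, "chromosome_class")
  expect_equal(dplyr::arrange(tibble::as_tibble(prof_rev), window, class),
               dplyr::arrange(tibble::as_tibble(prof), window, class))
  prof_ind <- diversity_profile(ds$hap, ds$windows, classing, "individual_class")
  expect_setequal(unique(prof_ind$class), c("melanistic", "non_melanistic"))
})

test_that("a class with fewer than two chromosomes reports NA diversity, not zero", {
  hap <- make_hap(rbind(c(1L, 0L), c(0L, 0L), c(0L, 1L), c(0L, 0L)),
                  pos = c(100L, 200L))
  core <- core_variant("chrT", 100, 1L, "dominant")
  meta <- tibble::tibble(sample_id = c("s01", "s02"), species = "t",
                         phenotype = c("melanistic", "non_melanistic"))
  classing <- classify(hap, core, meta)
  prof <- diversity_profile(hap, tibble::tibble(label = "W", chrom = "chrT",
                                                start = 0, end = 1000),
                            classing, "chromosome_class")
  expect_true(is.na(prof$pi[prof$class == "derived"]))
  expect_false(is.na(prof$pi[prof$class == "ancestral"]))
})

test_that("under a neutral random split the class difference is Monte-Carlo null", {
  # seed-averaged per-window difference between two random halves of the
  # ancestral panel, compared with 3x its Monte Carlo standard error; with
  # nine simultaneous windows one marginal exceedance is within the
  # false-positive allowance, gross exceedance is not.
  n_seeds <- 20
  diffs <- vapply(seq_len(n_seeds), function(s) {
    p <- sweep_sim_params(seed = s)
    anc <- simulate_ancestral_panel(p)
    set.seed(p$seed + 5000)
    ids <- sample(chrom_ids(anc))
    wins <- make_tiling_windows(p$L, 9, chrom = p$contig)
    vapply(seq_len(nrow(wins)), function(w) {
      nucleotide_diversity(anc, wins[w, ], chroms = ids[1:20])$pi -
        nucleotide_diversity(anc, wins[w, ], chroms = ids[21:40])$pi
    }, numeric(1))
  }, numeric(9))
  z <- abs(rowMeans(diffs)) / (apply(diffs, 1, sd) / sqrt(n_seeds))
  expect_lte(sum(z > 3), 1)
  expect_true(all(z < 5))
})

test_that("haplotype counting distinguishes distinct allele strings", {
  win <- tibble::tibble(chrom = "chrT", start = 0, end = 1000)
  expect_equal(haplotype_count(make_hap(matrix(0L, 5, 4)), win), 1L)
  distinct <- make_hap(diag(1L, 4))
  expect_equal(haplotype_count(distinct, win), 4L)
  # window without sites counts one haplotype by convention
  expect_equal(haplotype_count(distinct,
                               tibble::tibble(chrom = "chrT", start = 500,
                                              end = 600)), 1L)
  expect_error(haplotype_count(hap_subset(distinct, chroms = integer()), win),
               "empty", class = "sweepwatch_error")
})

test_that("the sweep founder model leaves fewer derived haplotypes in the core window", {
  wins <- make_tiling_windows(500000, 9)
  hits <- vapply(1:20, function(s) {
    p <- sweep_sim_params(seed = 300 + s)
    anc <- simulate_ancestral_panel(p)
    sw <- simulate_sweep_class(p, anc)
    comb <- combine_panels(anc, sw$hap)
    w <- wins[5, ]
    haplotype_count(comb, w, chroms = chrom_ids(sw$hap)) <
      haplotype_count(comb, w, chroms = chrom_ids(anc))
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("density thinning keeps the best site per kilobase bin", {
  win <- tibble::tibble(label = "W", chrom = "chrT", start = 0, end = 3000)
  # 10 sites crowded into one bin -> 1 retained
  crowded <- make_hap(matrix(0:1, 4, 10), pos = seq(10, 910, by = 100))
  expect_equal(n_sites(thin_variants(crowded, win)), 1L)
  # 3 sites in 3 distinct bins -> all retained
  spread <- make_hap(matrix(0:1, 4, 3), pos = c(500L, 1500L, 2500L))
  expect_equal(n_sites(thin_variants(spread, win)), 3L)
  # qualities [5, 9, 9] at positions [10, 20, 30]: tie broken to position 20
  tied <- make_hap(matrix(0:1, 4, 3), pos = c(10L, 20L, 30L),
                   qual = c(5, 9, 9))
  thinned <- thin_variants(tied, win)
  expect_equal(thinned$sites$pos, 20L)
  # all-missing quality: smallest position wins
  noq <- make_hap(matrix(0:1, 4, 3), pos = c(10L, 20L, 30L))
  expect_equal(thin_variants(noq, win)$sites$pos, 10L)
  # off-target sites are dropped
  off <- make_hap(matrix(0:1, 4, 2), pos = c(100L, 5000L))
  expect_equal(thin_variants(off, win)$sites$pos, 100L)
})
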
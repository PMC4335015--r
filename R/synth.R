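#' Parameters for the founder-sweep haplotype simulator
#'
#' The simulator produces two classes of phased chromosomes over one window
#' of length `L`: a neutral *ancestral* panel with background linkage
#' disequilibrium, and a *derived* class descended from a single founder
#' haplotype that carries the derived allele at the core site — the pattern
#' a recent selective sweep (or founder event) leaves in a targeted
#' resequencing region.
#'
#' The ancestral panel is a Li–Stephens-style mosaic: `k_founders` founder
#' haplotypes are drawn site-by-site from a `1/i`-weighted derived-count
#' spectrum, and each ancestral chromosome copies a founder, switching to a
#' uniformly chosen founder with per-bp probability `switch_rate`. Each
#' derived chromosome copies the sweep founder out to an exponentially
#' distributed recombination breakpoint on each side of the core (rate `rG`
#' per bp, i.e. recombination rate times sweep age) and an ancestral
#' chromosome beyond it, then receives `Poisson(muG * L)` private new
#' mutations (rate `muG` per bp, mutation rate times sweep age).
#'
#' Defaults describe a 500 kb capture target with a core variant at its
#' midpoint, 40 + 40 chromosomes, and `n_sites` chosen so expected
#' nucleotide diversity of the ancestral panel is ~0.05% per bp — the level
#' observed in small wild-felid populations.
#'
#' @param L Window length in bp.
#' @param core_pos Position of the core (causal) variant, 1-based, in (0, L).
#' @param n_anc,n_der Numbers of ancestral and derived chromosomes
#'   (`n_der >= 2`).
#' @param n_sites Segregating sites in the ancestral panel.
#' @param k_founders Number of mosaic founder haplotypes.
#' @param switch_rate Per-bp probability of switching founders along an
#'   ancestral chromosome (controls background LD decay).
#' @param rG Per-bp rate of the exponential breakpoint distance of derived
#'   chromosomes (recombination rate x sweep age).
#' @param muG Per-bp expected density of new mutations private to a derived
#'   chromosome (mutation rate x sweep age).
#' @param seed Integer seed; all randomness derives from it.
#' @param contig Contig label used in output files.
#' @return A list of class `sweep_sim_params`.
#' @export
sweep_sim_params <- function(L = 500000L, core_pos = 250000L,
                             n_anc = 40L, n_der = 40L, n_sites = 850L,
                             k_founders = 8L, switch_rate = 1e-5,
                             rG = 5e-6, muG = 1e-6, seed = 1L,
                             contig = "chrSim") {
  p <- list(L = as.integer(L), core_pos = as.integer(core_pos),
            n_anc = as.integer(n_anc), n_der = as.integer(n_der),
            n_sites = as.integer(n_sites), k_founders = as.integer(k_founders),
            switch_rate = switch_rate, rG = rG, muG = muG,
            seed = as.integer(seed), contig = contig)
  if (any(c(p$switch_rate, p$rG, p$muG) < 0)) {
    abort("rates must be >= 0", class = "sweepwatch_error")
  }
  if (p$n_der < 2) abort("n_der must be >= 2", class = "sweepwatch_error")
  if (p$core_pos <= 0 || p$core_pos >= p$L) {
    abort("core_pos must lie inside (0, L)", class = "sweepwatch_error")
  }
  if (p$n_sites < 1) abort("n_sites must be >= 1", class = "sweepwatch_error")
  structure(p, class = "sweep_sim_params")
}

#' Expected per-bp nucleotide diversity of the ancestral mosaic model
#'
#' Closed form: two distinct chromosomes carry independent uniformly chosen
#' founders at any one site, so a site contributes
#' `E[2 m'(k - m')] / k^2` where `m' ~ Binomial(k, m/k)` and the derived
#' count `m` follows the `1/i` spectrum on `1..k-1`; this reduces to
#' `(k-1)^2 / (H_{k-1} k^2)` per segregating site.
#'
#' @param params A [sweep_sim_params()].
#' @return Expected pairwise diversity per bp of the ancestral panel.
#' @export
expected_ancestral_pi <- function(params) {
  k <- params$k_founders
  h <- sum(1 / seq_len(k - 1))
  per_site <- (k - 1)^2 / (h * k^2)
  params$n_sites * per_site / params$L
}

#' Number of segregating sites needed for a target diversity
#'
#' @param target_pi Target per-bp nucleotide diversity of the ancestral
#'   panel (e.g. `5e-4` for 0.05%).
#' @param params A [sweep_sim_params()] supplying `L` and `k_founders`.
#' @return Integer number of sites.
#' @export
n_sites_for_target_pi <- function(target_pi, params) {
  one <- expected_ancestral_pi(modifyList2(params, n_sites = 1L))
  as.integer(round(target_pi / one))
}

# modifyList for the params class, keeping validation
modifyList2 <- function(params, ...) {
  p <- unclass(params)
  dots <- list(...)
  p[names(dots)] <- dots
  do.call(sweep_sim_params, p)
}

#' Simulate the neutral ancestral panel
#'
#' @param params A [sweep_sim_params()].
#' @return A [hap_matrix()] of `n_anc` chromosomes (`anc001`, ...). Site
#'   positions are uniform on `(0, L)` excluding `core_pos` (the core
#'   column is created by [simulate_sweep_class()]).
#' @export
simulate_ancestral_panel <- function(params) {
  stopifnot(inherits(params, "sweep_sim_params"))
  set.seed(params$seed)
  p <- params
  pool <- setdiff(seq_len(p$L), p$core_pos)
  pos <- sort(sample(pool, p$n_sites))
  # founder alleles: derived count m ~ 1/i spectrum, then iid Bernoulli(m/k)
  if (p$k_founders == 1) {
    founders <- matrix(0L, nrow = 1, ncol = p$n_sites)  # degenerate: monomorphic
  } else {
    m <- sample(seq_len(p$k_founders - 1), p$n_sites, replace = TRUE,
                prob = 1 / seq_len(p$k_founders - 1))
    f <- m / p$k_founders
    founders <- matrix(rbinom(p$k_founders * p$n_sites, 1L,
                              rep(f, each = p$k_founders)),
                       nrow = p$k_founders)
  }
  # per-interval switch probabilities between consecutive sites
  gap <- diff(pos)
  p_switch <- 1 - exp(-p$switch_rate * gap)
  geno <- matrix(0L, nrow = p$n_anc, ncol = p$n_sites)
  for (i in seq_len(p$n_anc)) {
    sw <- runif(p$n_sites - 1) < p_switch
    seg <- cumsum(c(0L, sw)) + 1L
    choice <- sample.int(p$k_founders, max(seg), replace = TRUE)
    geno[i, ] <- founders[cbind(choice[seg], seq_len(p$n_sites))]
  }
  rownames(geno) <- sprintf("anc%03d", seq_len(p$n_anc))
  ref <- sample(c("A", "C", "G", "T"), p$n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  sites <- tibble(chrom = p$contig, pos = pos, ref = ref, alt = unname(alt),
                  qual = NA_real_)
  hap_matrix(sites, geno)
}

#' Simulate the derived (sweep) class from an ancestral panel
#'
#' One ancestral chromosome becomes the sweep founder and is assigned the
#' derived allele at `core_pos` (a new site column). Each derived
#' chromosome copies the founder out to Exponential(`rG`) breakpoints on
#' each side of the core and a uniformly chosen ancestral chromosome
#' beyond them, then gains `Poisson(muG * L)` private new mutations at new
#' uniform positions. Every derived chromosome carries the derived allele
#' at the core; ancestral chromosomes carry code 0 at the core and at all
#' private-mutation columns.
#'
#' @param params A [sweep_sim_params()].
#' @param ancestral The panel from [simulate_ancestral_panel()].
#' @return A list with elements `hap` (the derived-class [hap_matrix()],
#'   chromosomes `der001`, ...) and `truth` (class `sweep_sim_truth`:
#'   `founder_haplotype`, `founder_id`, per-chromosome `breakpoints`
#'   tibble with `left_bp`/`right_bp` distances from the core,
#'   `new_mutation_positions`, and `params`).
#' @export
simulate_sweep_class <- function(params, ancestral) {
  stopifnot(inherits(params, "sweep_sim_params"), inherits(ancestral, "hap_matrix"))
  if (n_chrom(ancestral) == 0) abort("ancestral panel is empty", class = "sweepwatch_error")
  p <- params
  set.seed(p$seed + 1000003L)
  anc_pos <- ancestral$sites$pos
  if (p$core_pos %in% anc_pos) {
    abort("ancestral panel already segregates at core_pos", class = "sweepwatch_error")
  }
  founder_id <- sample.int(n_chrom(ancestral), 1)
  founder <- ancestral$geno[founder_id, ]
  dist_from_core <- abs(anc_pos - p$core_pos)
  left_of_core <- anc_pos < p$core_pos

  n <- p$n_der
  b_left <- if (p$rG > 0) rexp(n, rate = p$rG) else rep(Inf, n)
  b_right <- if (p$rG > 0) rexp(n, rate = p$rG) else rep(Inf, n)
  donors_l <- sample.int(n_chrom(ancestral), n, replace = TRUE)
  donors_r <- sample.int(n_chrom(ancestral), n, replace = TRUE)
  geno <- matrix(0L, nrow = n, ncol = length(anc_pos))
  for (i in seq_len(n)) {
    row <- founder
    out_l <- left_of_core & dist_from_core >= b_left[i]
    out_r <- !left_of_core & dist_from_core >= b_right[i]
    row[out_l] <- ancestral$geno[donors_l[i], out_l]
    row[out_r] <- ancestral$geno[donors_r[i], out_r]
    geno[i, ] <- row
  }
  rownames(geno) <- sprintf("der%03d", seq_len(n))

  # private new mutations: new columns, one carrier each
  n_mut <- rpois(n, p$muG * p$L)
  used <- c(anc_pos, p$core_pos)
  mut_pos <- vector("list", n)
  for (i in seq_len(n)) {
    if (n_mut[i] > 0) {
      pool <- setdiff(seq_len(p$L), used)
      mp <- sort(sample(pool, min(n_mut[i], length(pool))))
      used <- c(used, mp)
      mut_pos[[i]] <- mp
    } else {
      mut_pos[[i]] <- integer()
    }
  }
  all_mut <- unlist(mut_pos)
  extra_pos <- c(p$core_pos, all_mut)
  extra <- matrix(0L, nrow = n, ncol = length(extra_pos))
  extra[, 1] <- 1L  # derived allele at the core
  if (length(all_mut) > 0) {
    carrier <- rep(seq_len(n), times = lengths(mut_pos))
    extra[cbind(carrier, 1L + seq_along(all_mut))] <- 1L
  }
  ref_e <- sample(c("A", "C", "G", "T"), length(extra_pos), replace = TRUE)
  alt_e <- vapply(ref_e, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  sites <- rbind(ancestral$sites,
                 tibble(chrom = p$contig, pos = as.integer(extra_pos),
                        ref = ref_e, alt = unname(alt_e), qual = NA_real_))
  geno_all <- cbind(geno, extra)
  ord <- order(sites$chrom, sites$pos)
  hap <- hap_matrix(sites[ord, ], geno_all[, ord, drop = FALSE])

  founder_full <- c(founder, 1L, rep(0L, length(all_mut)))[ord]
  truth <- structure(
    list(founder_haplotype = founder_full,
         founder_id = chrom_ids(ancestral)[founder_id],
         breakpoints = tibble(chrom_id = rownames(geno),
                              left_bp = b_left, right_bp = b_right),
         new_mutation_positions = setNames(mut_pos, rownames(geno)),
         params = p),
    class = "sweep_sim_truth")
  list(hap = hap, truth = truth)
}

#' Combine ancestral and derived panels over the union of sites
#'
#' Sites absent from one panel are filled with allele code 0 there — new
#' mutations on the derived lineage (and the core allele) are genuinely
#' absent from ancestral chromosomes.
#'
#' @param ancestral,derived [hap_matrix()] objects from the simulator.
#' @return A single [hap_matrix()] with ancestral chromosomes first.
#' @export
combine_panels <- function(ancestral, derived) {
  key <- function(s) paste(s$chrom, s$pos)
  sites <- rbind(ancestral$sites, derived$sites)
  sites <- sites[!duplicated(key(sites)), ]
  sites <- sites[order(sites$chrom, sites$pos), ]
  expand <- function(hap) {
    idx <- match(key(sites), key(hap$sites))
    g <- matrix(0L, nrow = n_chrom(hap), ncol = nrow(sites))
    g[, !is.na(idx)] <- hap$geno[, idx[!is.na(idx)], drop = FALSE]
    rownames(g) <- chrom_ids(hap)
    g
  }
  hap_matrix(sites, rbind(expand(ancestral), expand(derived)))
}

#' Pair simulated chromosomes into diploid individuals
#'
#' Forms individuals with the requested genotype counts at the core
#' (hom-ancestral / het / hom-derived) and assigns phenotypes under the
#' inheritance mode: recessive — melanistic iff homozygous derived;
#' dominant — melanistic iff carrying at least one derived chromosome.
#'
#' @param ancestral,derived Panels from the simulator (pre-combination).
#' @param genotypes Named integer vector
#'   `c(hom_ancestral=, het=, hom_derived=)`; must use every chromosome:
#'   `2*hom_derived + het == n_der` and `2*hom_ancestral + het == n_anc`.
#' @param mode `"recessive"` or `"dominant"`.
#' @param species Species label written to metadata.
#' @return A list: `hap` (combined, chromosomes relabelled
#'   `ind01_A`, ... in individual order) and `meta` (tibble `sample_id`,
#'   `species`, `phenotype`).
#' @export
pair_into_individuals <- function(ancestral, derived,
                                  genotypes = c(hom_ancestral = 2L, het = 6L,
                                                hom_derived = 9L),
                                  mode = c("recessive", "dominant"),
                                  species = "synthetic") {
  mode <- match.arg(mode)
  g <- as.integer(genotypes[c("hom_ancestral", "het", "hom_derived")])
  if (anyNA(g)) abort("genotypes needs hom_ancestral, het, hom_derived",
                      class = "sweepwatch_error")
  if (2L * g[3] + g[2] != n_chrom(derived) ||
      2L * g[1] + g[2] != n_chrom(ancestral)) {
    abort(sprintf(paste0("cannot pair chromosomes: genotypes need %d derived ",
                         "and %d ancestral, have %d and %d"),
                  2L * g[3] + g[2], 2L * g[1] + g[2],
                  n_chrom(derived), n_chrom(ancestral)),
          class = "sweepwatch_error")
  }
  combined <- combine_panels(ancestral, derived)
  anc_ids <- chrom_ids(ancestral)
  der_ids <- chrom_ids(derived)
  n_ind <- sum(g)
  # individual i gets chromosome pair (A, B); order: hom_derived, het, hom_ancestral
  pairs <- c(
    lapply(seq_len(g[3]), function(i) der_ids[c(2 * i - 1, 2 * i)]),
    lapply(seq_len(g[2]), function(i) c(der_ids[2 * g[3] + i], anc_ids[i])),
    lapply(seq_len(g[1]), function(i) anc_ids[g[2] + c(2 * i - 1, 2 * i)])
  )
  n_derived_alleles <- rep(c(2L, 1L, 0L), times = g[c(3, 2, 1)])
  ids <- sprintf("ind%02d", seq_len(n_ind))
  hap <- hap_subset(combined, chroms = unlist(pairs))
  rownames(hap$geno) <- as.vector(rbind(paste0(ids, "_A"), paste0(ids, "_B")))
  phenotype <- if (mode == "recessive") {
    ifelse(n_derived_alleles == 2L, "melanistic", "non_melanistic")
  } else {
    ifelse(n_derived_alleles >= 1L, "melanistic", "non_melanistic")
  }
  list(hap = hap,
       meta = tibble(sample_id = ids, species = species, phenotype = phenotype))
}

#' Write a complete synthetic dataset to disk
#'
#' Runs the simulator, pairs chromosomes into individuals, and writes the
#' four files the scan pipeline consumes: a phased VCF, a metadata TSV, a
#' BED of tiling windows, and a ground-truth JSON. Byte-identical across
#' runs with identical parameters.
#'
#' @param params A [sweep_sim_params()].
#' @param dir Output directory (created if needed).
#' @param genotypes,mode,species Passed to [pair_into_individuals()];
#'   `genotypes = NULL` pairs chromosomes within class (no heterozygotes;
#'   requires even `n_anc` and `n_der`).
#' @param n_windows Number of tiling windows written to the BED. The
#'   default (9, odd) places the default mid-interval core variant at the
#'   centre of the middle window, mirroring a capture design where the
#'   causal site lies inside a fosmid rather than on a boundary.
#' @return Invisibly, a list: `hap`, `meta`, `windows`, `truth`, `core`
#'   (the [core_variant()] of the simulated sweep) and `paths`.
#' @export
emit_dataset <- function(params, dir, genotypes = NULL,
                         mode = c("recessive", "dominant"),
                         species = "synthetic", n_windows = 9) {
  mode <- match.arg(mode)
  if (is.null(genotypes)) {
    if (params$n_anc %% 2L != 0L || params$n_der %% 2L != 0L) {
      abort("odd chromosome counts cannot be paired without heterozygotes",
            class = "sweepwatch_error")
    }
    genotypes <- c(hom_ancestral = params$n_anc %/% 2L, het = 0L,
                   hom_derived = params$n_der %/% 2L)
  }
  anc <- simulate_ancestral_panel(params)
  sw <- simulate_sweep_class(params, anc)
  paired <- pair_into_individuals(anc, sw$hap, genotypes = genotypes,
                                  mode = mode, species = species)
  windows <- make_tiling_windows(params$L, n = n_windows, chrom = params$contig)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(vcf = file.path(dir, "panel.vcf"),
                metadata = file.path(dir, "samples.tsv"),
                windows = file.path(dir, "windows.bed"),
                truth = file.path(dir, "truth.json"))
  write_phased_vcf(paired$hap, paths$vcf)
  readr::write_tsv(paired$meta, paths$metadata)
  write_windows(windows, paths$windows)
  write_sim_truth(sw$truth, paths$truth)
  core <- core_variant(params$contig, params$core_pos, 1L, mode = mode,
                       name = "simulated core")
  invisible(list(hap = paired$hap, meta = paired$meta, windows = windows,
                 truth = sw$truth, core = core, paths = paths))
}

#' Write / read simulator ground truth as JSON
#'
#' @param truth A `sweep_sim_truth` from [simulate_sweep_class()].
#' @param path JSON path.
#' @return `write_sim_truth()` returns `path` invisibly;
#'   `read_sim_truth()` reconstructs the `sweep_sim_truth`.
#' @export
write_sim_truth <- function(truth, path) {
  obj <- list(
    founder_haplotype = truth$founder_haplotype,
    founder_id = truth$founder_id,
    breakpoints = truth$breakpoints,
    new_mutation_positions = lapply(truth$new_mutation_positions, as.integer),
    params = unclass(truth$params)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(founder_haplotype = as.integer(obj$founder_haplotype),
         founder_id = obj$founder_id,
         breakpoints = as_tibble(obj$breakpoints),
         new_mutation_positions = lapply(obj$new_mutation_positions, as.integer),
         params = do.call(sweep_sim_params, obj$params)),
    class = "sweep_sim_truth")
}
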
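#' Classify chromosomes and individuals at the core variant
#'
#' Chromosome class is determined solely by the allele carried at the core
#' site (`derived` / `ancestral`); individual class comes from the
#' phenotype metadata. Genotypes inconsistent with the inheritance mode
#' (e.g. a melanistic heterozygote under a recessive model, or a
#' melanistic homozygous-ancestral individual under either model) are
#' reported as violations, never silently dropped: a heterozygous
#' individual still contributes one chromosome to each class.
#'
#' @param hap A [hap_matrix()] with `<sample>_A`/`<sample>_B` ids.
#' @param core A [core_variant()] present in `hap` (its `mode` drives the
#'   consistency check).
#' @param meta Metadata tibble covering every sample.
#' @return An object of class `chrom_classing`: list of tibbles
#'   `chromosomes` (`chrom_id`, `sample_id`, `class`), `individuals`
#'   (`sample_id`, `phenotype`, `derived_dosage`) and `violations`
#'   (`sample_id`, `phenotype`, `derived_dosage`, `reason`).
#' @export
classify <- function(hap, core, meta) {
  i <- core_site_index(hap, core)
  ids <- chrom_ids(hap)
  samples <- sub("_[AB]$", "", ids)
  missing <- setdiff(unique(samples), meta$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("sample(s) missing from metadata: %s",
                  paste(missing, collapse = ", ")),
          class = "sweepwatch_error")
  }
  is_derived <- hap$geno[, i] == core$derived_allele_code
  chromosomes <- tibble(chrom_id = ids, sample_id = samples,
                        class = ifelse(is_derived, "derived", "ancestral"))
  dosage <- tapply(as.integer(is_derived), samples, sum)
  individuals <- tibble(sample_id = names(dosage),
                        phenotype = setNames(meta$phenotype,
                                             meta$sample_id)[names(dosage)],
                        derived_dosage = as.integer(dosage))
  expected_mel <- if (core$mode == "recessive") {
    individuals$derived_dosage == 2L
  } else {
    individuals$derived_dosage >= 1L
  }
  observed_mel <- individuals$phenotype == "melanistic"
  bad <- expected_mel != observed_mel
  violations <- individuals[bad, ]
  violations$reason <- sprintf(
    "phenotype %s inconsistent with dosage %d under %s model",
    violations$phenotype, violations$derived_dosage, core$mode)
  structure(list(chromosomes = chromosomes, individuals = individuals,
                 violations = violations),
            class = "chrom_classing")
}

#' @export
print.chrom_classing <- function(x, ...) {
  tab <- table(x$chromosomes$class)
  cat(sprintf("<chrom_classing> %d derived / %d ancestral chromosomes; %d individuals; %d violation(s)\n",
              tab["derived"], tab["ancestral"],
              nrow(x$individuals), nrow(x$violations)))
  invisible(x)
}

#' Run the full selective-sweep scan
#'
#' Orchestrates the pipeline: read inputs, classify chromosomes at the
#' core variant, tabulate the genotype-phenotype association, compute
#' windowed diversity profiles under both stratifications, haplotype
#' counts per window and class, EHH curves and bifurcation trees.
#' Deterministic given identical inputs; pass `out_dir` to also write all
#' tables ([write_scan_report()]).
#'
#' @param vcf Path to a phased VCF.
#' @param metadata Path to the sample metadata TSV.
#' @param windows Path to the windows BED.
#' @param core A [core_variant()], or a spec string
#'   `"chrom:pos:derived_code:mode"` (e.g. `"chrA3:120000:1:recessive"`).
#' @param out_dir Optional output directory for the report files.
#' @param denominator Diversity denominator, see [nucleotide_diversity()].
#' @param bifurcation_max_sites Site cap for the bifurcation trees.
#' @return An object of class `scan_report`: list with `association`
#'   (one-row tibble), `classing`, `diversity_by_chromosome`,
#'   `diversity_by_individual`, `haplotype_counts`, `ehh`, `bifurcation`
#'   (named list of four trees), and `log` (versions, config, config
#'   hash).
#' @export
run_scan <- function(vcf, metadata, windows, core, out_dir = NULL,
                     denominator = c("bp", "variant_sites"),
                     bifurcation_max_sites = 50) {
  denominator <- match.arg(denominator)
  for (p in c(vcf, metadata, windows)) {
    if (!file.exists(p)) {
      abort(sprintf("input file not found: %s", p), class = "sweepwatch_io_error")
    }
  }
  if (is.character(core)) core <- parse_core_spec(core)
  hap <- with_stage("hapio", read_phased_vcf(vcf))
  meta <- with_stage("hapio", read_metadata(metadata))
  wins <- with_stage("hapio", read_windows(windows))
  classing <- with_stage("classify", classify(hap, core, meta))
  gt <- with_stage("assoc", genotype_table_from_calls(hap, core, meta))
  association <- with_stage("assoc", melanism_summary(gt, mode = core$mode))
  div_chrom <- with_stage("divstats",
    diversity_profile(hap, wins, classing, by = "chromosome_class",
                      denominator = denominator))
  div_ind <- with_stage("divstats",
    diversity_profile(hap, wins, classing, by = "individual_class",
                      denominator = denominator))
  groups <- class_members(hap, classing, "chromosome_class")
  hap_counts <- purrr::map_dfr(seq_len(nrow(wins)), function(w) {
    purrr::map_dfr(names(groups), function(cl) {
      tibble(window = wins$label[w], class = cl,
             n_chrom = length(groups[[cl]]),
             n_haplotypes = if (length(groups[[cl]]) > 0)
               haplotype_count(hap, wins[w, ], chroms = groups[[cl]])
             else NA_integer_)
    })
  })
  ehh <- with_stage("ehh", ehh_curve(hap, core))
  bif <- with_stage("ehh", {
    combos <- expand.grid(class = c("derived", "ancestral"),
                          direction = c("upstream", "downstream"),
                          stringsAsFactors = FALSE)
    setNames(
      purrr::map(seq_len(nrow(combos)), function(k)
        bifurcation_tree(hap, core, combos$class[k], combos$direction[k],
                         max_sites = bifurcation_max_sites)),
      paste(combos$class, combos$direction, sep = "_"))
  })
  config <- list(vcf = vcf, metadata = metadata, windows = windows,
                 core = unclass(core), denominator = denominator,
                 bifurcation_max_sites = bifurcation_max_sites)
  report <- structure(
    list(association = association, classing = classing,
         diversity_by_chromosome = div_chrom,
         diversity_by_individual = div_ind,
         haplotype_counts = hap_counts, ehh = ehh, bifurcation = bif,
         log = list(package = "sweepwatch",
                    version = as.character(utils::packageVersion("sweepwatch")),
                    config = config, config_hash = config_hash(config))),
    class = "scan_report")
  if (!is.null(out_dir)) write_scan_report(report, out_dir)
  report
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)),
          class = "sweepwatch_stage_error", parent = e)
  })
}

# md5 of the deparsed config; stable across runs for identical configs.
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

#' Parse a core-variant spec string
#'
#' @param spec `"chrom:pos:derived_code:mode"`,
#'   e.g. `"chrA3:120000:1:recessive"`.
#' @return A [core_variant()].
#' @export
parse_core_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 4) {
    abort("core spec must be chrom:pos:derived_code:mode",
          class = "sweepwatch_parse_error")
  }
  core_variant(parts[1], as.integer(parts[2]), as.integer(parts[3]), parts[4])
}

#' Write every table of a scan report to a directory
#'
#' TSVs for the tabular results, JSON for the bifurcation trees and the
#' run log. Output is deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report A `scan_report` from [run_scan()].
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_scan_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    association = file.path(dir, "association.tsv"),
    diversity_by_chromosome = file.path(dir, "diversity_by_chromosome.tsv"),
    diversity_by_individual = file.path(dir, "diversity_by_individual.tsv"),
    haplotype_counts = file.path(dir, "haplotype_counts.tsv"),
    ehh = file.path(dir, "ehh.tsv"),
    violations = file.path(dir, "violations.tsv"))
  readr::write_tsv(report$association, paths["association"])
  readr::write_tsv(report$diversity_by_chromosome, paths["diversity_by_chromosome"])
  readr::write_tsv(report$diversity_by_individual, paths["diversity_by_individual"])
  readr::write_tsv(report$haplotype_counts, paths["haplotype_counts"])
  readr::write_tsv(as_tibble(report$ehh), paths["ehh"])
  readr::write_tsv(report$classing$violations, paths["violations"])
  for (nm in names(report$bifurcation)) {
    p <- file.path(dir, sprintf("bifurcation_%s.json", nm))
    write_bifurcation_json(report$bifurcation[[nm]], p)
    paths[paste0("bifurcation_", nm)] <- p
  }
  log_path <- file.path(dir, "run_log.json")
  jsonlite::write_json(report$log, log_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["log"] <- log_path
  invisible(paths)
}

#' @export
print.scan_report <- function(x, ...) {
  cat("<scan_report>\n")
  cat(sprintf("  association: chi2 = %.4g, allele freq = %s\n",
              x$association$chi2, x$association$allele_freq_rendered))
  cat(sprintf("  diversity: %d windows x 2 classes (both stratifications)\n",
              length(unique(x$diversity_by_chromosome$window))))
  cat(sprintf("  ehh: %d points; bifurcation trees: %d\n",
              nrow(x$ehh), length(x$bifurcation)))
  cat(sprintf("  violations: %d; config hash %s\n",
              nrow(x$classing$violations), x$log$config_hash))
  invisible(x)
}

#' @method glance scan_report
#' @export
glance.scan_report <- function(x, ...) {
  tibble(n_individuals = nrow(x$classing$individuals),
         n_chromosomes = nrow(x$classing$chromosomes),
         n_windows = length(unique(x$diversity_by_chromosome$window)),
         n_violations = nrow(x$classing$violations),
         chi2 = x$association$chi2,
         allele_freq = x$association$allele_freq,
         config_hash = x$log$config_hash)
}
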
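# Chromosome ids belonging to a core-allele class.
class_chromosomes <- function(hap, core, allele_class = c("derived", "ancestral")) {
  allele_class <- match.arg(allele_class)
  i <- core_site_index(hap, core)
  want <- if (allele_class == "derived") core$derived_allele_code
          else 1L - core$derived_allele_code
  chrom_ids(hap)[hap$geno[, i] == want]
}

# Homozygosity of a grouping: sum C(c_h, 2) / C(n, 2).
group_homozygosity <- function(group_ids) {
  n <- length(group_ids)
  cnt <- tabulate(group_ids)
  sum(choose(cnt, 2)) / choose(n, 2)
}

#' Extended haplotype homozygosity at a target site
#'
#' Probability that two randomly chosen chromosomes of a core-allele class
#' are identical over every site from the core to the target, inclusive:
#' the class is grouped by its extended haplotypes and
#' `EHH = sum_h C(c_h, 2) / C(n, 2)`. At the target = core this is exactly
#' 1 (the class shares the core allele by definition).
#'
#' @param hap A [hap_matrix()].
#' @param core A [core_variant()] present in `hap`.
#' @param allele_class `"derived"` or `"ancestral"`.
#' @param target_pos Position (1-based) of a site present in `hap`.
#' @return EHH in `[0, 1]`; `NA` if the class has fewer than 2 chromosomes.
#' @export
ehh_at <- function(hap, core, allele_class = c("derived", "ancestral"),
                   target_pos) {
  allele_class <- match.arg(allele_class)
  j <- which(hap$sites$chrom == core$chrom & hap$sites$pos == target_pos)
  if (length(j) != 1) {
    abort(sprintf("no site at target position %s:%d", core$chrom, target_pos),
          class = "sweepwatch_error")
  }
  i <- core_site_index(hap, core)
  ids <- class_chromosomes(hap, core, allele_class)
  if (length(ids) < 2) return(NA_real_)
  span <- seq(min(i, j), max(i, j))
  g <- hap$geno[ids, span, drop = FALSE]
  strings <- apply(g, 1, paste, collapse = "")
  group_homozygosity(match(strings, unique(strings)))
}

#' EHH curves away from the core variant, both directions
#'
#' Evaluates EHH for the derived and ancestral classes at every site
#' position moving upstream (decreasing position) and downstream
#' (increasing position) of the core. Relative EHH is
#' `ehh_derived / ehh_ancestral`, undefined (`NA`, not 0 or Inf) wherever
#' the ancestral EHH has reached 0; both class curves are reported in full
#' either way. EHH is non-increasing with distance along each direction by
#' construction.
#'
#' @param hap A [hap_matrix()].
#' @param core A [core_variant()] present in `hap`; both classes need at
#'   least 2 chromosomes.
#' @return A tibble of class `ehh_curves`: `direction`, `pos`,
#'   `distance_bp`, `ehh_derived`, `ehh_ancestral`, `rel_ehh`. The core
#'   site appears in both directions at distance 0 with EHH 1.
#' @export
ehh_curve <- function(hap, core) {
  i <- core_site_index(hap, core)
  classes <- list(derived = class_chromosomes(hap, core, "derived"),
                  ancestral = class_chromosomes(hap, core, "ancestral"))
  small <- names(classes)[lengths(classes) < 2]
  if (length(small) > 0) {
    abort(sprintf("allele class too small for EHH: %s",
                  paste(small, collapse = ", ")),
          class = "sweepwatch_error")
  }
  one_direction <- function(direction) {
    span <- if (direction == "upstream") rev(seq_len(i)) else seq(i, n_sites(hap))
    curves <- lapply(classes, function(ids) {
      g <- hap$geno[ids, span, drop = FALSE]
      grp <- rep(1L, length(ids))
      vapply(seq_along(span), function(k) {
        grp <<- match(paste(grp, g[, k]), unique(paste(grp, g[, k])))
        group_homozygosity(grp)
      }, numeric(1))
    })
    tibble(direction = direction,
           pos = hap$sites$pos[span],
           distance_bp = abs(hap$sites$pos[span] - core$pos),
           ehh_derived = curves$derived,
           ehh_ancestral = curves$ancestral,
           rel_ehh = ifelse(curves$ancestral > 0,
                            curves$derived / curves$ancestral, NA_real_))
  }
  out <- dplyr::bind_rows(one_direction("upstream"), one_direction("downstream"))
  class(out) <- c("ehh_curves", class(out))
  out
}

#' Haplotype bifurcation tree from the core variant
#'
#' Tracks how the chromosomes of one core-allele class split into distinct
#' extended haplotypes moving away from the core: the root holds the whole
#' class at the core site; at each successive site every node's chromosome
#' set is split by the allele carried there. Branch thickness in a
#' bifurcation diagram is the node count. Child order is deterministic
#' (allele 0 before 1).
#'
#' @param hap A [hap_matrix()].
#' @param core A [core_variant()] present in `hap`.
#' @param allele_class `"derived"` or `"ancestral"` (must be nonempty).
#' @param direction `"upstream"` (decreasing position) or `"downstream"`.
#' @param max_sites Optional cap on the number of sites walked away from
#'   the core (the tree of a large panel over hundreds of sites is mostly
#'   singleton paths; plots rarely need more than a few dozen splits).
#' @return A tibble of class `bifurcation_tree`: `node_id`, `parent_id`
#'   (`NA` for the root), `depth` (sites from the core), `pos` (site
#'   position reached), `allele` (allele taken at this split; `NA` for the
#'   root) and `count`. Attributes `class_size` and `direction`.
#' @export
bifurcation_tree <- function(hap, core,
                             allele_class = c("derived", "ancestral"),
                             direction = c("upstream", "downstream"),
                             max_sites = Inf) {
  allele_class <- match.arg(allele_class)
  direction <- match.arg(direction)
  i <- core_site_index(hap, core)
  ids <- class_chromosomes(hap, core, allele_class)
  if (length(ids) == 0) {
    abort(sprintf("no chromosomes in class '%s'", allele_class),
          class = "sweepwatch_error")
  }
  span <- if (direction == "upstream") rev(seq_len(i)) else seq(i, n_sites(hap))
  if (length(span) > max_sites) span <- span[seq_len(max_sites)]
  g <- hap$geno[ids, span, drop = FALSE]
  rows <- list(list(node_id = 1L, parent_id = NA_integer_, depth = 0L,
                    pos = hap$sites$pos[span[1]], allele = NA_integer_,
                    count = length(ids)))
  membership <- list(seq_along(ids))
  parent_ids <- 1L
  next_id <- 2L
  for (k in seq_along(span)[-1]) {
    new_membership <- list()
    new_parent_ids <- integer()
    for (p in seq_along(membership)) {
      members <- membership[[p]]
      for (al in 0:1) {
        sub <- members[g[members, k] == al]
        if (length(sub) == 0) next
        rows[[length(rows) + 1L]] <- list(
          node_id = next_id, parent_id = parent_ids[p], depth = k - 1L,
          pos = hap$sites$pos[span[k]], allele = al, count = length(sub))
        new_membership[[length(new_membership) + 1L]] <- sub
        new_parent_ids <- c(new_parent_ids, next_id)
        next_id <- next_id + 1L
      }
    }
    membership <- new_membership
    parent_ids <- new_parent_ids
  }
  nodes <- dplyr::bind_rows(rows)
  structure(nodes, class = c("bifurcation_tree", class(nodes)),
            class_size = length(ids), direction = direction,
            allele_class = allele_class)
}

#' Convert a bifurcation tree to a nested list (for JSON output)
#'
#' @param tree A [bifurcation_tree()].
#' @return A nested list `{pos, allele, count, children}` rooted at the core.
#' @export
bifurcation_as_list <- function(tree) {
  build <- function(id) {
    row <- tree[tree$node_id == id, ]
    kids <- tree$node_id[!is.na(tree$parent_id) & tree$parent_id == id]
    out <- list(pos = row$pos, count = row$count)
    if (!is.na(row$allele)) out$allele <- row$allele
    if (length(kids) > 0) out$children <- lapply(kids, build)
    out
  }
  build(tree$node_id[is.na(tree$parent_id)])
}

#' @rdname bifurcation_as_list
#' @param path JSON output path.
#' @export
write_bifurcation_json <- function(tree, path) {
  jsonlite::write_json(bifurcation_as_list(tree), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
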
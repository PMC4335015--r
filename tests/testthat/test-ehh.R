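core_at <- function(pos, code = 1L) core_variant("chrT", pos, code, "recessive")

test_that("EHH at the core is 1 and matches hand-enumerated pair counts", {
  # 4 derived chromosomes whose extended haplotypes are {A, A, B, C}
  g <- rbind(c(1L, 0L, 0L),   # A
             c(1L, 0L, 0L),   # A
             c(1L, 0L, 1L),   # B
             c(1L, 1L, 0L),   # C
             c(0L, 0L, 0L))   # ancestral
  hap <- make_hap(g, pos = c(100L, 200L, 300L))
  core <- core_at(100)
  expect_equal(ehh_at(hap, core, "derived", 100), 1)
  expect_equal(ehh_at(hap, core, "derived", 300), 1 / 6)
  # all extended haplotypes distinct -> 0
  g2 <- rbind(c(1L, 0L, 0L), c(1L, 0L, 1L), c(1L, 1L, 0L), c(1L, 1L, 1L))
  hap2 <- make_hap(g2, pos = c(100L, 200L, 300L))
  expect_equal(ehh_at(hap2, core, "derived", 300), 0)
  # fewer than two chromosomes in class -> undefined
  expect_equal(ehh_at(hap2, core, "ancestral", 300), NA_real_)
})

test_that("EHH matches the brute-force pair oracle on random matrices", {
  for (case in 1:30) {
    n <- sample(4:12, 1)
    m <- sample(3:20, 1)
    hap <- random_hap(n, m, seed = 2000 + case)
    ci <- sample(m, 1)
    core <- core_at(hap$sites$pos[ci])
    for (cls in c("derived", "ancestral")) {
      code <- if (cls == "derived") 1L else 0L
      rows <- hap$geno[, ci] == code
      if (sum(rows) < 2) next
      tj <- sample(m, 1)
      expect_equal(ehh_at(hap, core, cls, hap$sites$pos[tj]),
                   oracle_ehh(hap$geno[rows, , drop = FALSE], ci, tj),
                   label = sprintf("case %d class %s", case, cls))
    }
  }
})

test_that("EHH curves are monotone non-increasing and agree with pointwise EHH", {
  hap <- random_hap(12, 25, seed = 123)
  core <- core_at(hap$sites$pos[13])
  curves <- ehh_curve(hap, core)
  for (dir in c("upstream", "downstream")) {
    cc <- curves[curves$direction == dir, ]
    cc <- cc[order(cc$distance_bp), ]
    expect_true(all(diff(cc$ehh_derived) <= 1e-12))
    expect_true(all(diff(cc$ehh_ancestral) <= 1e-12))
    expect_equal(cc$ehh_derived[1], 1)
    expect_equal(cc$ehh_ancestral[1], 1)
  }
  # consistency with ehh_at at arbitrary targets
  for (tj in c(1, 7, 20, 25)) {
    pos <- hap$sites$pos[tj]
    row <- curves[curves$pos == pos &
                    curves$direction == if (tj <= 13) "upstream" else "downstream", ]
    expect_equal(row$ehh_derived[1], ehh_at(hap, core, "derived", pos))
    expect_equal(row$ehh_ancestral[1], ehh_at(hap, core, "ancestral", pos))
  }
  # relative EHH is undefined (NA), not 0 or Inf, where ancestral EHH is 0
  zero_anc <- curves$ehh_ancestral == 0
  if (any(zero_anc)) expect_true(all(is.na(curves$rel_ehh[zero_anc])))
  expect_true(all(is.finite(curves$rel_ehh[!zero_anc])))
})

test_that("flipping allele labels at non-core sites leaves EHH unchanged", {
  hap <- random_hap(10, 20, seed = 321)
  # first site where both core-allele classes have at least two chromosomes
  ci <- which(colSums(hap$geno) >= 2 & colSums(1 - hap$geno) >= 2)[1]
  core <- core_at(hap$sites$pos[ci])
  before <- ehh_curve(hap, core)
  flipped <- hap
  flip <- setdiff(sample(20, 8), ci)
  flipped$geno[, flip] <- 1L - flipped$geno[, flip]
  after <- ehh_curve(flipped, core)
  expect_equal(after$ehh_derived, before$ehh_derived)
  expect_equal(after$ehh_ancestral, before$ehh_ancestral)
})

test_that("a sweep with no recombination or mutation keeps derived EHH at 1", {
  p <- sweep_sim_params(rG = 0, muG = 0, seed = 9, n_sites = 100)
  anc <- simulate_ancestral_panel(p)
  sw <- simulate_sweep_class(p, anc)
  comb <- combine_panels(anc, sw$hap)
  curves <- ehh_curve(comb, core_variant(p$contig, p$core_pos, 1L))
  expect_true(all(curves$ehh_derived == 1))
})

test_that("derived EHH dominates ancestral EHH under sweep parameters", {
  hits <- vapply(1:20, function(s) {
    p <- sweep_sim_params(seed = 600 + s, muG = 0)
    anc <- simulate_ancestral_panel(p)
    sw <- simulate_sweep_class(p, anc)
    comb <- combine_panels(anc, sw$hap)
    curves <- ehh_curve(comb, core_variant(p$contig, p$core_pos, 1L))
    nearby <- curves$distance_bp > 0 & curves$distance_bp <= 1e5
    all(curves$ehh_derived[nearby] >= curves$ehh_ancestral[nearby])
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("bifurcation trees split counts conservatively with deterministic order", {
  # haplotypes {00, 01, 11} rightward from the core
  g <- rbind(c(1L, 0L, 0L), c(1L, 0L, 1L), c(1L, 1L, 1L))
  hap <- make_hap(g, pos = c(100L, 200L, 300L), ids = c("a_A", "a_B", "b_A"))
  tree <- bifurcation_tree(hap, core_at(100), "derived", "downstream")
  expect_equal(tree$count[tree$depth == 0], 3L)
  d1 <- tree[tree$depth == 1, ]
  expect_equal(d1$allele, c(0L, 1L))        # allele 0 before 1
  expect_equal(d1$count, c(2L, 1L))
  d2 <- tree[tree$depth == 2, ]
  expect_equal(d2$count, c(1L, 1L, 1L))
  # all chromosomes identical -> a path with full counts
  same <- make_hap(matrix(1L, 4, 3), pos = c(100L, 200L, 300L))
  path_tree <- bifurcation_tree(same, core_at(100), "derived", "downstream")
  expect_equal(path_tree$count, rep(4L, 3))
  expect_equal(path_tree$depth, 0:2)
})

test_that("node counts are conserved and reproduce the EHH curve", {
  for (case in 1:5) {
    hap <- random_hap(10, 15, seed = 3000 + case)
    ci <- 8
    core <- core_at(hap$sites$pos[ci])
    if (min(sum(hap$geno[, ci] == 1L), sum(hap$geno[, ci] == 0L)) < 2) next
    for (dir in c("upstream", "downstream")) {
      tree <- bifurcation_tree(hap, core, "derived", dir)
      # each internal node's count equals the sum of its children
      kids <- split(tree$count[!is.na(tree$parent_id)],
                    tree$parent_id[!is.na(tree$parent_id)])
      for (pid in names(kids)) {
        expect_equal(sum(kids[[pid]]), tree$count[tree$node_id == as.integer(pid)])
      }
      # leaves sum to the class size
      leaves <- tree[!tree$node_id %in% tree$parent_id, ]
      max_depth <- max(tree$depth)
      expect_equal(sum(leaves$count[leaves$depth == max_depth]) +
                     sum(leaves$count[leaves$depth < max_depth]),
                   attr(tree, "class_size"))
      # EHH recomputed from node counts at each depth
      n <- attr(tree, "class_size")
      curves <- ehh_curve(hap, core)
      cc <- curves[curves$direction == dir, ]
      for (d in unique(tree$depth)) {
        cnt <- tree$count[tree$depth == d]
        expect_equal(sum(choose(cnt, 2)) / choose(n, 2),
                     cc$ehh_derived[d + 1])
      }
    }
  }
})

test_that("bifurcation trees serialise to nested JSON and back-compatible lists", {
  g <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L))
  hap <- make_hap(g, pos = c(100L, 200L), ids = c("a_A", "a_B", "b_A"))
  tree <- bifurcation_tree(hap, core_at(100), "derived", "downstream")
  lst <- bifurcation_as_list(tree)
  expect_equal(lst$count, 3L)
  expect_equal(vapply(lst$children, `[[`, integer(1), "count"), c(2L, 1L))
  path <- tempfile(fileext = ".json")
  write_bifurcation_json(tree, path)
  round <- jsonlite::read_json(path)
  expect_equal(round$count, 3L)
})

test_that("simulated EHH decays at the 2 rG rate the founder model predicts", {
  p0 <- sweep_sim_params(n_der = 200, muG = 0)
  pts <- lapply(1:10, function(s) {
    p <- sweep_sim_params(seed = 700 + s, n_der = 200, muG = 0)
    anc <- simulate_ancestral_panel(p)
    sw <- simulate_sweep_class(p, anc)
    comb <- combine_panels(anc, sw$hap)
    curves <- ehh_curve(comb, core_variant(p$contig, p$core_pos, 1L))
    curves[curves$distance_bp > 0 & curves$distance_bp <= 1e5,
           c("distance_bp", "ehh_derived")]
  })
  df <- do.call(rbind, pts)
  bins <- cut(df$distance_bp, breaks = seq(0, 1e5, by = 5000))
  m <- tapply(df$ehh_derived, bins, mean)
  d <- tapply(df$distance_bp, bins, mean)
  keep <- !is.na(m) & m > 0.02
  slope <- unname(coef(lm(log(m[keep]) ~ d[keep]))[2])
  expect_lt(abs(slope / (-2 * p0$rG) - 1), 0.2)
})
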
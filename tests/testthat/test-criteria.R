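meta_for <- function(ids) {
  tibble::tibble(
    sample_id = ids,
    species_id = sub("[0-9]+$", "", ids),
    stage_label = paste0("t", sub("^[a-z]+", "", ids)),
    stage_ordinal = as.integer(sub("^[a-z]+", "", ids)) - 1L,
    replicate_id = "r1"
  )
}

test_that("species monophyly is read off bipartitions, singletons vacuously true", {
  phy <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  mono <- species_monophyly(phy, meta_for(c("a1", "a2", "b1", "b2")))
  expect_true(all(mono$monophyletic))
  phy2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  mono2 <- species_monophyly(phy2, meta_for(c("a1", "a2", "b1", "b2")))
  expect_false(any(mono2$monophyletic))
  phy3 <- ape::read.tree(text = "((a1:1,a2:1):1,c1:1);")
  mono3 <- species_monophyly(phy3, meta_for(c("a1", "a2", "c1")))
  expect_true(all(mono3$monophyletic))
  ## invariant to relabeling samples within a species
  phy4 <- phy
  phy4$tip.label <- c("a2", "a1", "b2", "b1")
  expect_true(all(species_monophyly(phy4, meta_for(phy4$tip.label))$monophyletic))
})

test_that("topology consistency collapses species and compares bipartitions", {
  ref <- ape::read.tree(text = "((((a:1,b:1):1,c:1):1,d:1):1,e:1);")
  samples <- c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2", "e1", "e2")
  good <- ape::read.tree(text = paste0(
    "(((((a1:1,a2:1):1,(b1:1,b2:1):1):1,(c1:1,c2:1):1):1,(d1:1,d2:1):1):1,",
    "(e1:1,e2:1):2);"))
  tc <- topology_consistency(good, ref, meta_for(samples))
  expect_equal(tc$rf, 0L)
  expect_true(tc$pass)

  ## one swapped cherry among 5 species: RF 2 (oracle: bipartition sets differ
  ## in exactly the ab vs ac split; verified by explicit enumeration below)
  swapped <- ape::read.tree(text = paste0(
    "(((((a1:1,a2:1):1,(c1:1,c2:1):1):1,(b1:1,b2:1):1):1,(d1:1,d2:1):1):1,",
    "(e1:1,e2:1):2);"))
  tc2 <- topology_consistency(swapped, ref, meta_for(samples))
  expect_equal(tc2$rf, 2L)
  expect_false(tc2$pass)
  biparts <- function(phy) {
    pp <- ape::prop.part(ape::unroot(phy))
    labs <- attr(pp, "labels")
    sets <- lapply(pp, function(i) sort(labs[i]))
    nt <- length(labs)
    keep <- lengths(sets) > 1 & lengths(sets) < nt - 1
    unique(vapply(sets[keep], paste, "", collapse = "|"))
  }
  ind <- ape::keep.tip(swapped, c("a1", "b1", "c1", "d1", "e1"))
  ind$tip.label <- sub("1$", "", ind$tip.label)
  b1 <- biparts(ind); b2 <- biparts(ref)
  expect_equal(length(setdiff(b1, b2)) + length(setdiff(b2, b1)), 2L)

  expect_error(topology_consistency(phy <- ape::read.tree(
    text = "((a1:1,b1:1):1,(a2:1,b2:1):1);"), ref,
    meta_for(c("a1", "a2", "b1", "b2"))), "not monophyletic")
  ref_small <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  expect_error(topology_consistency(good, ref_small, meta_for(samples)),
               "missing from reference")
})

test_that("GLCM descriptors match hand-enumerated windows", {
  const <- matrix(3L, 3, 3)
  g <- glcm_descriptors(const, levels = 8)
  expect_equal(g, c(contrast = 0, dissimilarity = 0, homogeneity = 1,
                    uniformity = 1, correlation = 1))
  ## 3x3 two-level checkerboard: all 12 (horizontal+vertical) co-occurrences
  ## are between unequal levels
  checker <- matrix(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L), 3, 3)
  gc <- glcm_descriptors(checker, levels = 2)
  expect_equal(gc[["contrast"]], 1)
  expect_equal(gc[["dissimilarity"]], 1)
  expect_equal(gc[["homogeneity"]], 0.5)
  expect_error(glcm_descriptors(matrix(0L, 1, 3), 2), "2x2")
  expect_error(glcm_descriptors(matrix(5L, 3, 3), 4), "levels")
})

test_that("GLCM bounds hold on random windows", {
  set.seed(3)
  for (i in 1:25) {
    w <- matrix(sample.int(8, 9, replace = TRUE) - 1L, 3, 3)
    g <- glcm_descriptors(w, 8)
    expect_gt(g[["homogeneity"]], 0); expect_lte(g[["homogeneity"]], 1)
    expect_gt(g[["uniformity"]], 0); expect_lte(g[["uniformity"]], 1)
    expect_gte(g[["correlation"]], -1); expect_lte(g[["correlation"]], 1)
    expect_gte(g[["contrast"]], g[["dissimilarity"]] - 1e-12)
  }
})

smooth_meta <- function(n_stages, species = "x") {
  tibble::tibble(
    sample_id = paste0(species, "_", seq_len(n_stages)),
    species_id = species,
    stage_label = as.character(seq_len(n_stages)),
    stage_ordinal = seq_len(n_stages) - 1L,
    replicate_id = "mean"
  )
}

test_that("smoothness wins sum to 100 and favor the smooth method", {
  set.seed(12)
  ids <- smooth_meta(6)$sample_id
  smooth_m <- outer(1:6, 1:6, function(a, b) abs(a - b) / 5)
  dimnames(smooth_m) <- list(ids, ids)
  noisy <- matrix(runif(36), 6, 6); noisy <- (noisy + t(noisy)) / 2
  diag(noisy) <- 0; dimnames(noisy) <- list(ids, ids)
  rep_ <- smoothness_scan(list(gradient = smooth_m, noise = noisy), smooth_meta(6))
  sums <- tapply(rep_$wins$win_pct, rep_$wins$descriptor, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  grad <- rep_$wins[rep_$wins$method == "gradient", ]
  expect_true(all(grad$win_pct[grad$descriptor %in%
                                 c("homogeneity", "uniformity")] == 100))
  ## a single supplied method wins everything
  rep1 <- smoothness_scan(list(only = smooth_m), smooth_meta(6))
  expect_true(all(rep1$wins$win_pct == 100))
  ## identical matrices tie and split fractionally
  rep2 <- smoothness_scan(list(a = smooth_m, b = smooth_m), smooth_meta(6))
  expect_true(all(abs(rep2$wins$win_pct - 50) < 1e-9))
})

test_that("species blocks with fewer than 3 stages are skipped with a warning", {
  ids <- c("x_1", "x_2")
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(ids, ids))
  expect_error(expect_warning(
    smoothness_scan(list(a = m), smooth_meta(2)), "fewer than 3"),
    "no species block")
})

test_that("the default scan enumerates 126 combinations deterministically", {
  sim <- small_sim(5)
  og <- sim_og_table(sim)
  st <- stage_mean_table(og, sim$meta)
  smeta <- attr(st, "stage_meta")
  scan <- scan_combinations(st, smeta, sim$species_tree)
  expect_s3_class(scan, "deriv_scan")
  expect_equal(nrow(scan), 126)    # 9 normalizations x 7 distances x 2 trees
  expect_equal(nrow(dplyr::distinct(scan[, 1:3])), 126)
  ## per-combo failures are recorded, not raised (z-scored values are negative,
  ## so jensen-shannon must error there)
  js_z <- scan[scan$normalization == "zscore" & scan$distance == "jensen_shannon", ]
  expect_true(all(!is.na(js_z$error)))
  ## restricting the grid to one of each gives one report
  one <- scan_combinations(st, smeta, sim$species_tree,
                           normalizations = table1_normalizations()["rank_ascending"],
                           distances = "spearman", tree_methods = "bionj")
  expect_equal(nrow(one), 1)
  expect_true(one$criterion1 & one$criterion2)
  expect_equal(glance(one)$n_pass_c12, 1)
})

test_that("criterion 2 is only evaluated where criterion 1 holds", {
  sim <- small_sim(6)
  og <- sim_og_table(sim)
  st <- stage_mean_table(og, sim$meta)
  smeta <- attr(st, "stage_meta")
  scan <- scan_combinations(st, smeta, sim$species_tree,
                            normalizations = table1_normalizations()[c(1, 4)],
                            distances = c("spearman", "euclidean"))
  failed_c1 <- scan[!is.na(scan$criterion1) & !scan$criterion1, ]
  expect_true(all(is.na(failed_c1$criterion2)))
  passed_c1 <- scan[!is.na(scan$criterion1) & scan$criterion1, ]
  expect_true(all(!is.na(passed_c1$criterion2_rf)))
})
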
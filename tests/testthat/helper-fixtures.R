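## Shared fixtures, built in code.

## Two species, two ortholog-groups; A has paralogs in og1, B lacks og1.
tiny_gene_tables <- function() {
  list(
    A = tibble::tibble(
      gene_id = c("gA1", "gA2", "gA3"),
      A_s1_r1 = c(2, 4, 1),
      A_s1_r2 = c(2, 4, 3),
      A_s2_r1 = c(0, 8, 5)
    ),
    B = tibble::tibble(
      gene_id = c("gB1"),
      B_s1_r1 = c(6),
      B_s2_r1 = c(2)
    )
  )
}

tiny_og_map <- function() {
  tibble::tibble(
    og_id = c("og1", "og1", "og2", "og2"),
    species_id = c("A", "A", "A", "B"),
    gene_id = c("gA1", "gA2", "gA3", "gB1")
  )
}

tiny_meta <- function() {
  tibble::tibble(
    sample_id = c("A_s1_r1", "A_s1_r2", "A_s2_r1", "B_s1_r1", "B_s2_r1"),
    species_id = c("A", "A", "A", "B", "B"),
    stage_label = c("s1", "s1", "s2", "s1", "s2"),
    stage_ordinal = c(0L, 0L, 1L, 0L, 1L),
    replicate_id = c("r1", "r2", "r1", "r1", "r1"),
    protocol = c("TruSeq", "TruSeq", "TruSeq", "QuartzSeq", "TruSeq"),
    mapped_best_hit_reads = c(100, 120, 90, 400, 410)
  )
}

## Small but fully structured simulation for pipeline-level tests.
small_sim <- function(seed = 1, stages_per_species = 5L, n_replicates = 2L,
                      n_ogs = 300L, ...) {
  simulate_transcriptomes(simulation_config(
    species_tree = "(((spA:0.4,spB:0.4):0.3,(spC:0.4,spD:0.4):0.3):0.4,spOUT:0.9);",
    stages_per_species = stages_per_species, n_replicates = n_replicates,
    n_ogs = n_ogs, seed = seed, ...))
}

sim_ingroup <- function(sim) setdiff(sim$species_tree$tip.label, sim$config$outgroup)

## OG table straight from a simulation (paralog-mean aggregation).
sim_og_table <- function(sim, ...) {
  suppressMessages(build_og_table(sim$tables, sim$og_map, ...))
}

## Mean-value pipeline recomposed from exported pieces (used to check that
## BRI machinery degenerates to it when each stage has a single replicate).
pipeline_tree_for_test <- function(og, meta, config = pipeline_config()) {
  st <- stage_mean_table(og, meta)
  infer_tree(pairwise_distance(normalize_table(st, config$normalization),
                               config$distance), config$tree_method)
}

## Random tree with strictly positive branch lengths (additive oracle).
random_additive_tree <- function(n) {
  phy <- ape::rtree(n, rooted = FALSE)
  phy$edge.length <- stats::runif(length(phy$edge.length), 0.1, 2)
  phy
}

expect_cophenetic_equal <- function(phy, d, tol = 1e-9) {
  got <- ape::cophenetic.phylo(phy)[rownames(d), colnames(d)]
  expect_lt(max(abs(got - d)), tol)
}
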
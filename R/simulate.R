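## Synthetic multi-species developmental transcriptomes with known truth.
##
## Model (log2 scale): each ortholog-group has a base level; the ancestral
## stage profile adds a stationary AR(1) trajectory over stages (gradual
## developmental change without unbounded drift). Expression evolves along
## the species tree as Brownian motion per group (variance = branch_rate^2 x
## branch length), and each species adds its own stationary AR(1) stage
## trajectory. Duplication emits paralogs with perturbed profiles, loss
## removes a group's genes for that species, replicates carry log-normal
## noise, and every sample column is rescaled to TPM (sum 1e6). A fraction
## of groups can be "planted" as derivedness-correlative: their expression
## decreases monotonically with the species' realized per-stage divergence
## from the ancestral profile.

#' Simulation configuration
#'
#' Defaults describe the package's reference study condition: 8 ingroup
#' species plus one outgroup on a fixed balanced tree, 10 stages, 3
#' replicates, with species divergence strong relative to within-species
#' stage change (embryos cluster by species, as observed for distantly
#' related taxa).
#'
#' @param species_tree Newick string with branch lengths (expected divergence
#'   units), including the outgroup.
#' @param outgroup Species id of the outgroup leaf.
#' @param stages_per_species Number of stages (>= 3).
#' @param n_replicates Replicates per stage (>= 1).
#' @param n_ogs Number of ortholog-groups.
#' @param duplication_prob Per (group, species) probability of a duplication
#'   (two paralogs).
#' @param loss_prob Per (group, species) probability the group is lost.
#' @param branch_rate Brownian step scale on log2 expression per unit branch
#'   length.
#' @param stage_drift Stationary standard deviation of the within-species
#'   stage process (log2 units).
#' @param ancestral_stage_sd Stationary sd of the ancestral stage profile.
#' @param stage_phi Lag-1 autocorrelation of the stage processes (smoothness
#'   of developmental change).
#' @param replicate_sd Log-normal replicate noise sd (natural-log scale).
#' @param base_log_mean,base_log_sd Mean and sd of per-group base log2
#'   expression.
#' @param paralog_sd Log-normal perturbation sd distinguishing paralogs.
#' @param planted_dco_fraction Fraction of groups planted as
#'   derivedness-correlative (testing device; recorded in the truth, never
#'   exposed in the emitted tables).
#' @param planted_noise_sd Log-normal noise sd applied to planted profiles.
#' @param seed Integer seed; same config + seed is bit-reproducible.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(
    species_tree = paste0("((((spA:0.3,spB:0.3):0.2,(spC:0.3,spD:0.3):0.2):0.2,",
                          "((spE:0.3,spF:0.3):0.2,(spG:0.3,spH:0.3):0.2):0.2):0.3,",
                          "spOUT:0.8);"),
    outgroup = "spOUT",
    stages_per_species = 10L,
    n_replicates = 3L,
    n_ogs = 2000L,
    duplication_prob = 0.1,
    loss_prob = 0.05,
    branch_rate = 1.5,
    stage_drift = 0.35,
    ancestral_stage_sd = 0.5,
    stage_phi = 0.8,
    replicate_sd = 0.1,
    base_log_mean = 3,
    base_log_sd = 2,
    paralog_sd = 0.25,
    planted_dco_fraction = 0,
    planted_noise_sd = 0.1,
    seed = 1L) {
  cfg <- list(species_tree = species_tree, outgroup = outgroup,
              stages_per_species = as.integer(stages_per_species),
              n_replicates = as.integer(n_replicates), n_ogs = as.integer(n_ogs),
              duplication_prob = duplication_prob, loss_prob = loss_prob,
              branch_rate = branch_rate, stage_drift = stage_drift,
              ancestral_stage_sd = ancestral_stage_sd, stage_phi = stage_phi,
              replicate_sd = replicate_sd, base_log_mean = base_log_mean,
              base_log_sd = base_log_sd, paralog_sd = paralog_sd,
              planted_dco_fraction = planted_dco_fraction,
              planted_noise_sd = planted_noise_sd, seed = as.integer(seed))
  for (p in c("duplication_prob", "loss_prob", "planted_dco_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(paste0(p, " must be in [0, 1]"))
  }
  for (p in c("branch_rate", "stage_drift", "ancestral_stage_sd",
              "replicate_sd", "paralog_sd", "planted_noise_sd")) {
    if (cfg[[p]] < 0) abort(paste0(p, " must be >= 0"))
  }
  if (cfg$stage_phi < 0 || cfg$stage_phi >= 1) abort("stage_phi must be in [0, 1)")
  if (cfg$stages_per_species < 3) abort("stages_per_species must be >= 3")
  if (cfg$n_replicates < 1) abort("n_replicates must be >= 1")
  if (cfg$n_ogs < 1) abort("n_ogs must be >= 1")
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Keys are the arguments of [simulation_config()]; see
#' `system.file("extdata", "example_sim_config.yaml", package = "derivtree")`.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the 'yaml' package is required to read YAML configs")
  }
  do.call(simulation_config, yaml::read_yaml(path))
}

## Stationary AR(1) stage process: n_ogs x stages, marginal sd `sd`.
ar1_stage_process <- function(n_ogs, stages, sd, phi) {
  w <- matrix(0, n_ogs, stages)
  if (sd == 0) return(w)
  w[, 1] <- rnorm(n_ogs, 0, sd)
  for (s in seq_len(stages)[-1]) {
    w[, s] <- phi * w[, s - 1] + rnorm(n_ogs, 0, sd * sqrt(1 - phi^2))
  }
  w
}

#' Simulate gene-level expression tables with known ground truth
#'
#' Emits exactly the inputs the pipeline consumes: per-species gene tables
#' (TPM; every column sums to 1e6), an ortholog-group map, sample metadata,
#' and the generating species tree, together with a `truth` record (per-group
#' fates, planted flags, ancestral profile, per-stage divergence, root-to-tip
#' depths).
#'
#' @param config A [simulation_config()].
#' @return List with elements `tables` (named list of tibbles), `og_map`,
#'   `meta`, `species_tree` (`phylo`), `config`, and `truth`.
#' @export
simulate_transcriptomes <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(cfg) {
  tr <- read_newick(text = cfg$species_tree)
  species <- tr$tip.label
  if (!cfg$outgroup %in% species) abort("outgroup must be a leaf of species_tree")
  n <- cfg$n_ogs; stages <- cfg$stages_per_species
  og_ids <- sprintf("og%05d", seq_len(n))
  stage_labels <- sprintf("s%02d", seq_len(stages))

  base <- rnorm(n, cfg$base_log_mean, cfg$base_log_sd)
  anc <- base + ar1_stage_process(n, stages, cfg$ancestral_stage_sd, cfg$stage_phi)
  rownames(anc) <- og_ids; colnames(anc) <- stage_labels

  ## Brownian per-group shifts accumulated root -> tip
  ntip <- length(species)
  ord <- ape::reorder.phylo(tr, "cladewise")
  shift <- matrix(0, n, ntip + tr$Nnode)
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    shift[, ch] <- shift[, par] +
      rnorm(n, 0, cfg$branch_rate * sqrt(ord$edge.length[e]))
  }
  tip_shift <- shift[, seq_len(ntip), drop = FALSE]
  colnames(tip_shift) <- species

  planted <- rep(FALSE, n)
  n_plant <- round(cfg$planted_dco_fraction * n)
  if (n_plant > 0) planted[sample.int(n, n_plant)] <- TRUE

  tables <- list(); meta_rows <- list(); map_rows <- list()
  fate_rows <- list(); div_rows <- list()
  for (sp in species) {
    w <- ar1_stage_process(n, stages, cfg$stage_drift, cfg$stage_phi)
    lg <- anc + tip_shift[, sp] + w
    ## realized per-stage divergence from the ancestral profile, decomposed
    ## into the species-wide shift plus the stage-specific component (the
    ## finite-size cross term is noise constant in expectation and omitted,
    ## so the stage ranking reflects genuine stage-specific divergence)
    d_anc <- sqrt(mean(tip_shift[, sp]^2) + colMeans(w^2))
    div_rows[[sp]] <- tibble(species_id = sp, stage_label = stage_labels,
                             stage_ordinal = seq_len(stages) - 1L,
                             divergence = unname(d_anc))
    tpm0 <- 2^lg
    if (any(planted)) {
      ## planted profile: monotone decreasing in this species' realized
      ## per-stage divergence from the ancestor (dynamic range ~16x)
      rk <- rank(d_anc, ties.method = "first")
      prof <- 2^(6 - 4 * (rk - 1) / (stages - 1))
      tpm0[planted, ] <- matrix(prof, sum(planted), stages, byrow = TRUE)
    }
    lost <- runif(n) < cfg$loss_prob
    dup <- !lost & (runif(n) < cfg$duplication_prob)
    fate_rows[[sp]] <- tibble(
      og_id = og_ids, species_id = sp,
      status = ifelse(lost, "lost", ifelse(dup, "duplicated", "retained")),
      n_paralogs = ifelse(lost, 0L, ifelse(dup, 2L, 1L))
    )
    keep <- which(!lost)
    np <- ifelse(dup[keep], 2L, 1L)
    gene_og <- rep(keep, np)
    paralog_no <- sequence(np)
    gene_ids <- paste0(sp, "_g", sub("^og", "", og_ids[gene_og]), "_p", paralog_no)
    gene_scale <- rep(1, length(gene_og))
    is_par <- gene_og %in% keep[dup[keep]]
    gene_scale[is_par] <- exp(rnorm(sum(is_par), 0, cfg$paralog_sd))
    map_rows[[sp]] <- tibble(og_id = og_ids[gene_og], species_id = sp,
                             gene_id = gene_ids)
    cols <- list()
    for (st in seq_len(stages)) {
      for (r in seq_len(cfg$n_replicates)) {
        noise <- exp(rnorm(length(gene_ids), 0, cfg$replicate_sd))
        is_pl <- planted[gene_og]
        if (any(is_pl)) {
          noise[is_pl] <- exp(rnorm(sum(is_pl), 0, cfg$planted_noise_sd))
        }
        x <- tpm0[gene_og, st] * gene_scale * noise
        x <- x / sum(x) * 1e6
        cols[[paste0(sp, "_", stage_labels[st], "_r", r)]] <- x
      }
    }
    tables[[sp]] <- dplyr::bind_cols(tibble(gene_id = gene_ids), tibble(!!!cols))
    meta_rows[[sp]] <- tidyr::expand_grid(
      stage_ordinal = seq_len(stages) - 1L,
      replicate = seq_len(cfg$n_replicates)
    ) |>
      dplyr::transmute(
        sample_id = paste0(sp, "_", stage_labels[.data$stage_ordinal + 1L],
                           "_r", .data$replicate),
        species_id = sp,
        stage_label = stage_labels[.data$stage_ordinal + 1L],
        stage_ordinal = .data$stage_ordinal,
        replicate_id = paste0("r", .data$replicate),
        protocol = "TruSeq"
      )
  }
  meta <- dplyr::bind_rows(meta_rows)
  meta$mapped_best_hit_reads <- round(runif(nrow(meta), 5e6, 2e7))
  depths <- ape::node.depth.edgelength(tr)[seq_len(ntip)]
  truth <- list(
    tree = tr,
    fates = dplyr::bind_rows(fate_rows),
    planted = tibble(og_id = og_ids, planted = planted),
    ancestral_profile = anc,
    stage_divergence = dplyr::bind_rows(div_rows),
    root_to_tip = tibble(species_id = species, depth = depths)
  )
  list(tables = tables, og_map = dplyr::bind_rows(map_rows), meta = meta,
       species_tree = tr, config = cfg, truth = truth)
}

#' Write a simulation to TSV / newick files
#'
#' Emits `<species>.expression.tsv` per species, `og_map.tsv`,
#' `metadata.tsv` and `species_tree.nwk` in `dir` — the exact dialects the
#' table-building and tree modules read back.
#'
#' @param sim Result of [simulate_transcriptomes()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$tables)) {
    write_expression_tsv(sim$tables[[sp]],
                         file.path(dir, paste0(sp, ".expression.tsv")))
  }
  readr::write_tsv(sim$og_map, file.path(dir, "og_map.tsv"), progress = FALSE)
  readr::write_tsv(sim$meta, file.path(dir, "metadata.tsv"), progress = FALSE)
  write_newick(sim$species_tree, file.path(dir, "species_tree.nwk"))
  invisible(dir)
}

#' How well the pipeline recovers the simulated ground truth
#'
#' @param sim Result of [simulate_transcriptomes()].
#' @param tree Unrooted stage-level tree inferred by the pipeline.
#' @param profile Optional derivedness profile over the stage-level samples
#'   (from the rooted tree); enables the divergence-vs-index correlation.
#' @param categories Optional tibble from [categorize_dco()]; with
#'   `clade`, enables planted-DCO sensitivity/specificity for the top
#'   category.
#' @param clade Species set used for `categories` (defaults to all ingroup
#'   species).
#' @return One-row tibble: `monophyly_rate`, `rf_to_truth`,
#'   `divergence_index_cor` (Spearman of true root-to-tip depth vs median
#'   index per ingroup species), `dco_sensitivity`, `dco_specificity`
#'   (`NA` where inputs were not supplied; sensitivity `NA` when nothing was
#'   planted).
#' @export
recovery_report <- function(sim, tree, profile = NULL, categories = NULL,
                            clade = NULL) {
  smeta <- stage_metadata(sim$meta)
  mono <- species_monophyly(tree, smeta)
  rf <- tryCatch(topology_consistency(tree, sim$species_tree, smeta)$rf,
                 error = function(e) NA_integer_)
  ingroup <- setdiff(sim$species_tree$tip.label, sim$config$outgroup)
  div_cor <- NA_real_
  if (!is.null(profile)) {
    sp_of <- setNames(smeta$species_id, smeta$sample_id)
    med <- tapply(profile$index, sp_of[profile$sample_id], median)
    med <- med[names(med) %in% ingroup]
    depth <- setNames(sim$truth$root_to_tip$depth, sim$truth$root_to_tip$species_id)
    div_cor <- suppressWarnings(cor(depth[names(med)], med, method = "spearman"))
  }
  sens <- spec <- NA_real_
  if (!is.null(categories)) {
    clade <- clade %||% ingroup
    top <- length(clade)
    pl <- setNames(sim$truth$planted$planted, sim$truth$planted$og_id)
    is_pl <- pl[categories$og_id]
    in_top <- categories$category == top
    sens <- if (any(is_pl)) mean(in_top[is_pl]) else NA_real_
    spec <- if (any(!is_pl)) mean(!in_top[!is_pl]) else NA_real_
  }
  tibble(monophyly_rate = mean(mono$monophyletic), rf_to_truth = rf,
         divergence_index_cor = div_cor,
         dco_sensitivity = sens, dco_specificity = spec)
}
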
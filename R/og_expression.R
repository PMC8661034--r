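## Ortholog-group expression tables.
##
## Per-species gene-level TPM tables are merged into one ortholog-group x
## sample matrix that is comparable across species: paralogs within a group
## are aggregated (mean by default), and a group with no gene in a species
## contributes an expression of exactly 0 for every sample of that species,
## so that gene loss is part of the measured signal rather than missing data.

#' Build an ortholog-group expression table
#'
#' Aggregates per-species gene-level expression tables into a single
#' ortholog-group table. For each group and sample, the value is the
#' `aggregator` (mean or sum) of the TPMs of that species' member genes;
#' species with no gene in a group get exactly 0. Genes present in a species
#' table but absent from the ortholog-group map are species-specific; by
#' default they are dropped (with a message), or retained as singleton groups
#' via `keep_species_specific`.
#'
#' @param tables Named list of per-species gene expression tibbles (first
#'   column `gene_id`, remaining columns numeric sample TPMs); names are
#'   species ids.
#' @param og_map Tibble with columns `og_id`, `species_id`, `gene_id`, one
#'   gene per row.
#' @param aggregator `"mean"` (default) or `"sum"` over paralogs.
#' @param min_species Keep only groups with genes in at least this many of the
#'   supplied species. The default 2 excludes species-specific groups; 1
#'   retains them.
#' @param keep_species_specific If `TRUE`, genes absent from `og_map` are kept
#'   as singleton groups with id `"ssp_<species>_<gene>"` instead of dropped.
#' @return A tibble with first column `og_id` and one numeric column per input
#'   sample, with attribute `"aggregator"`.
#' @export
build_og_table <- function(tables, og_map, aggregator = c("mean", "sum"),
                           min_species = 2L, keep_species_specific = FALSE) {
  aggregator <- match.arg(aggregator)
  if (min_species < 1) abort("min_species must be >= 1")
  if (is.null(names(tables)) || any(names(tables) == "")) {
    abort("'tables' must be a named list (names = species ids)")
  }
  dup <- og_map |>
    dplyr::distinct(.data$og_id, .data$species_id, .data$gene_id) |>
    dplyr::count(.data$species_id, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("gene(s) assigned to more than one ortholog-group: ",
                 paste(head(dup$gene_id, 5), collapse = ", ")))
  }

  species <- names(tables)
  mats <- lapply(species, function(sp) {
    m <- table_to_matrix(tables[[sp]], "gene_id")
    if (any(m < 0)) abort(paste0("negative TPM values in table for species ", sp))
    map_sp <- dplyr::filter(og_map, .data$species_id == sp)
    missing <- setdiff(map_sp$gene_id, rownames(m))
    if (length(missing) > 0) {
      abort(paste0("gene(s) in og_map missing from table of species ", sp, ": ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    unmapped <- setdiff(rownames(m), map_sp$gene_id)
    if (length(unmapped) > 0 && !keep_species_specific) {
      inform(paste0("dropping ", length(unmapped),
                    " species-specific gene(s) of ", sp, " absent from og_map"))
    }
    group_of <- setNames(map_sp$og_id, map_sp$gene_id)
    if (keep_species_specific && length(unmapped) > 0) {
      group_of <- c(group_of, setNames(paste0("ssp_", sp, "_", unmapped), unmapped))
    }
    keep <- rownames(m) %in% names(group_of)
    m <- m[keep, , drop = FALSE]
    g <- group_of[rownames(m)]
    sums <- rowsum(m, g)
    if (aggregator == "mean") {
      counts <- as.vector(table(g)[rownames(sums)])
      sums <- sums / counts
    }
    sums
  })
  names(mats) <- species

  og_ids <- sort(unique(unlist(lapply(mats, rownames))))
  n_species_per_og <- rowSums(vapply(mats, function(m) og_ids %in% rownames(m),
                                     logical(length(og_ids))))
  og_ids <- og_ids[n_species_per_og >= min_species]
  if (length(og_ids) == 0) abort("no ortholog-group satisfies min_species")

  blocks <- lapply(species, function(sp) {
    m <- mats[[sp]]
    out <- matrix(0, length(og_ids), ncol(m),
                  dimnames = list(og_ids, colnames(m)))
    shared <- intersect(og_ids, rownames(m))
    out[shared, ] <- m[shared, , drop = FALSE]
    out
  })
  res <- matrix_to_table(do.call(cbind, blocks), "og_id")
  attr(res, "aggregator") <- aggregator
  res
}

#' Average biological replicates into one column per developmental stage
#'
#' Each (species, stage) is represented by the mean of its replicate samples.
#' Output columns are named `<species_id>_<stage_label>` and ordered by species
#' (order of first appearance in `meta`) then `stage_ordinal`. Declared stages
#' with no replicate present in the table are omitted with a warning.
#'
#' @param table Ortholog-group expression tibble (`og_id` + sample columns).
#' @param meta Sample metadata tibble (`sample_id`, `species_id`,
#'   `stage_label`, `stage_ordinal`, `replicate_id`, ...).
#' @return A tibble `og_id` + one column per (species, stage), with the
#'   stage-level metadata as attribute `"stage_meta"` (see [stage_metadata()]).
#' @export
stage_mean_table <- function(table, meta) {
  assert_species_in_meta(meta)
  m <- table_to_matrix(table, names(table)[1])
  smeta <- stage_metadata(meta)
  cols <- lapply(seq_len(nrow(smeta)), function(i) {
    reps <- meta$sample_id[meta$species_id == smeta$species_id[i] &
                           meta$stage_label == smeta$stage_label[i]]
    reps <- intersect(reps, colnames(m))
    if (length(reps) == 0) return(NULL)
    rowMeans(m[, reps, drop = FALSE])
  })
  present <- !vapply(cols, is.null, logical(1))
  if (any(!present)) {
    warn(paste0("omitting stage(s) with no replicate in the table: ",
                paste(smeta$sample_id[!present], collapse = ", ")))
  }
  out <- do.call(cbind, cols[present])
  colnames(out) <- smeta$sample_id[present]
  rownames(out) <- rownames(m)
  res <- matrix_to_table(out, names(table)[1])
  attr(res, "stage_meta") <- smeta[present, , drop = FALSE]
  res
}

#' Stage-level metadata for a replicate-averaged table
#'
#' One row per (species, stage), with `sample_id = <species_id>_<stage_label>`
#' matching the column names produced by [stage_mean_table()] and by BRI
#' replicate selection.
#'
#' @inheritParams stage_mean_table
#' @return Tibble with columns `sample_id`, `species_id`, `stage_label`,
#'   `stage_ordinal`, `replicate_id` (`"mean"`).
#' @export
stage_metadata <- function(meta) {
  assert_species_in_meta(meta)
  meta |>
    dplyr::mutate(.sp_order = match(.data$species_id, unique(.data$species_id))) |>
    dplyr::distinct(.data$.sp_order, .data$species_id, .data$stage_label,
                    .data$stage_ordinal) |>
    dplyr::arrange(.data$.sp_order, .data$stage_ordinal) |>
    dplyr::transmute(
      sample_id = paste0(.data$species_id, "_", .data$stage_label),
      species_id = .data$species_id,
      stage_label = .data$stage_label,
      stage_ordinal = .data$stage_ordinal,
      replicate_id = "mean"
    )
}

#' Read-depth subsampling targets at a common reads-to-exome-size ratio
#'
#' Finds the largest read count per sample such that all samples share the
#' same reads-to-exome-size ratio: the smallest observed ratio is the
#' baseline, and each sample's target is `floor(r_min * exome_size)` of its
#' species. The sample attaining the minimum keeps its own read count; every
#' target is at most the available reads. Actual read subsampling is external.
#'
#' @param meta Sample metadata with `mapped_best_hit_reads` and `species_id`.
#' @param exome_sizes Named numeric vector (names = species ids) of exome
#'   sizes in bp, or a tibble with columns `species_id`, `exome_bp`.
#' @return Tibble `sample_id`, `species_id`, `mapped_best_hit_reads`,
#'   `target_reads`.
#' @export
subsample_targets <- function(meta, exome_sizes) {
  if (is.data.frame(exome_sizes)) {
    exome_sizes <- setNames(exome_sizes$exome_bp, exome_sizes$species_id)
  }
  if (!"mapped_best_hit_reads" %in% names(meta)) {
    abort("metadata has no 'mapped_best_hit_reads' column")
  }
  missing <- setdiff(unique(meta$species_id), names(exome_sizes))
  if (length(missing) > 0) {
    abort(paste0("no exome size for species: ", paste(missing, collapse = ", ")))
  }
  if (any(exome_sizes <= 0)) abort("exome sizes must be positive")
  exo <- unname(exome_sizes[meta$species_id])
  ratio <- meta$mapped_best_hit_reads / exo
  r_min <- min(ratio)
  ## floor with an absolute guard so the argmin sample's own read count
  ## (an exact integer up to rounding of reads/exo*exo) is not floored away
  tibble(
    sample_id = meta$sample_id,
    species_id = meta$species_id,
    mapped_best_hit_reads = meta$mapped_best_hit_reads,
    target_reads = floor(r_min * exo + 1e-9)
  )
}
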
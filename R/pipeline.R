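## End-to-end convenience: ortholog-group table -> normalized stage table ->
## distance -> tree -> rooting -> derivedness profile, under one config.

#' Run the derivedness pipeline on an ortholog-group table
#'
#' Replicate-averages the table (unless it is already stage-level), applies
#' the configured normalization chain, computes the distance matrix, infers
#' the tree, roots it by the outgroup species, and extracts the derivedness
#' profile from the ancestral node (the ingroup side of the rooting edge).
#'
#' @param table Ortholog-group expression tibble (sample- or stage-level).
#' @param meta Matching metadata (sample-level metadata if `table` is
#'   sample-level).
#' @param outgroup_species Character vector of outgroup species ids.
#' @param config A [pipeline_config()].
#' @param stage_level Set `TRUE` if `table` columns are already one per
#'   stage and `meta` is stage-level.
#' @return List: `stage_table`, `stage_meta`, `distance` (`deriv_dist`),
#'   `tree` (unrooted), `rooted` (rooted, ancestral node marked), `profile`
#'   (tibble `sample_id`, `index`, ingroup leaves only).
#' @export
derivedness_pipeline <- function(table, meta, outgroup_species,
                                 config = pipeline_config(),
                                 stage_level = FALSE) {
  if (stage_level) {
    stage_table <- table
    smeta <- meta
  } else {
    stage_table <- stage_mean_table(table, meta)
    smeta <- attr(stage_table, "stage_meta")
  }
  norm <- normalize_table(stage_table, config$normalization)
  d <- pairwise_distance(norm, config$distance)
  phy <- infer_tree(d, config$tree_method)
  sp_of <- setNames(smeta$species_id, smeta$sample_id)
  out_tips <- phy$tip.label[sp_of[phy$tip.label] %in% outgroup_species]
  if (length(out_tips) == 0) abort("no leaves belong to the outgroup species")
  rooted <- root_by_outgroup(phy, out_tips)
  ## outgroup leaves sit above the ancestral node by construction; their
  ## exclusion from the profile is intended, so the warning is muffled here
  profile <- withCallingHandlers(
    derivedness_profile(rooted),
    warning = function(w) invokeRestart("muffleWarning"))
  profile <- profile[!sp_of[profile$sample_id] %in% outgroup_species, ]
  list(stage_table = stage_table, stage_meta = smeta, distance = d,
       tree = phy, rooted = rooted, profile = profile)
}

#' Boxplot of derivedness indices per species
#'
#' @param profile Tibble `sample_id`, `index` (e.g. from
#'   [derivedness_profile()]).
#' @param meta Metadata mapping `sample_id` to `species_id`.
#' @return A ggplot object.
#' @export
plot_derivedness_profile <- function(profile, meta) {
  df <- dplyr::left_join(profile, meta, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$species_id, .data$index)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "derivedness index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
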
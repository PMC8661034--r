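## Derivedness-correlative ortholog-groups (DCOs).
##
## Per (ortholog-group, species): Spearman correlation between stage-mean
## expression and the per-stage derivedness index. Groups are classified by
## how many clade species show a negative correlation (the top category =
## negative in every species), profiled for temporal pleiotropy (fraction of
## stages with TPM >= 1), and tested for annotation enrichment.

#' Ortholog-groups with a gene in every clade species
#'
#' @param og_map Tibble `og_id`, `species_id`, `gene_id`.
#' @param clade Non-empty character vector of species ids.
#' @return Character vector of og ids present in all clade species.
#' @export
clade_filter <- function(og_map, clade) {
  if (length(clade) == 0) abort("clade must be non-empty")
  og_map |>
    dplyr::filter(.data$species_id %in% clade) |>
    dplyr::distinct(.data$og_id, .data$species_id) |>
    dplyr::count(.data$og_id) |>
    dplyr::filter(.data$n == length(clade)) |>
    dplyr::pull(.data$og_id)
}

#' Spearman correlation of expression with the derivedness index, per species
#'
#' For each species and ortholog-group, the mid-rank Spearman correlation
#' between stage-mean expression and the stage derivedness index over that
#' species' stages (in developmental order). `NA` where either vector is
#' constant or the species has fewer than `min_stages` stages (with a
#' warning). Exclude protocol-confounded samples (e.g. Quartz-Seq) upstream.
#'
#' @param stage_table Stage-level ortholog-group expression tibble.
#' @param profile Derivedness profile tibble (`sample_id`, `index`) over the
#'   stage-level samples, e.g. from [derivedness_profile()] on the mean-value
#'   tree.
#' @param meta Stage-level metadata.
#' @param min_stages Minimum stages per species (default 3).
#' @return Tibble `og_id`, `species_id`, `rho`.
#' @export
derivedness_correlation <- function(stage_table, profile, meta, min_stages = 3L) {
  m <- table_to_matrix(stage_table, names(stage_table)[1])
  idx <- setNames(profile$index, profile$sample_id)
  sp_of <- setNames(meta$species_id, meta$sample_id)
  ord_of <- setNames(meta$stage_ordinal, meta$sample_id)
  ids <- intersect(colnames(m), names(idx))
  species <- unique(sp_of[ids])
  rows <- lapply(species[!is.na(species)], function(s) {
    cols <- ids[sp_of[ids] %in% s]
    cols <- cols[order(ord_of[cols])]
    if (length(cols) < min_stages) {
      warn(paste0("species ", s, " has fewer than ", min_stages,
                  " stages; rho set to NA"))
      return(tibble(og_id = rownames(m), species_id = s, rho = NA_real_))
    }
    rho <- suppressWarnings(as.vector(cor(t(m[, cols, drop = FALSE]), idx[cols],
                                          method = "spearman")))
    tibble(og_id = rownames(m), species_id = s, rho = rho)
  })
  dplyr::bind_rows(rows)
}

#' Classify ortholog-groups by the number of negatively correlated species
#'
#' The category of a group is the count of clade species with strictly
#' negative correlation; `NA` correlations count as non-negative. Apply
#' [clade_filter()] first so every group has a gene in each clade species.
#'
#' @param dco Tibble from [derivedness_correlation()].
#' @param clade Character vector of clade species ids.
#' @return Tibble `og_id`, `category` (0..length(clade)), `mean_rho` (mean
#'   over non-`NA` clade species), `n_rho` (how many species entered the
#'   mean).
#' @export
categorize_dco <- function(dco, clade) {
  dco |>
    dplyr::filter(.data$species_id %in% clade) |>
    dplyr::group_by(.data$og_id) |>
    dplyr::summarise(
      category = sum(!is.na(.data$rho) & .data$rho < 0),
      mean_rho = if (all(is.na(.data$rho))) NA_real_ else
        mean(.data$rho, na.rm = TRUE),
      n_rho = sum(!is.na(.data$rho)),
      .groups = "drop"
    )
}

#' Temporal pleiotropy: fraction of stages in which a group is expressed
#'
#' For each ortholog-group and clade species, the percentage of that species'
#' stages with stage-mean expression at or above `threshold` (TPM scale;
#' apply to the raw-TPM stage table, not to rank- or z-scored values); then
#' the mean percentage across clade species, binned into 10% ranges
#' (`floor(mean / 10)`, with exactly 100% in its own top bin).
#'
#' @param stage_table Raw-TPM-scale stage-mean table.
#' @param meta Stage-level metadata.
#' @param clade Character vector of clade species ids.
#' @param threshold Expression threshold (default TPM 1).
#' @return Tibble `og_id`, `mean_pct`, `bin` (0..10), `bin_label`.
#' @export
temporal_pleiotropy <- function(stage_table, meta, clade, threshold = 1) {
  m <- table_to_matrix(stage_table, names(stage_table)[1])
  sp_of <- setNames(meta$species_id, meta$sample_id)
  pct <- vapply(clade, function(s) {
    cols <- colnames(m)[sp_of[colnames(m)] %in% s]
    if (length(cols) == 0) abort(paste0("no stages for clade species ", s))
    100 * rowMeans(m[, cols, drop = FALSE] >= threshold)
  }, numeric(nrow(m)))
  mean_pct <- rowMeans(pct)
  bin <- pmin(floor(mean_pct / 10), 10)
  tibble(
    og_id = rownames(m),
    mean_pct = mean_pct,
    bin = as.integer(bin),
    bin_label = ifelse(bin == 10, "100%", paste0(bin * 10, "-", bin * 10 + 9, "%"))
  )
}

#' Annotation enrichment of the top DCO category
#'
#' For each category, a two-sided Fisher exact test of the 2x2 table
#' (flagged / unflagged) x (reference category / that category). The
#' reference defaults to the top category (negative in every clade species).
#'
#' @param categories Tibble from [categorize_dco()].
#' @param flags Named logical vector (names = og ids) or tibble
#'   `og_id`, `flag`; annotation such as development-relatedness.
#' @param reference_category Category compared against the others (default
#'   the maximum present).
#' @return Tibble `category`, `n`, `n_flagged`, `odds_ratio`, `p_value`
#'   (`NA` for empty categories or degenerate tables).
#' @export
dco_enrichment <- function(categories, flags, reference_category = NULL) {
  if (is.data.frame(flags)) flags <- setNames(flags$flag, flags$og_id)
  miss <- setdiff(categories$og_id, names(flags))
  if (length(miss) > 0) {
    abort(paste0("no annotation flag for og(s): ", paste(head(miss, 5), collapse = ", ")))
  }
  fl <- flags[categories$og_id]
  ref <- reference_category %||% max(categories$category)
  in_ref <- categories$category == ref
  a <- sum(fl & in_ref); b <- sum(!fl & in_ref)
  cats <- sort(unique(categories$category))
  rows <- lapply(cats, function(cc) {
    in_c <- categories$category == cc
    n <- sum(in_c); nf <- sum(fl & in_c)
    if (cc == ref) {
      return(tibble(category = cc, n = n, n_flagged = nf,
                    odds_ratio = NA_real_, p_value = NA_real_))
    }
    if (n == 0 || (a + b) == 0 || (a == 0 && nf == 0)) {
      return(tibble(category = cc, n = n, n_flagged = nf,
                    odds_ratio = NA_real_, p_value = NA_real_))
    }
    tab <- matrix(c(a, b, nf, n - nf), 2, 2, byrow = TRUE)
    ht <- stats::fisher.test(tab, alternative = "two.sided")
    tibble(category = cc, n = n, n_flagged = nf,
           odds_ratio = unname(ht$estimate), p_value = ht$p.value)
  })
  dplyr::bind_rows(rows)
}

#' Bar chart of DCO categories
#'
#' @param categories Tibble from [categorize_dco()].
#' @return A ggplot object.
#' @export
plot_dco_categories <- function(categories) {
  df <- dplyr::count(categories, .data$category)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$category), .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "species with negative correlation", y = "ortholog-groups") +
    ggplot2::theme_minimal()
}

#' Stacked pleiotropy-bin composition per DCO category
#'
#' @param categories Tibble from [categorize_dco()].
#' @param pleiotropy Tibble from [temporal_pleiotropy()].
#' @return A ggplot object (per category, the ratio of groups in each
#'   temporal-pleiotropy bin).
#' @export
plot_pleiotropy_bins <- function(categories, pleiotropy) {
  df <- dplyr::inner_join(categories, pleiotropy, by = "og_id") |>
    dplyr::count(.data$category, .data$bin, .data$bin_label) |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(ratio = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$category), .data$ratio,
                                   fill = stats::reorder(.data$bin_label, .data$bin))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_d(name = "stages expressed") +
    ggplot2::labs(x = "species with negative correlation", y = "ratio of ortholog-groups") +
    ggplot2::theme_minimal()
}
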
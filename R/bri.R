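## Biological-replicates-included (BRI) resampling.
##
## A BRI table picks one replicate per (species, stage) uniformly at random;
## trees inferred from many BRI tables give consensus supports for the
## mean-value tree and per-stage derivedness index distributions. One master
## seed spawns per-draw sub-seeds, so runs are reproducible end to end.

#' Draw one replicate per (species, stage)
#'
#' @param meta Sample metadata tibble.
#' @param seed Integer seed; the same seed always yields the same draw.
#' @return Tibble `species_id`, `stage_label`, `stage_ordinal`, `replicate_id`,
#'   `sample_id`, `stage_id` (the `<species>_<stage>` column name the sample
#'   stands for), one row per (species, stage).
#' @export
draw_bri <- function(meta, seed) {
  assert_species_in_meta(meta)
  smeta <- stage_metadata(meta)
  picks <- with_seed(seed, {
    vapply(seq_len(nrow(smeta)), function(i) {
      reps <- meta$sample_id[meta$species_id == smeta$species_id[i] &
                             meta$stage_label == smeta$stage_label[i]]
      if (length(reps) == 0) {
        abort(paste0("no replicate for ", smeta$sample_id[i]))
      }
      reps[sample.int(length(reps), 1)]
    }, character(1))
  })
  dplyr::mutate(
    smeta,
    replicate_id = meta$replicate_id[match(picks, meta$sample_id)],
    sample_id = picks,
    stage_id = paste0(.data$species_id, "_", .data$stage_label)
  )
}

## Stage-level table for one BRI draw: selected replicate columns renamed to
## the stage ids, so every draw shares one leaf set with the mean-value tree.
bri_table <- function(table, draw) {
  m <- table_to_matrix(table, names(table)[1])
  miss <- setdiff(draw$sample_id, colnames(m))
  if (length(miss) > 0) {
    abort(paste0("drawn sample(s) missing from table: ", paste(miss, collapse = ", ")))
  }
  sel <- m[, draw$sample_id, drop = FALSE]
  colnames(sel) <- draw$stage_id
  matrix_to_table(sel, names(table)[1])
}

#' Configuration of the normalization -> distance -> tree pipeline
#'
#' @param normalization Character vector of normalization steps (see
#'   [normalize_table()]); default ascending rank.
#' @param distance Distance method; default `"spearman"`.
#' @param tree_method `"bionj"` (default) or `"nj"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(normalization = "rank_ascending",
                            distance = "spearman",
                            tree_method = "bionj") {
  structure(list(normalization = normalization, distance = distance,
                 tree_method = tree_method), class = "pipeline_config")
}

## Unrooted tree from a stage-level table under a pipeline config.
pipeline_tree <- function(stage_table, config) {
  norm <- normalize_table(stage_table, config$normalization)
  d <- pairwise_distance(norm, config$distance)
  infer_tree(d, config$tree_method)
}

#' Infer trees from repeated BRI draws
#'
#' Each draw selects one replicate per stage, renames the columns to stage
#' ids, and runs the configured pipeline. Failing draws are skipped and
#' recorded in `attr(, "errors")`.
#'
#' @param table Sample-level ortholog-group expression tibble.
#' @param meta Sample metadata.
#' @param config A [pipeline_config()].
#' @param n_draws Number of BRI draws (the headline analyses use 100).
#' @param seed Master seed.
#' @return A `multiPhylo` list of unrooted trees, with attributes `"seeds"`
#'   (per-draw sub-seeds) and `"errors"` (named character of skipped draws).
#' @export
bri_trees <- function(table, meta, config = pipeline_config(),
                      n_draws = 100L, seed = 1L) {
  if (n_draws < 1) abort("n_draws must be >= 1")
  seeds <- spawn_seeds(seed, n_draws)
  errors <- character(0)
  trees <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    trees[[i]] <- tryCatch(
      pipeline_tree(bri_table(table, draw_bri(meta, seeds[i])), config),
      error = function(e) {
        errors[[as.character(i)]] <<- conditionMessage(e)
        NULL
      })
  }
  keep <- !vapply(trees, is.null, logical(1))
  if (length(errors) > 0) {
    warn(paste0(length(errors), " BRI draw(s) failed and were skipped"))
  }
  out <- trees[keep]
  class(out) <- "multiPhylo"
  attr(out, "seeds") <- seeds
  attr(out, "errors") <- errors
  out
}

#' Consensus support of a target tree's bipartitions over a tree set
#'
#' For each internal edge of `target`, the percentage of `trees` containing
#' the same leaf bipartition, written into `target$node.label`.
#'
#' @param trees `multiPhylo` (or list) of trees over the same leaf set.
#' @param target The tree to annotate (typically the mean-value tree).
#' @return `target` with `node.label` set to supports in percent (root label
#'   empty), and attribute `"supports"` holding the numeric vector.
#' @export
consensus_support <- function(trees, target) {
  for (tr in trees) {
    if (!setequal(tr$tip.label, target$tip.label)) {
      abort("all trees must share the target's leaf set")
    }
  }
  cls <- class(trees)
  if (!inherits(trees, "multiPhylo")) class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(target, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- 100 * counts / length(trees)
  root <- tree_root_node(target)
  ntip <- length(target$tip.label)
  labels <- format_support(supports)
  labels[root - ntip] <- ""   # trivial (whole leaf set) bipartition
  target$node.label <- labels
  attr(target, "supports") <- supports
  class(trees) <- cls
  target
}

format_support <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, as.character(round(x)),
         formatC(x, digits = 1, format = "f"))
}

#' Per-stage derivedness index distributions over BRI trees
#'
#' Roots every tree by the outgroup, locates the ancestral node (the ingroup
#' side of the rooting edge, or a clade-specific ancestor), and collects each
#' stage's derivedness index across draws.
#'
#' @param trees List of unrooted BRI trees over stage-level leaves.
#' @param meta Stage-level metadata (see [stage_metadata()]).
#' @param outgroup_species Character vector of outgroup species ids.
#' @param clade Optional character vector of species ids; when given, indices
#'   are measured from the most recent common ancestor of that clade's
#'   samples, and only that clade's leaves are profiled.
#' @return A `stage_index_distribution`: list with `draws` (tibble `draw`,
#'   `sample_id`, `species_id`, `stage_label`, `stage_ordinal`, `index`) and
#'   `summary` (per stage: `n`, `min`, `q1`, `median`, `q3`, `max`).
#' @export
stage_distributions <- function(trees, meta, outgroup_species, clade = NULL) {
  sp_of <- setNames(meta$species_id, meta$sample_id)
  rows <- lapply(seq_along(trees), function(i) {
    phy <- trees[[i]]
    out_tips <- phy$tip.label[sp_of[phy$tip.label] %in% outgroup_species]
    rt <- root_by_outgroup(phy, out_tips)
    anc <- attr(rt, "ancestral_node")
    keep_tips <- setdiff(rt$tip.label, out_tips)
    if (!is.null(clade)) {
      keep_tips <- rt$tip.label[sp_of[rt$tip.label] %in% clade]
      anc <- mrca_node(rt, keep_tips)
    }
    prof <- withCallingHandlers(derivedness_profile(rt, anc),
                                warning = function(w) invokeRestart("muffleWarning"))
    prof <- prof[prof$sample_id %in% keep_tips, ]
    dplyr::mutate(prof, draw = i)
  })
  draws <- dplyr::bind_rows(rows) |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::select("draw", "sample_id", "species_id", "stage_label",
                  "stage_ordinal", "index")
  summary <- draws |>
    dplyr::group_by(.data$species_id, .data$stage_label, .data$stage_ordinal) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$index),
      q1 = quantile(.data$index, 0.25, names = FALSE),
      median = median(.data$index),
      q3 = quantile(.data$index, 0.75, names = FALSE),
      max = max(.data$index),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$species_id, .data$stage_ordinal)
  structure(list(draws = draws, summary = summary),
            class = "stage_index_distribution")
}

#' @export
print.stage_index_distribution <- function(x, ...) {
  cat("<stage_index_distribution> ", max(x$draws$draw), " draws, ",
      nrow(x$summary), " stages\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.stage_index_distribution <- function(x, ...) x$summary

#' Least-derived stage per species (argmin of the median index)
#'
#' @param x A `stage_index_distribution`.
#' @return Tibble `species_id`, `stage_label`, `stage_ordinal`, `median`.
#' @export
least_derived_stages <- function(x) {
  x$summary |>
    dplyr::group_by(.data$species_id) |>
    dplyr::slice_min(.data$median, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("species_id", "stage_label", "stage_ordinal", "median")
}

#' Boxplots of per-stage derivedness index distributions
#'
#' @param object A `stage_index_distribution`.
#' @param ... Unused.
#' @return A ggplot object, one facet per species.
#' @export
autoplot.stage_index_distribution <- function(object, ...) {
  df <- object$draws |>
    dplyr::mutate(stage = stats::reorder(.data$stage_label, .data$stage_ordinal))
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$index)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~species_id, scales = "free") +
    ggplot2::labs(x = "developmental stage", y = "derivedness index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Rank tests on derivedness index groups
#'
#' `index_group_test()` compares index values between groups: Kruskal-Wallis
#' for 2+ groups or a two-sided (exact where possible) Mann-Whitney/Wilcoxon
#' for exactly 2. `stage_friedman_test()` tests, per species, whether stages
#' differ across BRI draws, blocking on draws (treatments = stages).
#'
#' @param values Numeric vector of index values.
#' @param groups Grouping vector, same length.
#' @param test `"kruskal"` or `"wilcoxon"`.
#' @return Tibble `test`, `statistic`, `p_value` (plus `species_id` for the
#'   Friedman variant).
#' @export
index_group_test <- function(values, groups, test = c("kruskal", "wilcoxon")) {
  test <- match.arg(test)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (min(table(groups)) < 1) abort("degenerate group sizes")
  if (test == "kruskal") {
    ht <- stats::kruskal.test(values, groups)
    tibble(test = "kruskal_wallis", statistic = unname(ht$statistic),
           p_value = ht$p.value)
  } else {
    if (nlevels(groups) != 2) abort("wilcoxon test needs exactly 2 groups")
    ht <- stats::wilcox.test(values[groups == levels(groups)[1]],
                             values[groups == levels(groups)[2]],
                             alternative = "two.sided")
    tibble(test = "mann_whitney", statistic = unname(ht$statistic),
           p_value = ht$p.value)
  }
}

#' @param distribution A `stage_index_distribution`.
#' @rdname index_group_test
#' @export
stage_friedman_test <- function(distribution) {
  draws <- distribution$draws
  out <- draws |>
    dplyr::group_by(.data$species_id) |>
    dplyr::group_modify(function(df, key) {
      wide <- tidyr::pivot_wider(df[, c("draw", "stage_label", "index")],
                                 names_from = "stage_label", values_from = "index")
      m <- as.matrix(wide[, -1])
      if (ncol(m) < 2 || nrow(m) < 2) {
        abort("friedman test needs >= 2 stages and >= 2 draws")
      }
      if (all(apply(m, 1, function(r) max(r) == min(r)))) {
        ## every block fully tied: no treatment effect by definition, but the
        ## tie correction in stats::friedman.test degenerates to 0/0
        return(tibble(test = "friedman", statistic = 0, p_value = 1))
      }
      ht <- stats::friedman.test(m)
      tibble(test = "friedman", statistic = unname(ht$statistic),
             p_value = ht$p.value)
    }) |>
    dplyr::ungroup()
  out
}
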
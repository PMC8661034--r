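## The three method-selection criteria and the combination scan.
##
## [1] samples cluster by species (every species monophyletic);
## [2] the species-collapsed topology matches the reference phylogeny
##     (unrooted Robinson-Foulds distance 0);
## [3] within-species distance images change smoothly along development,
##     scored with gray-level co-occurrence (GLCM) texture descriptors.

#' Per-species monophyly on a sample tree
#'
#' A species passes if its sample set forms one side of a bipartition of the
#' (rooted or unrooted) tree; singleton species pass vacuously.
#'
#' @param phy `phylo` over samples.
#' @param meta Metadata tibble mapping `sample_id` to `species_id` (stage-level
#'   metadata for stage trees).
#' @return Tibble `species_id`, `monophyletic`.
#' @export
species_monophyly <- function(phy, meta) {
  sp_of <- setNames(meta$species_id, meta$sample_id)[phy$tip.label]
  if (anyNA(sp_of)) abort("tree has leaves missing from the metadata")
  species <- unique(sp_of)
  tibble(
    species_id = species,
    monophyletic = vapply(species, function(s) {
      is_bipartition(phy, phy$tip.label[sp_of == s])
    }, logical(1))
  )
}

#' Consistency of the species-collapsed tree with a reference phylogeny
#'
#' Requires every species to be monophyletic (criterion 1); each species clade
#' is collapsed to one leaf and the induced unrooted topology is compared with
#' the reference by Robinson-Foulds distance. Passes iff RF = 0.
#'
#' @param phy Sample tree (`phylo`).
#' @param reference Reference species tree (`phylo`, tips = species ids).
#' @param meta Metadata mapping samples to species.
#' @return A list with `rf` (integer) and `pass` (logical).
#' @export
topology_consistency <- function(phy, reference, meta) {
  mono <- species_monophyly(phy, meta)
  if (!all(mono$monophyletic)) {
    abort(paste0("species not monophyletic: ",
                 paste(mono$species_id[!mono$monophyletic], collapse = ", ")))
  }
  miss <- setdiff(mono$species_id, reference$tip.label)
  if (length(miss) > 0) {
    abort(paste0("species missing from reference tree: ",
                 paste(miss, collapse = ", ")))
  }
  sp_of <- setNames(meta$species_id, meta$sample_id)[phy$tip.label]
  keep <- phy$tip.label[!duplicated(sp_of)]
  induced <- ape::keep.tip(phy, keep)
  induced$tip.label <- unname(sp_of[induced$tip.label])
  ref <- ape::keep.tip(reference, mono$species_id)
  rf <- as.integer(phangorn::RF.dist(ape::unroot(induced), ape::unroot(ref)))
  list(rf = rf, pass = rf == 0L)
}

#' GLCM texture descriptors of a quantized window
#'
#' Builds the symmetric, normalized gray-level co-occurrence matrix for the
#' distance-1 horizontal and vertical offsets (pooled), and returns the five
#' standard descriptors. Correlation is defined as 1 when either marginal
#' variance is zero (a constant window is perfectly smooth).
#'
#' @param window Integer-valued matrix (at least 2x2) with values in
#'   `[0, levels - 1]`.
#' @param levels Number of gray levels.
#' @return Named numeric vector: `contrast`, `dissimilarity`, `homogeneity`,
#'   `uniformity`, `correlation`.
#' @export
glcm_descriptors <- function(window, levels) {
  if (is.null(dim(window)) || nrow(window) < 2 || ncol(window) < 2) {
    abort("window must be at least 2x2")
  }
  if (any(window < 0 | window > levels - 1)) {
    abort("window values must lie in [0, levels - 1]")
  }
  p <- matrix(0, levels, levels)
  add_pairs <- function(a, b) {
    for (k in seq_along(a)) {
      i <- a[k] + 1L; j <- b[k] + 1L
      p[i, j] <<- p[i, j] + 1
      p[j, i] <<- p[j, i] + 1
    }
  }
  nr <- nrow(window); nc <- ncol(window)
  add_pairs(as.vector(window[, -nc]), as.vector(window[, -1]))   # offset (0,1)
  add_pairs(as.vector(window[-nr, ]), as.vector(window[-1, ]))   # offset (1,0)
  p <- p / sum(p)
  lv <- 0:(levels - 1)
  di <- outer(lv, lv, "-")
  mu_i <- sum(rowSums(p) * lv)
  mu_j <- sum(colSums(p) * lv)
  var_i <- sum(rowSums(p) * (lv - mu_i)^2)
  var_j <- sum(colSums(p) * (lv - mu_j)^2)
  corr <- if (var_i * var_j <= 0) 1 else {
    sum(p * outer(lv - mu_i, lv - mu_j)) / sqrt(var_i * var_j)
  }
  c(contrast = sum(p * di^2),
    dissimilarity = sum(p * abs(di)),
    homogeneity = sum(p / (1 + di^2)),
    uniformity = sum(p^2),
    correlation = corr)
}

## Min-max quantization of a numeric block to `levels` grays (0-based).
quantize_block <- function(block, levels) {
  rng <- range(block)
  if (rng[2] == rng[1]) return(matrix(0L, nrow(block), ncol(block)))
  q <- floor((block - rng[1]) / (rng[2] - rng[1]) * levels)
  matrix(as.integer(pmin(q, levels - 1)), nrow(block), ncol(block))
}

## Average GLCM descriptors over all 3x3 sliding windows of a species block.
block_smoothness <- function(block, levels = 8L, window = 3L) {
  qb <- quantize_block(block, levels)
  nr <- nrow(qb); nc <- ncol(qb)
  acc <- c(contrast = 0, dissimilarity = 0, homogeneity = 0,
           uniformity = 0, correlation = 0)
  nwin <- 0L
  for (i in seq_len(nr - window + 1)) {
    for (j in seq_len(nc - window + 1)) {
      acc <- acc + glcm_descriptors(qb[i:(i + window - 1), j:(j + window - 1)], levels)
      nwin <- nwin + 1L
    }
  }
  acc / nwin
}

glcm_descriptor_names <- c("contrast", "dissimilarity", "homogeneity",
                           "uniformity", "correlation")
## smaller is smoother for these two, larger for the rest
glcm_minimized <- c("contrast", "dissimilarity")

#' Smoothness comparison of distance methods over within-species blocks
#'
#' For each species, the within-species distance submatrix (samples in stage
#' order) is min-max quantized to `levels` grays and each GLCM descriptor is
#' averaged over all 3x3 sliding windows. Per (species, descriptor), the
#' best-scoring method (argmin for contrast/dissimilarity, argmax otherwise)
#' earns a win; ties are split fractionally. Species with fewer than 3 stages
#' are skipped with a warning.
#'
#' @param matrices Named list of `deriv_dist` matrices over the same
#'   stage-level samples (one per distance method).
#' @param meta Stage-level metadata (`sample_id`, `species_id`,
#'   `stage_ordinal`).
#' @param levels Gray levels for quantization.
#' @return A `smoothness_report`: list with `scores` (tibble `species_id`,
#'   `method`, `descriptor`, `score`) and `wins` (tibble `method`,
#'   `descriptor`, `win_pct`, summing to 100 per descriptor).
#' @export
smoothness_scan <- function(matrices, meta, levels = 8L) {
  if (is.null(names(matrices)) || any(names(matrices) == "")) {
    abort("'matrices' must be a named list (names = method labels)")
  }
  ids0 <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!setequal(rownames(m), ids0)) abort("all matrices must cover the same samples")
  }
  sp_of <- setNames(meta$species_id, meta$sample_id)
  ord_of <- setNames(meta$stage_ordinal, meta$sample_id)
  species <- unique(sp_of[ids0])
  scores <- list()
  for (s in species[!is.na(species)]) {
    ids <- ids0[sp_of[ids0] %in% s]
    ids <- ids[order(ord_of[ids])]
    if (length(ids) < 3) {
      warn(paste0("species ", s, " has fewer than 3 stages; block skipped"))
      next
    }
    for (meth in names(matrices)) {
      sc <- block_smoothness(unclass(matrices[[meth]])[ids, ids], levels)
      scores[[paste(s, meth)]] <- tibble(
        species_id = s, method = meth,
        descriptor = names(sc), score = unname(sc)
      )
    }
  }
  if (length(scores) == 0) abort("no species block with >= 3 stages")
  scores <- dplyr::bind_rows(scores)
  wins <- scores |>
    dplyr::group_by(.data$species_id, .data$descriptor) |>
    dplyr::mutate(best = if (unique(.data$descriptor) %in% glcm_minimized) {
      .data$score <= min(.data$score) + 1e-12
    } else {
      .data$score >= max(.data$score) - 1e-12
    }) |>
    dplyr::mutate(win = .data$best / sum(.data$best)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$method, .data$descriptor) |>
    dplyr::summarise(win_pct = 100 * sum(.data$win) /
                       dplyr::n_distinct(scores$species_id), .groups = "drop")
  structure(list(scores = scores, wins = wins), class = "smoothness_report")
}

#' @export
print.smoothness_report <- function(x, ...) {
  cat("<smoothness_report> win percentages (rows sum to 100 per descriptor)\n")
  print(tidyr::pivot_wider(x$wins, names_from = "descriptor", values_from = "win_pct"))
  invisible(x)
}

#' @export
tidy.smoothness_report <- function(x, ...) x$wins

#' @export
glance.smoothness_report <- function(x, ...) {
  x$wins |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mean_win_pct = mean(.data$win_pct), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_win_pct))
}

#' Scan normalization x distance x tree-method combinations
#'
#' Runs every combination on a (stage-level) ortholog-group table and
#' evaluates the three selection criteria. Per-combination errors (e.g.
#' Jensen-Shannon on z-scored, negative values) are captured in the report,
#' not raised. Criterion 2 is evaluated only where criterion 1 holds.
#'
#' @param table Stage-level ortholog-group expression tibble (raw TPM scale;
#'   each chain is applied to it in turn).
#' @param meta Stage-level metadata.
#' @param reference Reference species tree (`phylo`).
#' @param normalizations Named list of normalization chains
#'   (default [table1_normalizations()]).
#' @param distances Character vector of distance methods (default all 7).
#' @param tree_methods Character vector among `"nj"`, `"bionj"`.
#' @param levels Gray levels for the smoothness descriptors.
#' @return A `deriv_scan` tibble: one row per combination with `normalization`,
#'   `distance`, `tree_method`, `criterion1`, `criterion2_rf`, `criterion2`,
#'   the five mean GLCM descriptors, and `error`.
#' @export
scan_combinations <- function(table, meta, reference,
                              normalizations = table1_normalizations(),
                              distances = distance_methods,
                              tree_methods = c("nj", "bionj"),
                              levels = 8L) {
  grid <- expand.grid(tree_method = tree_methods, distance = distances,
                      normalization = names(normalizations),
                      stringsAsFactors = FALSE)[, 3:1]
  grid <- grid[order(match(grid$normalization, names(normalizations)),
                     match(grid$distance, distances),
                     match(grid$tree_method, tree_methods)), ]
  norm_cache <- list()
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    nm <- grid$normalization[k]; dm <- grid$distance[k]; tm <- grid$tree_method[k]
    res <- tibble(normalization = nm, distance = dm, tree_method = tm,
                  criterion1 = NA, criterion2_rf = NA_integer_, criterion2 = NA,
                  contrast = NA_real_, dissimilarity = NA_real_,
                  homogeneity = NA_real_, uniformity = NA_real_,
                  correlation = NA_real_, error = NA_character_)
    tryCatch({
      if (is.null(norm_cache[[nm]])) {
        norm_cache[[nm]] <<- withCallingHandlers(
          normalize_table(table, normalizations[[nm]]),
          warning = function(w) invokeRestart("muffleWarning"))
      }
      d <- pairwise_distance(norm_cache[[nm]], dm)
      phy <- infer_tree(d, tm)
      mono <- species_monophyly(phy, meta)
      res$criterion1 <- all(mono$monophyletic)
      if (res$criterion1) {
        tc <- topology_consistency(phy, reference, meta)
        res$criterion2_rf <- tc$rf
        res$criterion2 <- tc$pass
      }
      sm <- withCallingHandlers(
        smoothness_scan(setNames(list(d), dm), meta, levels),
        warning = function(w) invokeRestart("muffleWarning"))
      avg <- sm$scores |>
        dplyr::group_by(.data$descriptor) |>
        dplyr::summarise(score = mean(.data$score))
      for (dn in glcm_descriptor_names) {
        res[[dn]] <- avg$score[avg$descriptor == dn]
      }
      res
    }, error = function(e) {
      res$error <- conditionMessage(e)
      res
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("deriv_scan", class(out))
  out
}

#' @export
tidy.deriv_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "deriv_scan")
  out
}

#' @export
glance.deriv_scan <- function(x, ...) {
  tibble(
    n_combos = nrow(x),
    n_errors = sum(!is.na(x$error)),
    n_pass_c1 = sum(x$criterion1, na.rm = TRUE),
    n_pass_c12 = sum(x$criterion1 & x$criterion2, na.rm = TRUE)
  )
}

#' Pass/fail overview of a combination scan
#'
#' @param object A `deriv_scan`.
#' @param ... Unused.
#' @return A ggplot object (tiles: normalization x distance, faceted by tree
#'   method, colored by the highest criterion passed).
#' @export
autoplot.deriv_scan <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(status = dplyr::case_when(
      !is.na(.data$error) ~ "error",
      .data$criterion1 & .data$criterion2 ~ "criteria 1+2",
      .data$criterion1 ~ "criterion 1",
      TRUE ~ "none"
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$distance, .data$normalization,
                                   fill = .data$status)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::facet_wrap(~tree_method) +
    ggplot2::labs(x = "distance method", y = "normalization chain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
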
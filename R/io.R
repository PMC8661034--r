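## Plain-text interchange formats: TSV expression tables (first column an id,
## header = sample ids), one-gene-per-line ortholog-group maps, sample
## metadata, square distance matrices, newick trees.

#' Read / write an expression table (TSV)
#'
#' First column is the row identifier (gene or ortholog-group id), remaining
#' columns are numeric, header row holds sample ids.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @param table Tibble as returned by [read_expression_tsv()] or
#'   [build_og_table()].
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read an ortholog-group membership map (TSV)
#'
#' Columns `og_id`, `species_id`, `gene_id`, one gene per line.
#' @param path File path.
#' @return A tibble.
#' @export
read_og_map <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("og_id", "species_id", "gene_id")
  if (!all(need %in% names(out))) {
    abort("og map must have columns og_id, species_id, gene_id")
  }
  out
}

#' Read sample metadata (TSV)
#'
#' Expects columns `sample_id`, `species_id`, `stage_label`, `stage_ordinal`,
#' `replicate_id` and optionally `protocol`, `mapped_best_hit_reads`.
#' @param path File path.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  assert_species_in_meta(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Read / write a square distance matrix (TSV)
#'
#' Square layout with row and column sample ids; the method name is kept as a
#' `"method"` attribute / first-line comment is not used.
#'
#' @param path File path.
#' @param method Distance method label to attach on read.
#' @return For the reader, a `deriv_dist` matrix.
#' @export
read_distance_tsv <- function(path, method = NA_character_) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  new_deriv_dist(m, method)
}

#' @param d `deriv_dist` matrix.
#' @rdname read_distance_tsv
#' @export
write_distance_tsv <- function(d, path) {
  tab <- as_tibble(unclass(d), rownames = "sample_id")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read and write newick trees
#'
#' Thin wrappers over \pkg{ape} that round-trip topology, labels, branch
#' lengths (to better than 1e-9 relative) and internal-node support labels.
#' `read_newick()` validates parenthesis balance first and reports the
#' 1-based character position of the first imbalance.
#'
#' @param text Newick string (terminated by `;`). Exactly one of `text`/`file`.
#' @param file Path to a newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) abort("supply exactly one of text/file")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      abort(paste0("malformed newick: unbalanced ')' at position ", i))
    }
  }
  if (depth != 0L) {
    abort(paste0("malformed newick: ", depth, " unclosed '(' at end of string"))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) abort(paste0("malformed newick: ", conditionMessage(e))))
  if (is.null(phy)) abort("malformed newick: parser returned no tree")
  phy
}

#' @param phy A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @rdname read_newick
#' @export
write_newick <- function(phy, file = NULL, digits = 15L) {
  txt <- ape::write.tree(phy, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(file))
  }
  txt
}
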
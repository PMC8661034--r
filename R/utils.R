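## Internal helpers shared across modules.
##
## Expression tables are tibbles whose first column holds row identifiers
## (gene_id or og_id) and whose remaining columns are numeric sample columns.
## Most numerics happen on plain matrices; these helpers convert both ways.

table_to_matrix <- function(table, id_col = NULL) {
  stopifnot(is.data.frame(table), ncol(table) >= 2)
  id_col <- id_col %||% names(table)[1]
  ids <- as.character(table[[id_col]])
  m <- as.matrix(table[setdiff(names(table), id_col)])
  if (!is.numeric(m)) {
    abort("expression table columns other than the id column must be numeric")
  }
  rownames(m) <- ids
  m
}

matrix_to_table <- function(m, id_col = "og_id") {
  out <- as_tibble(m, rownames = id_col)
  out
}

## Deterministic seeded evaluation that does not disturb the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

## Draw n sub-seeds (< 2^31) reproducibly from one master seed.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_species_in_meta <- function(meta) {
  required <- c("sample_id", "species_id", "stage_label", "stage_ordinal", "replicate_id")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste0("metadata is missing column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(meta)
}

#' Drop samples acquired by a given library-preparation protocol
#'
#' Library preparation can dominate transcriptomic distances (samples cluster
#' by protocol rather than by stage), so analyses that mix protocols usually
#' exclude the minority protocol first. This is a plain metadata filter; apply
#' it before table building or stage averaging and subset expression columns to
#' the remaining `sample_id`s.
#'
#' @param meta Sample metadata tibble with a `protocol` column.
#' @param protocol Character vector of protocol names to drop
#'   (e.g. `"QuartzSeq"`).
#' @return The filtered metadata tibble.
#' @export
exclude_protocol <- function(meta, protocol = "QuartzSeq") {
  if (!"protocol" %in% names(meta)) {
    abort("metadata has no 'protocol' column")
  }
  dplyr::filter(meta, !.data$protocol %in% !!protocol)
}
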
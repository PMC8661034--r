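## Expression normalization steps and chains.
##
## Nine chains are scanned for tree construction (see table1_normalizations()):
## log2(TPM+1), log10(TPM+1), quantile, ascending/descending rank, z-score,
## and the log2 -> quantile / z-score / quantile -> z-score compositions.
## Rank, z-score and quantile operate per column (per sample): cross-species
## comparability requires scaling within each embryo, not within each gene
## (a per-gene variant is available via `margin`).

#' Log-transform an expression matrix
#'
#' Entrywise `log_base(x + 1)`; the +1 offset keeps zero expression at zero
#' and avoids log(0).
#'
#' @param x Non-negative numeric matrix or vector.
#' @param base 2 or 10.
#' @return Transformed matrix/vector of the same shape.
#' @export
log_transform <- function(x, base = 2) {
  if (!base %in% c(2, 10)) abort("base must be 2 or 10")
  if (any(x < 0, na.rm = TRUE)) abort("log_transform requires non-negative input")
  log(x + 1, base = base)
}

#' Column-wise fractional ranks
#'
#' Mid-ranks (ties averaged); ascending assigns rank 1 to the smallest value,
#' descending reverses.
#'
#' @param x Numeric matrix or vector (a vector is one column).
#' @param direction `"ascending"` or `"descending"`.
#' @param margin 2 ranks within each column (default), 1 within each row.
#' @return Ranks, same shape as `x`.
#' @export
rank_transform <- function(x, direction = c("ascending", "descending"), margin = 2L) {
  direction <- match.arg(direction)
  rk <- function(v) if (direction == "ascending") rank(v) else rank(-v)
  if (is.null(dim(x))) return(rk(x))
  out <- if (margin == 2L) apply(x, 2, rk) else t(apply(x, 1, rk))
  dimnames(out) <- dimnames(x)
  out
}

#' Classic quantile normalization over columns
#'
#' Each column's sorted values are replaced by the across-column mean of
#' sorted values at the same rank, so every output column carries the
#' identical multiset of values. Tied input values receive adjacent quantile
#' means in input order (deterministic), which preserves the exact-multiset
#' property. Idempotent.
#'
#' @param x Numeric matrix with at least 2 columns (a single column is
#'   returned unchanged with a warning).
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  if (is.null(dim(x)) || ncol(x) < 2) {
    warn("quantile_normalize needs >= 2 columns; returning input unchanged")
    return(x)
  }
  ord <- apply(x, 2, order)
  sorted <- vapply(seq_len(ncol(x)), function(j) x[ord[, j], j], numeric(nrow(x)))
  mu <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) out[ord[, j], j] <- mu
  dimnames(out) <- dimnames(x)
  out
}

#' Column-wise z-scores
#'
#' `(x - mean) / sd` with the sample standard deviation (denominator n-1).
#' A constant column maps to all zeros with a warning (common for
#' ortholog-groups absent from a species).
#'
#' @param x Numeric matrix or vector.
#' @param margin 2 per column (default), 1 per row.
#' @return Same shape as `x`.
#' @export
zscore_transform <- function(x, margin = 2L) {
  z <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      warn("constant column in zscore_transform; returning zeros")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  if (is.null(dim(x))) return(z(x))
  out <- if (margin == 2L) apply(x, 2, z) else t(apply(x, 1, z))
  dimnames(out) <- dimnames(x)
  out
}

norm_step_names <- c("log2p1", "log10p1", "quantile",
                     "rank_ascending", "rank_descending", "zscore")

apply_norm_step <- function(m, step, margin = 2L) {
  switch(step,
    log2p1 = log_transform(m, 2),
    log10p1 = log_transform(m, 10),
    quantile = quantile_normalize(m),
    rank_ascending = rank_transform(m, "ascending", margin),
    rank_descending = rank_transform(m, "descending", margin),
    zscore = zscore_transform(m, margin),
    abort(paste0("unknown normalization step: ", step))
  )
}

#' Apply an ordered normalization chain to an expression table
#'
#' Steps are applied strictly left to right. Step names: `log2p1`, `log10p1`,
#' `quantile`, `rank_ascending`, `rank_descending`, `zscore`; an empty chain
#' (or `"identity"`) returns the table unchanged.
#'
#' @param table Expression tibble (id column + numeric sample columns).
#' @param steps Character vector of step names, in application order.
#' @param margin 2 = per sample column (default), 1 = per gene row, for the
#'   rank and z-score steps.
#' @return Normalized tibble of the same shape.
#' @export
normalize_table <- function(table, steps, margin = 2L) {
  if (length(steps) == 0 || identical(steps, "identity")) return(table)
  m <- table_to_matrix(table, names(table)[1])
  for (s in steps) m <- apply_norm_step(m, s, margin)
  out <- matrix_to_table(m, names(table)[1])
  attr(out, "stage_meta") <- attr(table, "stage_meta")
  out
}

#' The nine scanned normalization chains
#'
#' Named list of step vectors covering the standard scan grid: the six single
#' steps applied to TPM and the three log2-anchored compositions.
#'
#' @return Named list of character vectors usable as `steps` in
#'   [normalize_table()].
#' @export
table1_normalizations <- function() {
  list(
    log2p1 = "log2p1",
    log10p1 = "log10p1",
    quantile = "quantile",
    rank_ascending = "rank_ascending",
    rank_descending = "rank_descending",
    zscore = "zscore",
    log2p1_quantile = c("log2p1", "quantile"),
    log2p1_zscore = c("log2p1", "zscore"),
    log2p1_quantile_zscore = c("log2p1", "quantile", "zscore")
  )
}
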
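## Pairwise transcriptomic distances between samples (columns).
##
## Seven methods: correlation distances 1 - r and 1 - rho (range [0, 2]),
## plain euclidean/manhattan on the (already normalized) table, cosine
## distance, canberra with the 0/0 := 0 convention (lost-gene rows are zero
## in several species at once), and the Jensen-Shannon distance (square root
## of the base-2 divergence of columns rescaled to sum 1, range [0, 1]).

distance_methods <- c("pearson", "spearman", "euclidean", "manhattan",
                      "cosine", "canberra", "jensen_shannon")

new_deriv_dist <- function(m, method) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  structure(m, method = method, class = c("deriv_dist", class(m)))
}

#' Pairwise distance matrix between samples of an expression table
#'
#' @param table Expression tibble (id column + >= 2 numeric sample columns).
#' @param method One of `"pearson"`, `"spearman"`, `"euclidean"`,
#'   `"manhattan"`, `"cosine"`, `"canberra"`, `"jensen_shannon"`.
#' @return A `deriv_dist`: symmetric numeric matrix, zero diagonal, sample ids
#'   as dimnames, with attribute `"method"`.
#' @export
pairwise_distance <- function(table, method = distance_methods) {
  method <- match.arg(method)
  x <- table_to_matrix(table, names(table)[1])
  if (ncol(x) < 2) abort("need at least 2 samples")
  d <- switch(method,
    pearson = dist_correlation(x, "pearson"),
    spearman = dist_correlation(x, "spearman"),
    euclidean = as.matrix(stats::dist(t(x), method = "euclidean")),
    manhattan = as.matrix(stats::dist(t(x), method = "manhattan")),
    cosine = dist_cosine(x),
    canberra = dist_canberra(x),
    jensen_shannon = dist_jensen_shannon(x)
  )
  diag(d) <- 0
  d <- (d + t(d)) / 2   # enforce exact symmetry against rounding
  dimnames(d) <- list(colnames(x), colnames(x))
  new_deriv_dist(d, method)
}

dist_correlation <- function(x, kind) {
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("correlation distance undefined for constant sample(s): ",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  1 - cor(x, method = kind)
}

dist_cosine <- function(x) {
  nrm <- sqrt(colSums(x^2))
  if (any(nrm == 0)) {
    abort(paste0("cosine distance undefined for all-zero sample(s): ",
                 paste(colnames(x)[nrm == 0], collapse = ", ")))
  }
  sim <- crossprod(x) / tcrossprod(nrm)
  1 - pmin(pmax(sim, -1), 1)
}

dist_canberra <- function(x) {
  n <- ncol(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    xi <- x[, i]
    for (j in (i + 1):n) {
      num <- abs(xi - x[, j])
      den <- abs(xi) + abs(x[, j])
      term <- ifelse(den == 0, 0, num / den)   # 0/0 := 0
      d[i, j] <- d[j, i] <- sum(term)
    }
  }
  d
}

dist_jensen_shannon <- function(x) {
  if (any(x < 0)) abort("jensen_shannon requires non-negative values")
  cs <- colSums(x)
  if (any(cs == 0)) {
    abort(paste0("jensen_shannon undefined for all-zero sample(s): ",
                 paste(colnames(x)[cs == 0], collapse = ", ")))
  }
  p <- sweep(x, 2, cs, "/")
  plogp <- function(v) sum(v[v > 0] * log2(v[v > 0]))
  negent <- apply(p, 2, plogp)   # sum p log2 p per column, reused per pair
  n <- ncol(p)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mmix <- (p[, i] + p[, j]) / 2
      jsd <- negent[i] / 2 + negent[j] / 2 - plogp(mmix)
      d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
    }
  }
  d
}

#' @export
print.deriv_dist <- function(x, ...) {
  cat("<deriv_dist> ", attr(x, "method"), " distance, ",
      nrow(x), " x ", ncol(x), " samples\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Tidy a distance matrix into a long tibble
#'
#' @param x A `deriv_dist`.
#' @param ... Unused.
#' @return Tibble `sample_a`, `sample_b`, `distance`, `method`.
#' @export
tidy.deriv_dist <- function(x, ...) {
  m <- unclass(x)
  as_tibble(m, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b", values_to = "distance") |>
    dplyr::mutate(method = attr(x, "method") %||% NA_character_)
}

#' Heatmap of a distance matrix
#'
#' Samples keep their matrix order; use stage-ordered tables to read
#' within-species smoothness off the diagonal blocks.
#'
#' @param object A `deriv_dist`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deriv_dist <- function(object, ...) {
  df <- tidy(object)
  df$sample_a <- factor(df$sample_a, levels = rownames(object))
  df$sample_b <- factor(df$sample_b, levels = rev(rownames(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0(attr(object, "method"), " distance")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}
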
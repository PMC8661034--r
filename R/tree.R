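## Distance-tree inference and derivedness indices.
##
## One agglomeration engine implements both neighbor joining (Saitou-Nei via
## the Studier-Keppler Q criterion) and BIONJ (the same joins with
## variance-weighted reduction weights lambda). Both reconstruct any additive
## distance matrix exactly in double precision. Negative branch estimates are
## clamped to 0 on the returned tree (derivedness indices are path sums and
## must stay non-negative); the raw estimates are kept as an edge attribute.

#' Infer an unrooted distance tree by NJ or BIONJ
#'
#' @param d Symmetric distance matrix with sample ids as dimnames (a
#'   `deriv_dist` or plain matrix), at least 3 samples.
#' @param method `"bionj"` (default) or `"nj"`.
#' @return An unrooted `phylo`. Branch lengths are clamped at 0; raw
#'   (possibly negative) estimates are in `attr(, "edge_length_raw")`,
#'   aligned with the `edge` matrix. `attr(, "tree_method")` records the
#'   method.
#' @export
infer_tree <- function(d, method = c("bionj", "nj")) {
  method <- match.arg(method)
  m <- unclass(d)
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("d must be a square matrix")
  if (max(abs(m - t(m))) > 1e-8) abort("distance matrix is not symmetric")
  if (nrow(m) < 3) abort("need at least 3 samples to infer a tree")
  if (is.null(rownames(m))) abort("distance matrix must have sample ids as dimnames")
  phy <- nj_engine(m, variance_weighted = (method == "bionj"))
  raw <- phy$edge.length
  phy$edge.length <- pmax(raw, 0)
  attr(phy, "edge_length_raw") <- raw
  attr(phy, "tree_method") <- method
  phy
}

## Shared NJ/BIONJ agglomeration. Builds the tree as a newick string with
## full-precision (%.17g) branch lengths, then parses it with ape so all
## downstream phylo machinery applies. Ties in the Q criterion break to the
## first (column-major) minimum - deterministic.
nj_engine <- function(D, variance_weighted = FALSE) {
  n <- nrow(D)
  d <- unname(D)
  v <- d                      # BIONJ variance estimates start at the distances
  frag <- as.list(rownames(D))
  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    k <- which.min(q)
    i <- (k - 1) %% n + 1
    j <- (k - 1) %/% n + 1
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    rest <- setdiff(seq_len(n), c(i, j))
    if (variance_weighted) {
      vij <- v[i, j]
      lam <- if (vij > 0) {
        0.5 + sum(v[j, rest] - v[i, rest]) / (2 * (n - 2) * vij)
      } else 0.5
      lam <- min(1, max(0, lam))
    } else {
      lam <- 0.5
    }
    du <- lam * (d[i, rest] - li) + (1 - lam) * (d[j, rest] - lj)
    vu <- lam * v[i, rest] + (1 - lam) * v[j, rest] - lam * (1 - lam) * v[i, j]
    d <- rbind(cbind(d[rest, rest, drop = FALSE], du), c(du, 0))
    v <- rbind(cbind(v[rest, rest, drop = FALSE], vu), c(vu, 0))
    frag <- c(frag[rest],
              sprintf("(%s:%.17g,%s:%.17g)", frag[[i]], li, frag[[j]], lj))
    n <- n - 1
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[[1]], la, frag[[2]], lb, frag[[3]], lc)
  ape::read.tree(text = nwk)
}

tree_root_node <- function(phy) {
  cand <- unique(phy$edge[, 1])
  cand[!cand %in% phy$edge[, 2]]
}

#' Root a tree on the edge separating an outgroup from the ingroup
#'
#' The outgroup samples must form one side of a bipartition of the unrooted
#' tree. The root is placed at the midpoint of the separating edge (50/50
#' split); the designated ancestral node is the ingroup-side endpoint of that
#' edge, so the split choice never affects ingroup derivedness indices.
#'
#' @param phy Unrooted `phylo` over samples.
#' @param outgroup Character vector of outgroup sample ids (non-empty, proper
#'   subset of the leaves).
#' @return A rooted `phylo` with `attr(, "ancestral_node")` set to the
#'   ingroup-side node number.
#' @export
root_by_outgroup <- function(phy, outgroup) {
  tips <- phy$tip.label
  if (length(outgroup) == 0) abort("outgroup is empty")
  if (!all(outgroup %in% tips)) {
    abort(paste0("outgroup sample(s) not in tree: ",
                 paste(setdiff(outgroup, tips), collapse = ", ")))
  }
  ingroup <- setdiff(tips, outgroup)
  if (length(ingroup) == 0) abort("outgroup contains every sample; no ingroup left")
  if (!is_bipartition(phy, outgroup)) {
    viol <- bipartition_violators(phy, outgroup)
    abort(paste0("outgroup is not monophyletic; interleaved sample(s): ",
                 paste(viol, collapse = ", ")))
  }
  rt <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  rt <- ape::reorder.phylo(rt, "cladewise")
  root <- tree_root_node(rt)
  kids <- which(rt$edge[, 1] == root)
  if (length(kids) != 2) abort("internal error: rooted tree root is not binary")
  total <- sum(rt$edge.length[kids])
  rt$edge.length[kids] <- total / 2
  ## ancestral node = root child on the ingroup side
  child_nodes <- rt$edge[kids, 2]
  on_ingroup <- vapply(child_nodes, function(nd) {
    below <- tips_below(rt, nd)
    all(below %in% ingroup)
  }, logical(1))
  if (!any(on_ingroup)) abort("internal error: no ingroup-side root child")
  attr(rt, "ancestral_node") <- child_nodes[which(on_ingroup)[1]]
  attr(rt, "tree_method") <- attr(phy, "tree_method")
  rt
}

## Leaves below a node in a rooted tree (the node itself if it is a leaf).
tips_below <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  phy$tip.label[phangorn::Descendants(phy, node, type = "tips")[[1]]]
}

## Does `group` form one side of a bipartition of the (possibly unrooted)
## tree? Tested by rooting at a non-group tip and checking the MRCA clade.
is_bipartition <- function(phy, group) {
  tips <- phy$tip.label
  if (length(group) <= 1 || length(group) >= length(tips) - 1) return(TRUE)
  anchor <- setdiff(tips, group)[1]
  rt <- ape::root(phy, outgroup = anchor, resolve.root = TRUE)
  mr <- ape::getMRCA(rt, group)
  setequal(tips_below(rt, mr), group)
}

bipartition_violators <- function(phy, group) {
  anchor <- setdiff(phy$tip.label, group)[1]
  rt <- ape::root(phy, outgroup = anchor, resolve.root = TRUE)
  mr <- ape::getMRCA(rt, group)
  setdiff(tips_below(rt, mr), group)
}

#' Most recent common ancestor of a set of samples
#'
#' @param phy Rooted `phylo`.
#' @param samples Non-empty character vector of leaf labels.
#' @return Node number (the leaf's own number for a single sample).
#' @export
mrca_node <- function(phy, samples) {
  if (length(samples) == 0) abort("samples must be non-empty")
  miss <- setdiff(samples, phy$tip.label)
  if (length(miss) > 0) {
    abort(paste0("sample(s) not in tree: ", paste(miss, collapse = ", ")))
  }
  if (length(samples) == 1) return(match(samples, phy$tip.label))
  ape::getMRCA(phy, samples)
}

#' Derivedness index of each sample: branch length from the ancestral node
#'
#' The index of a leaf is the sum of (clamped, non-negative) branch lengths on
#' the path from the designated ancestral node down to the leaf. Leaves that
#' are not descendants of the ancestor are excluded with a warning, which is
#' what restricting to a clade-specific ancestor does.
#'
#' @param phy Rooted `phylo` (typically from [root_by_outgroup()]).
#' @param ancestor Node number; defaults to `attr(phy, "ancestral_node")`.
#' @return Tibble `sample_id`, `index`.
#' @export
derivedness_profile <- function(phy, ancestor = NULL) {
  ancestor <- ancestor %||% attr(phy, "ancestral_node")
  if (is.null(ancestor)) {
    abort("no ancestor given and the tree has no ancestral_node attribute")
  }
  depths <- ape::node.depth.edgelength(phy)   # path length from the root
  below <- tips_below(phy, ancestor)
  excluded <- setdiff(phy$tip.label, below)
  if (length(excluded) > 0) {
    warn(paste0(length(excluded),
                " leaf/leaves not below the ancestor excluded from the profile"))
  }
  idx <- match(below, phy$tip.label)
  tibble(sample_id = below, index = depths[idx] - depths[ancestor])
}
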
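dist_of <- function(phy) ape::cophenetic.phylo(phy)

test_that("three-taxon closed form places branches exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  for (meth in c("nj", "bionj")) {
    phy <- infer_tree(d, meth)
    cd <- dist_of(phy)
    expect_equal(cd["A", "B"], 3)
    expect_equal(cd["A", "C"], 4)
    expect_equal(cd["B", "C"], 5)
    ## pendant branches a=1, b=2, c=3
    pend <- setNames(phy$edge.length[phy$edge[, 2] <= 3],
                     phy$tip.label[phy$edge[phy$edge[, 2] <= 3, 2]])
    expect_equal(pend[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
  }
})

test_that("the 4-taxon additive worked example is recovered with its lengths", {
  ## oracle: generating tree ((A:1,B:2):1,(C:3,D:4)); pairwise sums below
  labs <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4));")
  for (meth in c("nj", "bionj")) {
    phy <- infer_tree(d, meth)
    expect_equal(phangorn::RF.dist(ape::unroot(phy), ape::unroot(ref)), 0)
    expect_equal(dist_of(phy)[labs, labs], d, tolerance = 1e-12)
  }
})

test_that("NJ and BIONJ reconstruct random additive matrices exactly", {
  set.seed(101)
  for (i in 1:25) {
    truth <- random_additive_tree(sample(4:12, 1))
    d <- dist_of(truth)
    for (meth in c("nj", "bionj")) {
      phy <- infer_tree(d, meth)
      expect_equal(phangorn::RF.dist(ape::unroot(truth), ape::unroot(phy)), 0)
      expect_cophenetic_equal(phy, d, tol = 1e-9)
    }
  }
})

test_that("our NJ matches the ape oracle topology on noisy matrices", {
  set.seed(55)
  for (i in 1:10) {
    truth <- random_additive_tree(8)
    d <- dist_of(truth)
    noise <- matrix(runif(64, 0, 0.05), 8, 8)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    dn <- d + noise
    ours <- infer_tree(dn, "nj")
    oracle <- ape::nj(dn)
    expect_equal(phangorn::RF.dist(ape::unroot(ours), ape::unroot(oracle)), 0)
  }
})

test_that("identical rows join as a zero-length cherry; negatives are clamped", {
  labs <- c("A", "B", "C", "D")
  truth <- random_additive_tree(4)
  truth$tip.label <- labs
  d <- dist_of(truth)
  d["A", "B"] <- d["B", "A"] <- 0
  d["A", "C"] <- d["C", "A"] <- d["B", "C"]
  d["A", "D"] <- d["D", "A"] <- d["B", "D"]
  phy <- infer_tree(d, "bionj")
  expect_equal(dist_of(phy)["A", "B"], 0)

  ## triangle-inequality violation forces a negative pendant estimate
  dd <- matrix(c(0, 1, 1, 1, 0, 3, 1, 3, 0), 3, 3,
               dimnames = list(labs[1:3], labs[1:3]))
  phy2 <- infer_tree(dd, "nj")
  raw <- attr(phy2, "edge_length_raw")
  expect_true(any(raw < 0))
  expect_true(all(phy2$edge.length >= 0))
  expect_equal(phy2$edge.length, pmax(raw, 0))
})

test_that("non-symmetric and too-small matrices are rejected", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(infer_tree(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_error(infer_tree(d3), "symmetric")
})

test_that("outgroup rooting splits the separating edge and marks the ancestor", {
  phy <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,O:3):0.5);")
  rt <- root_by_outgroup(phy, "O")
  root <- setdiff(unique(rt$edge[, 1]), rt$edge[, 2])
  kids <- which(rt$edge[, 1] == root)
  expect_length(kids, 2)
  expect_equal(rt$edge.length[kids], c(1.5, 1.5))  # O's pendant edge 3, split 50/50
  anc <- attr(rt, "ancestral_node")
  below <- sort(rt$tip.label[phangorn::Descendants(rt, anc, "tips")[[1]]])
  expect_equal(below, c("A", "B", "C"))
  ## ingroup path lengths unaffected by the split choice
  cd <- dist_of(rt)
  expect_equal(cd["A", "C"], 1 + 0.5 + 0.5 + 1.5)
})

test_that("rooting rejects empty, full, or interleaved outgroups", {
  phy <- ape::read.tree(text = "((A:1,O1:1):1,(B:1,O2:1):1);")
  expect_error(root_by_outgroup(phy, character(0)), "empty")
  expect_error(root_by_outgroup(phy, c("A", "B", "O1", "O2")), "no ingroup")
  expect_error(root_by_outgroup(phy, c("O1", "O2")), "not monophyletic")
  expect_error(root_by_outgroup(phy, "missing"), "not in tree")
})

test_that("mrca handles single leaves, full sets, and plain clades", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  phy <- ape::root(phy, outgroup = "C", resolve.root = TRUE)
  expect_equal(mrca_node(phy, "A"), match("A", phy$tip.label))
  expect_equal(mrca_node(phy, phy$tip.label),
               setdiff(unique(phy$edge[, 1]), phy$edge[, 2]))
  ab <- mrca_node(phy, c("A", "B"))
  expect_setequal(phy$tip.label[phangorn::Descendants(phy, ab, "tips")[[1]]],
                  c("A", "B"))
  expect_error(mrca_node(phy, character(0)), "non-empty")
})

test_that("derivedness indices are ancestor-to-leaf path sums", {
  phy <- ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
  prof <- derivedness_profile(phy, root)
  idx <- setNames(prof$index, prof$sample_id)
  expect_equal(idx[c("A", "B", "C")], c(A = 1.5, B = 2.5, C = 3))
  ## from an internal ancestor, non-descendants are excluded with a warning
  ab <- mrca_node(phy, c("A", "B"))
  expect_warning(prof2 <- derivedness_profile(phy, ab), "excluded")
  expect_setequal(prof2$sample_id, c("A", "B"))
  expect_equal(prof2$index[prof2$sample_id == "A"], 1)
  ## zero-length tree gives zero indices
  phy0 <- phy; phy0$edge.length[] <- 0
  expect_equal(derivedness_profile(phy0, root)$index, rep(0, 3))
})

test_that("index is additive along the path and scales with the matrix", {
  set.seed(77)
  truth <- random_additive_tree(8)
  d <- dist_of(truth)
  phy <- infer_tree(d, "bionj")
  rt <- root_by_outgroup(phy, phy$tip.label[1])
  anc <- attr(rt, "ancestral_node")
  prof <- suppressWarnings(derivedness_profile(rt, anc))
  ## additivity: index from ancestor = index from intermediate + path to it
  depths <- ape::node.depth.edgelength(rt)
  kid_edges <- which(rt$edge[, 1] == anc & rt$edge[, 2] > length(rt$tip.label))
  if (length(kid_edges) > 0) {
    mid <- rt$edge[kid_edges[1], 2]
    below_mid <- rt$tip.label[phangorn::Descendants(rt, mid, "tips")[[1]]]
    prof_mid <- suppressWarnings(derivedness_profile(rt, mid))
    for (tip in below_mid) {
      expect_equal(prof$index[prof$sample_id == tip],
                   prof_mid$index[prof_mid$sample_id == tip] +
                     (depths[mid] - depths[anc]))
    }
  }
  ## uniform scaling of distances scales every index by the same factor
  phy2 <- infer_tree(d * 2.5, "bionj")
  rt2 <- root_by_outgroup(phy2, phy2$tip.label[1])
  prof2 <- suppressWarnings(derivedness_profile(rt2, attr(rt2, "ancestral_node")))
  m <- match(prof$sample_id, prof2$sample_id)
  expect_equal(prof2$index[m], prof$index * 2.5, tolerance = 1e-9)
})

test_that("newick io round-trips lengths and supports and flags imbalance", {
  phy <- read_newick(text = "((A:1,B:2):0.5,C:3);")
  expect_equal(sort(phy$tip.label), c("A", "B", "C"))
  txt <- write_newick(phy)
  phy2 <- read_newick(text = txt)
  expect_equal(dist_of(phy2), dist_of(phy), tolerance = 1e-12)

  sup <- read_newick(text = "((A:1,B:2)95:0.5,C:3);")
  expect_true("95" %in% sup$node.label)
  expect_match(write_newick(sup), "95")

  set.seed(8)
  truth <- random_additive_tree(10)
  back <- read_newick(text = write_newick(truth))
  expect_lt(max(abs(dist_of(back)[truth$tip.label, truth$tip.label] -
                    dist_of(truth))), 1e-9)

  expect_error(read_newick(text = "((A:1,B:2:0.5,C:3);"), "unclosed")
  expect_error(read_newick(text = "(A:1,B:2)):0.5;"), "position")
})
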
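# Shared fixtures, built in code at test time.

# A random unrooted tree with known branch lengths and its exact (additive)
# leaf-to-leaf distance matrix.
random_additive_case <- function(n_leaves, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.1, 2))
  tree <- ape::unroot(tree)
  d <- ape::cophenetic.phylo(tree)
  d <- d[sort(rownames(d)), sort(rownames(d))]
  list(tree = tree, d = d)
}

# Topology-only split keys (ignores branch lengths).
split_keys <- function(tree) sort(names(tree_bipartitions(tree)))

# Length of a leaf's pendant branch, read off the bipartition table. The
# canonical key of a pendant split is the leaf's own name, except for the
# alphabetically first leaf, whose key is the complement set.
pendant_length <- function(tree, leaf) {
  b <- tree_bipartitions(tree)
  ref <- sort(tree$tip.label)[1]
  key <- if (leaf == ref) {
    paste(sort(setdiff(tree$tip.label, leaf)), collapse = "|")
  } else {
    leaf
  }
  unname(b[key])
}

# The spec-style 4-leaf additive matrix realized by ((a:1,b:2):1,c:3,d:4).
additive4 <- function() {
  labs <- c("a", "b", "c", "d")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["a", "b"] <- 3; d["a", "c"] <- 5; d["a", "d"] <- 6
  d["b", "c"] <- 6; d["b", "d"] <- 7; d["c", "d"] <- 7
  d + t(d)
}

# A deterministic base partition for planted-collection experiments
# (6 chemically coherent groups).
planted_base <- function() {
  simplified_alphabet("base6", "AGPST,C,DENQ,FWY,HKR,ILMV",
                      name = "planted base", category = "other")
}

toy_collection <- function() {
  as_alphabet_collection(list(
    simplified_alphabet("c1", "AGPST,C,DENQ,FWY,HKR,ILMV",
                        category = "chemistry"),
    simplified_alphabet("c2", "ACFGILMVWY,DE,HKR,NPQST",
                        category = "chemistry"),
    simplified_alphabet("p1", "A,C,DENQ,FWY,G,H,ILMV,KR,P,ST",
                        category = "sequence_alignment"),
    simplified_alphabet("p2", "AGPST,DENQ,HKR,CFILMVWY",
                        category = "protein_blocks")
  ))
}
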
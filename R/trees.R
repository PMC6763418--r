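# Trees are ape "phylo" objects, always unrooted: the dendrograms express
# similarity, not ancestry, so no root or outgroup logic exists anywhere.

# Coerce input to a plain labelled distance matrix. Similarity matrices
# (alphabet_similarity / consensus_similarity) are complemented to 1 - s.
as_distance_matrix <- function(d, tol = 1e-9) {
  if (inherits(d, "alphabet_similarity") || inherits(d, "consensus_similarity")) {
    d <- similarity_to_distance(d)
  }
  d <- unclass(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("L", seq_len(nrow(d)))
  }
  if (nrow(d) < 3L) stop("need at least 3 labels", call. = FALSE)
  if (max(abs(d - t(d))) > tol) {
    stop("distance matrix is asymmetric beyond tolerance 1e-9", call. = FALSE)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou--Nei agglomeration with the Q-criterion. When several
#' pairs minimize Q, the pair whose (sorted) representative labels are
#' lexicographically smallest is joined, making the output deterministic;
#' a cluster is represented by the smallest original label it contains.
#' Branch lengths may be negative, as in the classical algorithm.
#'
#' Similarity matrices ([build_similarity_matrix()], [build_consensus()])
#' are accepted and complemented to distances `1 - s` first.
#'
#' @param d Symmetric labelled distance matrix with at least 3 rows, or a
#'   similarity matrix of one of the package's similarity classes.
#' @return An unrooted `phylo` tree over the row labels.
#' @export
neighbor_joining <- function(d) {
  d <- as_distance_matrix(d)
  labels <- rownames(d)
  frag <- labels                      # growing Newick fragments
  rep_label <- labels                 # tie-break representatives
  fmt <- function(x) sprintf("%.12g", x)

  while (length(frag) > 3L) {
    n <- length(frag)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      paste(sort(rep_label[ij]), collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    new_rep <- min(rep_label[c(i, j)])
    keep <- setdiff(seq_len(n), c(i, j))
    new_d <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d),
               c(new_d, 0))
    frag <- c(frag[keep], new_frag)
    rep_label <- c(rep_label[keep], new_rep)
  }

  # three remaining nodes: closed-form star lengths
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[1], fmt(la), frag[2], fmt(lb), frag[3], fmt(lc))
  ape::read.tree(text = newick)
}

# One parent edge index per non-root node, and the storage root.
edge_of_node <- function(phy) {
  eo <- integer(max(phy$edge))
  eo[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  eo
}

# For each tip: indices of the edges on its path to the storage root.
tip_root_paths <- function(phy) {
  eo <- edge_of_node(phy)
  parent <- integer(max(phy$edge))
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  lapply(seq_along(phy$tip.label), function(t) {
    path <- integer(0)
    node <- t
    while (node != root) {
      path <- c(path, eo[node])
      node <- parent[node]
    }
    path
  })
}

#' Ordinary-least-squares branch lengths on a fixed topology
#'
#' Re-fits every branch length of `topology` to minimize the sum over leaf
#' pairs of squared differences between tree path length and the input
#' distance, solving the edge--path incidence system by QR. The topology is
#' unchanged; fitted lengths may be negative and are reported as fitted
#' (see [clamp_negative_branches()] for a display-only clamp).
#'
#' @param topology A `phylo` tree whose tip set equals the matrix labels.
#' @param d Symmetric labelled distance matrix (or package similarity
#'   matrix, complemented as in [neighbor_joining()]).
#' @return The tree with OLS-fitted `edge.length`.
#' @export
fit_ols_branch_lengths <- function(topology, d) {
  d <- as_distance_matrix(d)
  tips <- topology$tip.label
  if (!setequal(tips, rownames(d))) {
    stop("tree leaf set does not match matrix labels", call. = FALSE)
  }
  paths <- tip_root_paths(topology)
  n <- length(tips)
  pairs <- utils::combn(n, 2L)
  n_edges <- nrow(topology$edge)
  X <- matrix(0, ncol(pairs), n_edges)
  y <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    onpath <- union(setdiff(paths[[i]], paths[[j]]),
                    setdiff(paths[[j]], paths[[i]]))
    X[p, onpath] <- 1
    y[p] <- d[tips[i], tips[j]]
  }
  qx <- qr(X)
  if (qx$rank < n_edges) {
    stop("singular edge-path system; cannot fit branch lengths",
         call. = FALSE)
  }
  topology$edge.length <- as.numeric(qr.coef(qx, y))
  topology
}

#' Build a consensus dendrogram from an alphabet collection
#'
#' Convenience wrapper: consensus similarity -> distance -> neighbor joining
#' -> OLS branch-length refinement.
#'
#' @param collection An `alphabet_collection`.
#' @return An unrooted `phylo` tree over the 20 amino acids.
#' @export
consensus_tree <- function(collection) {
  d <- similarity_to_distance(build_consensus(collection))
  fit_ols_branch_lengths(neighbor_joining(d), d)
}

#' Dendrogram of the alphabets themselves
#'
#' Builds the all-against-all alphabet similarity matrix, complements it to
#' distances and fits a neighbor-joining + OLS tree, so nearby leaves are
#' alphabets that group amino acids in similar ways.
#'
#' @param collection An `alphabet_collection` of at least 3 alphabets.
#' @return An unrooted `phylo` tree over the alphabet ids.
#' @export
alphabet_tree <- function(collection) {
  s <- build_similarity_matrix(collection)
  d <- similarity_to_distance(s)
  fit_ols_branch_lengths(neighbor_joining(d), d)
}

#' Serialize a tree to Newick / parse Newick to a tree
#'
#' Thin wrappers around [ape::write.tree()] and [ape::read.tree()]. Parsing
#' first checks bracket balance and the terminating semicolon and reports the
#' character position of the first problem.
#'
#' @param tree A `phylo` object.
#' @return `tree_to_newick`: a single Newick string (semicolon-terminated).
#' @export
tree_to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 12)
}

#' @rdname tree_to_newick
#' @param text A Newick string.
#' @export
newick_to_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") depth <- depth + 1L
    if (chars[pos] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop(sprintf("malformed Newick: unmatched ')' at position %d", pos),
           call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed Newick: %d unclosed '(' at position %d",
                 depth, nchar(text) + 1L), call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop(sprintf("malformed Newick: missing terminating ';' (position %d)",
                 nchar(text) + 1L), call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick: unparseable tree", call. = FALSE)
  }
  tree
}

#' Bipartitions (splits) of an unrooted tree with their branch lengths
#'
#' Every edge of the tree induces a bipartition of the leaf set. Splits are
#' keyed canonically by the sorted labels of the side not containing the
#' alphabetically first leaf, so keys are comparable across trees on the
#' same leaf set and invariant under side swapping. Pendant edges are
#' included.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Named numeric vector: names are split keys, values branch lengths.
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  nnode_all <- max(tree$edge)
  below <- vector("list", nnode_all)
  for (t in seq_len(ntip)) below[[t]] <- tree$tip.label[t]
  ord <- rev(seq_len(nrow(tree$edge)))  # cladewise storage: reverse = postorder-ish
  # accumulate tip sets bottom-up; iterate until stable for safety
  repeat {
    changed <- FALSE
    for (e in ord) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      add <- below[[child]]
      if (!is.null(add) && !all(add %in% below[[par]])) {
        below[[par]] <- union(below[[par]], add)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ref <- sort(tree$tip.label)[1L]
  keys <- character(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    side <- below[[tree$edge[e, 2]]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys[e] <- paste(sort(side), collapse = "|")
  }
  lens <- tree$edge.length
  if (is.null(lens)) lens <- rep(0, nrow(tree$edge))
  stats::setNames(lens, keys)
}

#' Branch score distance between two trees
#'
#' For every bipartition present in either tree, takes the difference of the
#' associated branch lengths (an absent split contributes length 0), and
#' aggregates the squared differences over all splits. The default returns
#' the square root of that sum; `squared = TRUE` returns the sum itself
#' (both conventions are in circulation for this statistic).
#'
#' @param t1,t2 `phylo` trees over the identical leaf-label set.
#' @param squared If `TRUE`, return the sum of squared differences without
#'   taking the square root.
#' @return A non-negative number; 0 exactly when the trees have identical
#'   topology and branch lengths.
#' @export
branch_score_distance <- function(t1, t2, squared = FALSE) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf-label sets", call. = FALSE)
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  all_keys <- union(names(b1), names(b2))
  l1 <- ifelse(all_keys %in% names(b1), b1[all_keys], 0)
  l2 <- ifelse(all_keys %in% names(b2), b2[all_keys], 0)
  ss <- sum((l1 - l2)^2)
  if (squared) ss else sqrt(ss)
}

#' Jackknife robustness of the consensus dendrogram
#'
#' Systematically drops one alphabet at a time, rebuilds the consensus
#' distance matrix and its NJ + OLS dendrogram from the remaining n - 1
#' alphabets, and scores each reduced tree against the full-collection tree
#' with the branch score distance. Small distances mean no single study
#' dominates the consensus.
#'
#' @param collection An `alphabet_collection` of at least 2 alphabets.
#' @param squared Branch-score convention flag, see
#'   [branch_score_distance()].
#' @return Data frame with columns `dropped_id` and `branch_score_distance`
#'   (one row per alphabet, in collection order); attribute `convention` is
#'   `"sqrt"` or `"squared"`.
#' @export
jackknife_consensus <- function(collection, squared = FALSE) {
  stopifnot(inherits(collection, "alphabet_collection"))
  if (length(collection) < 2L) {
    stop("need at least 2 alphabets to jackknife", call. = FALSE)
  }
  full <- consensus_tree(collection)
  dists <- vapply(seq_along(collection), function(i) {
    branch_score_distance(full, consensus_tree(collection[-i]),
                          squared = squared)
  }, numeric(1))
  structure(
    data.frame(dropped_id = names(collection),
               branch_score_distance = dists,
               row.names = NULL, stringsAsFactors = FALSE),
    convention = if (squared) "squared" else "sqrt"
  )
}

#' Cut the consensus hierarchy into a simplified alphabet of k groups
#'
#' Average-linkage agglomerative clustering of the consensus distance
#' (1 - consensus similarity), cut at `k` clusters, yields a nested family
#' of simplified alphabets from size 20 down to 1: grouping the most similar
#' amino acids first, exactly as reading the consensus dendrogram from its
#' tips inward.
#'
#' @param m A `consensus_similarity` matrix.
#' @param k Number of groups, between 1 and 20.
#' @return A `simplified_alphabet` with `k` groups, id `consensus_k<k>`.
#' @export
agglomerate_alphabet <- function(m, k) {
  stopifnot(inherits(m, "consensus_similarity"))
  if (!is.numeric(k) || k < 1L || k > 20L) {
    stop("`k` must be between 1 and 20", call. = FALSE)
  }
  k <- as.integer(k)
  d <- similarity_to_distance(m)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  mem <- stats::cutree(hc, k = k)
  groups <- split(AMINO_ACIDS, mem[AMINO_ACIDS])
  simplified_alphabet(sprintf("consensus_k%d", k), unname(groups),
                      name = sprintf("agglomerated consensus, %d groups", k),
                      category = "other")
}

#' Clamp negative branch lengths to zero (display only)
#'
#' OLS refinement can fit small negative branch lengths; statistics such as
#' the branch score distance always use the raw fitted lengths, but for
#' plotting or export a non-negative version is sometimes wanted.
#'
#' @param tree A `phylo` object.
#' @return The tree with `edge.length` floored at 0.
#' @export
clamp_negative_branches <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}
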
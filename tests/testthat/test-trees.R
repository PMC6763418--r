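test_that("neighbor joining on 3 leaves gives the closed-form star", {
  labs <- c("a", "b", "c")
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, dimnames = list(labs, labs))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, labs)
  # pendant lengths: (d_ab + d_ac - d_bc)/2 etc.
  expect_equal(pendant_length(tr, "a"), (2 + 3 - 4) / 2)
  expect_equal(pendant_length(tr, "b"), (2 + 4 - 3) / 2)
  expect_equal(pendant_length(tr, "c"), (3 + 4 - 2) / 2)
})

test_that("the 4-leaf additive matrix is reproduced exactly with the ab|cd split", {
  d <- additive4()
  tr <- fit_ols_branch_lengths(neighbor_joining(d), d)
  expect_true("c|d" %in% names(tree_bipartitions(tr)))
  cd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(cd, d, tolerance = 1e-9)
  # OLS residual is zero on additive input
  expect_lt(sum((cd - d)^2), 1e-18)
})

test_that("all-equal distances resolve deterministically with equal pendants", {
  labs <- letters[1:5]
  d <- matrix(1, 5, 5, dimnames = list(labs, labs)); diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(tree_to_newick(t1), tree_to_newick(t2))
  pend <- vapply(labs, function(l) pendant_length(t1, l), numeric(1))
  expect_equal(unname(pend), rep(pend[[1]], 5))
})

test_that("NJ + OLS reproduces random additive matrices exactly", {
  for (seed in 1:50) {
    n <- 5 + seed %% 8
    case <- random_additive_case(n, seed)
    fit <- fit_ols_branch_lengths(neighbor_joining(case$d), case$d)
    cd <- ape::cophenetic.phylo(fit)[rownames(case$d), colnames(case$d)]
    expect_equal(cd, case$d, tolerance = 1e-6)
    # topology agrees with the independent NJ implementation in ape
    expect_identical(split_keys(fit),
                     split_keys(ape::nj(as.dist(case$d))))
  }
})

test_that("OLS branch lengths vary continuously with the input matrix", {
  case <- random_additive_case(7, 99)
  topo <- neighbor_joining(case$d)
  base <- fit_ols_branch_lengths(topo, case$d)$edge.length
  for (eps in c(1e-6, 1e-4, 1e-2)) {
    d2 <- case$d
    d2[1, 2] <- d2[2, 1] <- d2[1, 2] + eps
    pert <- fit_ols_branch_lengths(topo, d2)$edge.length
    expect_lt(max(abs(pert - base)), 10 * eps)
  }
})

test_that("OLS on a 3-leaf star equals the NJ closed form", {
  labs <- c("a", "b", "c")
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, dimnames = list(labs, labs))
  nj <- neighbor_joining(d)
  ols <- fit_ols_branch_lengths(nj, d)
  expect_equal(tree_bipartitions(ols), tree_bipartitions(nj),
               tolerance = 1e-9)
})

test_that("Newick serialization round-trips topology and lengths", {
  t1 <- newick_to_tree("((a:1,b:2):1,c:3,d:4);")
  rt <- newick_to_tree(tree_to_newick(t1))
  expect_equal(tree_bipartitions(rt), tree_bipartitions(t1),
               tolerance = 1e-9)

  multi <- newick_to_tree("(a:1,b:1,c:1,d:2,(e:1,f:1):0.5);")
  rt2 <- newick_to_tree(tree_to_newick(multi))
  expect_equal(tree_bipartitions(rt2), tree_bipartitions(multi),
               tolerance = 1e-9)

  neg <- newick_to_tree("((a:1,b:-0.25):1,c:3,d:4);")
  rt3 <- newick_to_tree(tree_to_newick(neg))
  expect_equal(sort(tree_bipartitions(rt3)), sort(tree_bipartitions(neg)),
               tolerance = 1e-12)
  expect_equal(min(rt3$edge.length), -0.25)

  expect_error(newick_to_tree("((a:1,b:2):1,c:3"), "position")
  expect_error(newick_to_tree("(a:1,b:2))"), "position 10")
})

test_that("branch score distance follows its definition on hand-built cases", {
  t1 <- newick_to_tree("((a:1,b:2):1,c:3,d:4);")
  expect_identical(branch_score_distance(t1, t1), 0)

  # same topology, one internal edge 1.0 vs 1.5
  t2 <- newick_to_tree("((a:1,b:2):1.5,c:3,d:4);")
  expect_equal(branch_score_distance(t1, t2), 0.5)
  expect_equal(branch_score_distance(t1, t2, squared = TRUE), 0.25)

  # conflicting splits ab|cd (x = 1) vs ac|bd (y = 0.7), pendants equal
  t3 <- newick_to_tree("((a:1,c:3):0.7,b:2,d:4);")
  expect_equal(branch_score_distance(t1, t3), sqrt(1^2 + 0.7^2))

  expect_error(
    branch_score_distance(t1, newick_to_tree("((a:1,b:2):1,c:3,e:4);")),
    "leaf-label sets")
})

test_that("branch score distance agrees with phangorn and is a metric", {
  trees <- lapply(1:12, function(s) {
    set.seed(s)
    ape::rtree(8, rooted = FALSE, tip.label = letters[1:8])
  })
  for (i in 1:6) {
    d12 <- branch_score_distance(trees[[i]], trees[[i + 1]])
    expect_equal(
      d12,
      unname(phangorn::treedist(trees[[i]],
                                trees[[i + 1]])["branch.score.difference"]),
      tolerance = 1e-9)
    # symmetry, non-negativity
    expect_gte(d12, 0)
    expect_equal(d12, branch_score_distance(trees[[i + 1]], trees[[i]]))
  }
  # identity of indiscernibles and triangle inequality on sampled triples
  for (i in 1:10) {
    expect_identical(branch_score_distance(trees[[i]], trees[[i]]), 0)
  }
  set.seed(1)
  for (rep in 1:20) {
    ijk <- sample(length(trees), 3)
    dij <- branch_score_distance(trees[[ijk[1]]], trees[[ijk[2]]])
    djk <- branch_score_distance(trees[[ijk[2]]], trees[[ijk[3]]])
    dik <- branch_score_distance(trees[[ijk[1]]], trees[[ijk[3]]])
    expect_lte(dik, dij + djk + 1e-12)
  }
})

test_that("jackknife distances vanish for identical collections and respect twins", {
  base <- planted_base()
  same <- generate_planted_collection(base, n = 6, noise = 0, seed = 2)
  jk <- jackknife_consensus(same)
  expect_identical(nrow(jk), 6L)
  expect_true(all(jk$branch_score_distance < 1e-9))
  expect_identical(attr(jk, "convention"), "sqrt")

  # a duplicated alphabet: dropping either twin gives the same distance
  col <- bundled_collection()[1:8]
  twin <- col[[3]]
  twin$id <- paste0(twin$id, "_twin")
  col2 <- as_alphabet_collection(c(unclass(col), list(twin)))
  jk2 <- jackknife_consensus(col2)
  d_orig <- jk2$branch_score_distance[jk2$dropped_id == col[[3]]$id]
  d_twin <- jk2$branch_score_distance[jk2$dropped_id == twin$id]
  expect_equal(d_orig, d_twin, tolerance = 1e-9)

  expect_error(jackknife_consensus(same[1]), "at least 2")
})

test_that("jackknife perturbations stay small on a mildly noisy planted collection", {
  col <- generate_planted_collection(planted_base(), n = 20, noise = 0.05,
                                     seed = 3)
  full <- consensus_tree(col)
  jk <- jackknife_consensus(col)
  expect_lt(max(jk$branch_score_distance), 0.10 * sum(full$edge.length))
})

test_that("agglomeration cuts the consensus into valid partitions of size k", {
  cons <- build_consensus(bundled_collection())
  a20 <- agglomerate_alphabet(cons, 20)
  expect_true(all(lengths(a20$groups) == 1))
  a1 <- agglomerate_alphabet(cons, 1)
  expect_length(a1$groups, 1)
  for (k in c(2, 5, 11, 19)) {
    expect_length(agglomerate_alphabet(cons, k)$groups, k)
  }
  expect_error(agglomerate_alphabet(cons, 0), "between 1 and 20")
  expect_error(agglomerate_alphabet(cons, 21), "between 1 and 20")

  # noiseless planted consensus recovers the base partition exactly
  base <- planted_base()
  cons0 <- build_consensus(
    generate_planted_collection(base, n = 10, noise = 0, seed = 5))
  rec <- agglomerate_alphabet(cons0, length(base$groups))
  expect_identical(
    sort(vapply(rec$groups, paste, "", collapse = "")),
    sort(vapply(base$groups, paste, "", collapse = "")))
})
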